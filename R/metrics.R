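# Fit metrics used throughout: RMSE and out-of-sample R-squared.

#' Root mean squared error
#'
#' @param y observed values.
#' @param yhat predicted values (same length).
#' @return `sqrt(mean((y - yhat)^2))`.
#' @export
rmse <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) > 0)
  sqrt(mean((y - yhat)^2))
}

#' Out-of-sample coefficient of determination
#'
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`, with the baseline mean
#' taken from the evaluation set itself (recorded so the alternative --
#' a training-set mean -- can be supplied via `baseline`). Unlike squared
#' correlation this is negative whenever the predictions do worse than the
#' evaluation-set mean, which occurs after aggressive occlusion.
#'
#' @param y observed values of the evaluation set.
#' @param yhat predictions.
#' @param baseline baseline value for the total sum of squares; defaults to
#'   `mean(y)`.
#' @return A scalar, possibly negative; `NA` (with a warning) when `y` has
#'   zero variance.
#' @export
r_squared <- function(y, yhat, baseline = mean(y)) {
  stopifnot(length(y) == length(yhat), length(y) > 0)
  ss_tot <- sum((y - baseline)^2)
  if (ss_tot == 0) {
    warning("zero variance in observed values; R^2 undefined")
    return(NA_real_)
  }
  1 - sum((y - yhat)^2) / ss_tot
}

#' Select the best cross-validation instance
#'
#' The winner minimizes the mean of validation and test RMSE; ties break
#' deterministically toward the lowest fold id.
#'
#' @param instances list of trained instances (see [train_instance()]),
#'   each carrying `rmse_val`, `rmse_test` and `fold`.
#' @return The selected instance.
#' @export
select_best_instance <- function(instances) {
  if (length(instances) == 0) stop("no instances to select from")
  score <- vapply(instances, function(it) {
    if (is.null(it$rmse_val) || is.null(it$rmse_test) ||
        !is.finite(it$rmse_val) || !is.finite(it$rmse_test))
      stop("all instances must carry finite validation and test RMSE")
    mean(c(it$rmse_val, it$rmse_test))
  }, numeric(1))
  folds <- vapply(instances, function(it) as.numeric(it$fold), numeric(1))
  instances[[order(score, folds)[1]]]
}
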