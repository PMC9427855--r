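# End-to-end evaluation of the pipeline against the phantom's planted truth:
# does the saliency GLM recover the planted effect regions, does occlusion
# collapse predictive power, and do the strength-of-association curves cross
# near the planted changepoint?

#' Evaluate planted-signal recovery on the synthetic phantom
#'
#' Runs generation, preprocessing, cross-validation training, saliency and
#' GLM cluster detection under a single master seed, then scores the result
#' against the generator's ground truth: cluster coverage and Dice overlap
#' of the planted effect regions, null-region containment, post-occlusion
#' out-of-sample R-squared for the union of planted regions, and the
#' crossing point of the low-CL and high-CL strength-of-association curves.
#'
#' @param seed master seed for the whole run.
#' @param config optional `taucl_pipeline_config`; defaults to
#'   `pipeline_config(seed = seed)` (stages up to the GLM are forced on).
#' @param verbose print stage progress.
#' @return A list: `report` (the pipeline report), and the scalar summaries
#'   `coverage`, `dice`, `max_cluster_null_fraction`, `any_cluster_all_null`,
#'   `baseline_r2` (per split), `occluded_r2` (per split, all planted
#'   regions occluded), `crossing_cl` (first crossing of the high- over the
#'   low-CL curve, `NA` if none), `n_clusters`.
#' @export
evaluate_recovery <- function(seed, config = NULL, verbose = FALSE) {
  if (is.null(config)) config <- pipeline_config(seed = seed)
  config$stages <- c("generate", "preprocess", "train", "saliency", "glm")
  rep <- run_pipeline(config, verbose = verbose)
  atlas <- rep$atlas
  planted_low <- atlas_role_mask(atlas, "effect_low")
  planted_high <- atlas_role_mask(atlas, "effect_high")
  planted <- planted_low | planted_high
  cs <- rep$glm$best_saliency$clusters
  cm <- cluster_mask(cs)
  coverage <- sum(cm & planted) / sum(planted)
  dice <- if (sum(cm) + sum(planted) > 0)
    2 * sum(cm & planted) / (sum(cm) + sum(planted)) else NA_real_
  nullm <- atlas_role_mask(atlas, "null")
  null_fracs <- vapply(cs$clusters,
                       function(cl) mean(nullm[cl$voxels]), numeric(1))
  # occlusion of all planted regions (amyloid-negative template fill)
  fill <- resolve_fill(config$fill, rep$X, rep$cohort$cl,
                       config$synth$changepoint_cl)
  col_of <- stats::setNames(seq_len(nrow(rep$cohort)), rep$cohort$id)
  bf <- rep$plan$folds[[rep$best$fold]]
  splits <- list(train = unname(col_of[bf$train]),
                 validation = unname(col_of[bf$validation]),
                 test = unname(col_of[rep$plan$test]))
  occ <- occlusion_r2(rep$best, rep$X, rep$cohort$cl, splits, planted,
                      fill = fill)
  curve_low <- strength_of_association(rep$instances, rep$X, rep$cohort$cl,
                                       planted_low, span = config$span,
                                       fill = fill)
  curve_high <- strength_of_association(rep$instances, rep$X, rep$cohort$cl,
                                        planted_high, span = config$span,
                                        fill = fill)
  # the dominance changepoint: the crossing above which the high-CL curve
  # permanently overtakes the low-CL curve (earlier sign flips can occur in
  # the near-zero tails of both curves)
  crossings <- curve_crossing(curve_high, curve_low)
  tab <- occ$table
  list(report = rep,
       coverage = coverage, dice = dice,
       max_cluster_null_fraction = if (length(null_fracs)) max(null_fracs)
       else NA_real_,
       any_cluster_all_null = any(null_fracs >= 1),
       baseline_r2 = stats::setNames(tab$r2_baseline, tab$split),
       occluded_r2 = stats::setNames(tab$r2_post, tab$split),
       crossing_cl = if (length(crossings))
         crossings[length(crossings)] else NA_real_,
       curves = list(low = curve_low, high = curve_high),
       n_clusters = length(cs$clusters))
}

#' Empirical family-wise error rate of the permutation maxT threshold
#'
#' Monte-Carlo calibration check: pure-noise dependent stacks are generated
#' under the null (no association between the data and any covariate), the
#' permutation maxT threshold is computed for each replicate, and the
#' fraction of replicates whose observed maximum t exceeds the threshold
#' estimates the family-wise error rate. Under exchangeability the
#' procedure's exact level is `floor(alpha * (n_perm + 1)) / (n_perm + 1)`.
#'
#' @param n_subjects subjects per replicate (default 30).
#' @param n_voxels voxels per replicate (default 400).
#' @param n_reps number of null replicates (default 500).
#' @param n_perm permutations per replicate (default 199).
#' @param alpha nominal FWE level (default 0.05).
#' @param seed master seed.
#' @param tail contrast tail (see [fwe_threshold()]).
#' @return List with `fwer` (empirical rate), `n_reps`, and `rejections`.
#' @export
estimate_fwer <- function(n_subjects = 30L, n_voxels = 400L, n_reps = 500L,
                          n_perm = 199L, alpha = 0.05, seed = 1L,
                          tail = "positive") {
  rejections <- vapply(seq_len(n_reps), function(r) {
    with_seed(derive_seed(seed, paste0("fwer/", r)), {
      cohort <- data.frame(cl = stats::runif(n_subjects, -10, 140),
                           age = stats::rnorm(n_subjects, 71, 7.7),
                           sex = sample(c("F", "M"), n_subjects,
                                        replace = TRUE))
      X <- make_design(cohort)
      Y <- matrix(stats::rnorm(n_subjects * n_voxels), n_subjects, n_voxels)
      thr <- fwe_threshold(Y, X, alpha = alpha, n_perm = n_perm,
                           seed = derive_seed(seed, paste0("perm/", r)),
                           tail = tail)
      fit <- fit_voxelwise_glm(Y, X)
      obs <- if (tail == "two.sided") max(abs(fit$tstat)) else max(fit$tstat)
      obs > as.numeric(thr)
    })
  }, logical(1))
  list(fwer = mean(rejections), n_reps = n_reps, rejections = rejections)
}
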