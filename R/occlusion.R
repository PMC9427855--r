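# Occlusion analyses: how much unique predictive information a cluster
# carries (out-of-sample R-squared after zeroing it out of the input), and
# how that importance moves across the Centiloid continuum (LOESS-smoothed
# absolute prediction differences = "strength of association").

#' Occlude a region of a volume
#'
#' Sets the masked voxels to a fill value (default 0, the minimum of the
#' \[0, 1\]-scaled input, representing absent signal; mean fill over the
#' mask is available for sensitivity analyses).
#'
#' @param v a `taucl_volume`.
#' @param mask region to occlude (atlas, volume or logical array).
#' @param fill fill value, or `"mean"` for the in-region mean of `v`.
#' @return A `taucl_volume` with the region replaced.
#' @export
occlude_volume <- function(v, mask, fill = 0) {
  stopifnot(is_volume(v))
  m <- as_mask_array(mask, dim(v$values))
  out <- v$values
  if (identical(fill, "mean")) fill <- if (any(m)) mean(out[m]) else 0
  out[m] <- fill
  volume_like(v, out)
}

# `fill` may be a scalar or a voxel-wise template vector (length nvox)
occlude_matrix <- function(X, mask, fill = 0) {
  idx <- which(as.vector(mask))
  if (length(fill) > 1) {
    stopifnot(length(fill) == nrow(X))
    X[idx, ] <- fill[idx]
  } else {
    X[idx, ] <- fill
  }
  X
}

#' Out-of-sample R-squared before and after occlusion
#'
#' Recomputes predictions on occluded inputs for each split with the
#' network weights untouched, and compares per-split R-squared against the
#' unoccluded baseline.
#'
#' @param instance a `taucl_instance`.
#' @param X input matrix from [as_input_matrix()] (scaled volumes).
#' @param y Centiloid targets per column of `X`.
#' @param splits named list of column-index vectors (e.g. `train`,
#'   `validation`, `test`).
#' @param mask occlusion mask (logical array on the input grid).
#' @param fill scalar fill value, `"mean"`, or a voxel-wise numeric
#'   template of length `nrow(X)` (e.g. an amyloid-negative mean image).
#' @return A `taucl_occlusion` list: `table` (data frame with per-split
#'   `r2_baseline`, `r2_post`, `rmse_post`), and `predictions` (per-subject
#'   full and occluded predictions).
#' @export
occlusion_r2 <- function(instance, X, y, splits, mask, fill = 0) {
  stopifnot(length(y) == ncol(X))
  check_same_grid(dim(mask), attr(X, "input_dim") %||% instance$input_dim,
                  "mask and input grids")
  if (identical(fill, "mean")) fill <- mean(X[as.vector(mask), ])
  Xo <- occlude_matrix(X, mask, fill)
  pred_full <- predict_batch(instance, X)
  pred_occ <- predict_batch(instance, Xo)
  tab <- do.call(rbind, lapply(names(splits), function(s) {
    idx <- splits[[s]]
    data.frame(split = s,
               n = length(idx),
               r2_baseline = r_squared(y[idx], pred_full[idx]),
               r2_post = r_squared(y[idx], pred_occ[idx]),
               rmse_post = rmse(y[idx], pred_occ[idx]),
               stringsAsFactors = FALSE)
  }))
  structure(list(table = tab,
                 predictions = data.frame(index = seq_along(y), cl = y,
                                          pred_full = pred_full,
                                          pred_occluded = pred_occ),
                 fill = if (length(fill) > 1) "voxelwise template" else fill,
                 mask_size = sum(mask)),
            class = "taucl_occlusion")
}

#' @export
print.taucl_occlusion <- function(x, ...) {
  cat(sprintf("<taucl_occlusion> %d voxels occluded (fill %s)\n",
              x$mask_size,
              if (is.character(x$fill)) x$fill else format(x$fill)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Local weighted regression (tricube, local-linear)
#'
#' For each grid point, a degree-1 weighted least-squares fit over the
#' `ceiling(span * n)` nearest data points, with tricube weights
#' `(1 - (d/h)^3)^3` scaled by the bandwidth `h` = distance to the
#' farthest included neighbor.
#'
#' @param x,y data vectors (at least 5 points; `x` must vary).
#' @param span fraction of points in each local fit, in (0, 1].
#' @param grid evaluation points (default: 100 evenly spaced points over
#'   `range(x)`).
#' @return Numeric vector of smoothed values at `grid`.
#' @export
loess_smooth <- function(x, y, span = 0.5, grid = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 5,
            span > 0, span <= 1)
  if (diff(range(x)) == 0) stop("degenerate x: all values equal")
  if (is.null(grid)) grid <- seq(min(x), max(x), length.out = 100L)
  n <- length(x)
  q <- min(n, max(2L, ceiling(span * n)))
  vapply(grid, function(g) {
    d <- abs(x - g)
    h <- sort(d, partial = q)[q]
    if (h == 0) return(mean(y[d == 0]))
    w <- pmax(0, 1 - (d / h)^3)^3
    use <- w > 0
    xw <- x[use] - g
    W <- w[use]
    # weighted normal equations for intercept + slope at the grid point
    s0 <- sum(W); s1 <- sum(W * xw); s2 <- sum(W * xw^2)
    t0 <- sum(W * y[use]); t1 <- sum(W * xw * y[use])
    det <- s0 * s2 - s1^2
    if (det <= .Machine$double.eps * s0 * max(s2, 1)) return(t0 / s0)
    (s2 * t0 - s1 * t1) / det
  }, numeric(1))
}

#' Strength of association across the Centiloid continuum
#'
#' For each instance, the absolute difference between predictions on full
#' and occluded inputs is computed for every subject (all splits pooled)
#' and LOESS-smoothed against measured Centiloid on a common grid; the
#' cross-instance mean and standard error of the mean summarize the curve.
#' Smoothed values are clamped at zero (the underlying errors are
#' nonnegative).
#'
#' @param instances list of `taucl_instance`s (>= 1).
#' @param X input matrix (scaled volumes).
#' @param y measured Centiloid per column of `X`.
#' @param mask occlusion mask.
#' @param span LOESS span (default 0.3; narrow enough to resolve
#'   importance changes on the ~20 CL scale of a changepoint).
#' @param grid Centiloid evaluation grid (default 100 points over the
#'   observed range; points outside the observed range are clipped with a
#'   warning).
#' @param fill scalar fill value, `"mean"`, or a voxel-wise template
#'   vector (e.g. a tau-naive template from the lowest-CL subjects).
#' @return A `taucl_assoc_curve`: list with `grid`, `per_instance`
#'   (instances x grid matrix), `mean`, `sem`, `span`.
#' @export
strength_of_association <- function(instances, X, y, mask, span = 0.3,
                                    grid = NULL, fill = 0) {
  stopifnot(length(instances) >= 1)
  rng <- range(y)
  if (is.null(grid)) {
    grid <- seq(rng[1], rng[2], length.out = 100L)
  } else {
    if (any(grid < rng[1] | grid > rng[2])) {
      warning("grid points outside the observed CL range were clipped")
      grid <- grid[grid >= rng[1] & grid <= rng[2]]
    }
    if (is.unsorted(grid, strictly = TRUE)) stop("grid must be increasing")
  }
  if (identical(fill, "mean")) fill <- mean(X[as.vector(mask), ])
  Xo <- occlude_matrix(X, mask, fill)
  per <- t(vapply(instances, function(inst) {
    e <- abs(predict_batch(inst, X) - predict_batch(inst, Xo))
    pmax(0, loess_smooth(y, e, span = span, grid = grid))
  }, numeric(length(grid))))
  k <- nrow(per)
  sem <- if (k > 1) apply(per, 2, stats::sd) / sqrt(k) else rep(0, length(grid))
  structure(list(grid = grid, per_instance = per,
                 mean = colMeans(per), sem = sem, span = span,
                 n_instances = k),
            class = "taucl_assoc_curve")
}

#' @export
print.taucl_assoc_curve <- function(x, ...) {
  cat(sprintf(
    "<taucl_assoc_curve> %d grid points on CL [%.1f, %.1f], %d instance(s), span %.2f\n",
    length(x$grid), min(x$grid), max(x$grid), x$n_instances, x$span))
  cat(sprintf("  mean strength: %.2f (min) to %.2f (max)\n",
              min(x$mean), max(x$mean)))
  invisible(x)
}

#' Crossing point of two strength-of-association curves
#'
#' Finds where `a` overtakes `b` (or vice versa) by locating sign changes
#' of the mean-curve difference on the common grid, interpolating linearly
#' within the bracketing interval.
#'
#' @param a,b `taucl_assoc_curve`s on the same grid.
#' @return Numeric vector of crossing CL values (possibly empty).
#' @export
curve_crossing <- function(a, b) {
  stopifnot(inherits(a, "taucl_assoc_curve"), inherits(b, "taucl_assoc_curve"),
            isTRUE(all.equal(a$grid, b$grid)))
  d <- a$mean - b$mean
  s <- sign(d)
  idx <- which(s[-1] * s[-length(s)] < 0)
  vapply(idx, function(i) {
    x0 <- a$grid[i]; x1 <- a$grid[i + 1]
    x0 + (x1 - x0) * abs(d[i]) / (abs(d[i]) + abs(d[i + 1]))
  }, numeric(1))
}

#' Split a cluster into atlas-defined sub-clusters
#'
#' Intersects a cluster's voxels with the atlas parcels; every nonempty
#' intersection becomes a sub-cluster named for its region, and voxels on
#' the atlas background form a `"residual"` sub-cluster. The sub-clusters
#' partition the cluster exactly.
#'
#' @param cluster one element of a `taucl_clusters$clusters` list (needs
#'   `voxels`), or a logical mask array.
#' @param atlas a `taucl_atlas` on the same grid.
#' @return Named list of logical mask arrays.
#' @export
split_subclusters <- function(cluster, atlas) {
  vox <- if (is.list(cluster) && !is.null(cluster$voxels)) cluster$voxels
  else which(cluster != 0)
  labs <- atlas$labels[vox]
  out <- list()
  for (lb in sort(unique(labs))) {
    m <- array(FALSE, dim(atlas$labels))
    m[vox[labs == lb]] <- TRUE
    nm <- if (lb == 0) "residual"
    else atlas$name_map$name[match(lb, atlas$name_map$label)]
    out[[nm]] <- m
  }
  out
}
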