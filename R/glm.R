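# Voxel-wise general linear models: SUVR or saliency values regressed on
# Centiloid with age and sex covariates, a t-contrast on the Centiloid
# coefficient, family-wise error control by Freedman-Lane permutation of the
# maximum statistic, and cluster-extent thresholding of the t-map.

#' Build the subject-level design matrix
#'
#' Columns: intercept, `cl`, `age`, and a sex indicator; the contrast of
#' interest selects the Centiloid coefficient. Row order follows the cohort.
#'
#' @param cohort cohort table with `cl`, `age`, `sex`.
#' @return A numeric matrix with attribute `focus = "cl"`.
#' @export
make_design <- function(cohort) {
  X <- stats::model.matrix(~ cl + age + sex, data = cohort)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[-seq_len(qr_x$rank)]]
    stop(sprintf("design matrix is rank deficient; collinear column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  attr(X, "focus") <- "cl"
  X
}

#' Fit ordinary least squares at every voxel
#'
#' Per voxel, `beta = (X'X)^{-1} X' y` and the t statistic of the focus
#' coefficient `t = c'beta / sqrt(sigma2 * c'(X'X)^{-1} c)`, with
#' `sigma2 = RSS / df` and `df = n - p`. Voxels fit exactly (zero residual)
#' get an infinite t and are counted in attribute `n_exact`.
#'
#' @param Y `n x V` matrix of dependent values (subjects by voxels).
#' @param design design matrix from [make_design()] (or any full-rank
#'   numeric matrix).
#' @param focus name or index of the coefficient to test (defaults to the
#'   design's `focus` attribute, else `"cl"`).
#' @return List with `beta` (`p x V`), `tstat` (length `V`), `df`,
#'   `focus`, and `se` (standard errors of the focus coefficient).
#' @export
fit_voxelwise_glm <- function(Y, design, focus = NULL) {
  X <- design
  stopifnot(nrow(Y) == nrow(X))
  if (is.null(focus)) focus <- attr(X, "focus") %||% "cl"
  j <- if (is.character(focus)) match(focus, colnames(X)) else as.integer(focus)
  if (is.na(j)) stop(sprintf("focus column '%s' not in the design", focus))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[-seq_len(qr_x$rank)]]
    stop(sprintf("design matrix is rank deficient; collinear column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  n <- nrow(X); p <- ncol(X); df <- n - p
  if (df <= 0) stop("no residual degrees of freedom")
  XtX_inv <- chol2inv(qr.R(qr_x))
  beta <- XtX_inv %*% crossprod(X, Y)
  res <- Y - X %*% beta
  rss <- colSums(res^2)
  # numerically exact fits (zero residual up to round-off): flag, t = +-Inf
  exact <- rss <= .Machine$double.eps^1.5 * pmax(colSums(Y^2), 1)
  sigma2 <- rss / df
  cvc <- XtX_inv[j, j]
  se <- sqrt(sigma2 * cvc)
  tstat <- beta[j, ] / se
  tstat[exact] <- Inf * sign(beta[j, exact])
  list(beta = beta, tstat = tstat, df = df, focus = colnames(X)[j] %||% j,
       se = se, n_exact = sum(exact))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all permutations of 1..n (used when n! is small enough to enumerate)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Permutation maxT threshold with family-wise error control
#'
#' Freedman-Lane scheme: the dependent data are residualized against the
#' nuisance covariates, residual rows are permuted, the nuisance fit is
#' added back, and the full-model t statistic of the focus coefficient is
#' recomputed; the threshold is the `floor(alpha * (B + 1))`-th largest of
#' the `B` permutation maxima, so that rejecting `t > threshold` controls
#' the family-wise error rate at `floor(alpha * (B + 1)) / (B + 1)` under
#' exchangeability. If fewer than `n_perm` distinct permutations exist they
#' are enumerated exhaustively (with a warning).
#'
#' @param Y `n x V` dependent matrix.
#' @param design design matrix.
#' @param focus focus coefficient (default from the design, else `"cl"`).
#' @param alpha family-wise error level (default 0.05).
#' @param n_perm number of random permutations (default 499; at least 100).
#' @param seed integer seed for the permutation draw.
#' @param tail `"positive"` (default) thresholds t; `"two.sided"`
#'   thresholds |t|.
#' @return The threshold (numeric scalar) with attributes `null_max_t`
#'   (the permutation maxima), `alpha`, `tail` and `n_perm`.
#' @export
fwe_threshold <- function(Y, design, focus = NULL, alpha = 0.05,
                          n_perm = 499L, seed = 1L,
                          tail = c("positive", "two.sided")) {
  tail <- match.arg(tail)
  X <- design
  stopifnot(nrow(Y) == nrow(X), alpha > 0, alpha <= 1)
  if (n_perm < 100L) stop("need at least 100 permutations")
  if (is.null(focus)) focus <- attr(X, "focus") %||% "cl"
  j <- if (is.character(focus)) match(focus, colnames(X)) else as.integer(focus)
  if (is.na(j)) stop(sprintf("focus column '%s' not in the design", focus))
  n <- nrow(X); p <- ncol(X); df <- n - p
  Z <- X[, -j, drop = FALSE]
  Qz <- qr.Q(qr(Z))                       # orthonormal nuisance basis
  xr <- X[, j] - Qz %*% crossprod(Qz, X[, j])
  xr_norm <- sqrt(sum(xr^2))
  if (xr_norm < 1e-12) stop("focus column is collinear with the nuisance")
  u <- xr / xr_norm
  E <- Y - Qz %*% crossprod(Qz, Y)        # nuisance residuals
  css <- colSums(E^2)                     # invariant under row permutation
  # permutation set
  if (lgamma(n + 1) <= log(n_perm)) {
    warning(sprintf(
      "only %d distinct permutations of %d rows; enumerating exhaustively",
      factorial(n), n))
    P <- all_perms(n)
    P <- P[-1L, , drop = FALSE]           # drop the identity
  } else {
    P <- with_seed(derive_seed(seed, "fwe"),
                   t(replicate(n_perm, sample.int(n))))
  }
  B <- nrow(P)
  UQ <- cbind(u, Qz)                      # (n x (1 + pz))
  max_t <- vapply(seq_len(B), function(b) {
    Ep <- E[P[b, ], , drop = FALSE]
    M <- crossprod(UQ, Ep)                # first row: a = u'Ep
    a <- M[1L, ]
    rssf <- pmax(css - colSums(M^2), 0)
    tt <- a / sqrt(rssf / df)
    if (tail == "two.sided") max(abs(tt)) else max(tt)
  }, numeric(1))
  k <- min(max(1L, floor(alpha * (B + 1))), B)
  thr <- sort(max_t, decreasing = TRUE)[k]
  structure(thr, null_max_t = max_t, alpha = alpha, tail = tail,
            n_perm = B, focus = colnames(X)[j] %||% j)
}

neighbor_offsets <- function(connectivity = 26L) {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  man <- rowSums(abs(offs))
  switch(as.character(connectivity),
         "6" = offs[man == 1, , drop = FALSE],
         "18" = offs[man <= 2, , drop = FALSE],
         "26" = offs,
         stop("connectivity must be 6, 18 or 26"))
}

# connected components over a logical 3D array by breadth-first flood fill
label_components <- function(cond, connectivity = 26L) {
  d <- dim(cond)
  offs <- neighbor_offsets(connectivity)
  lab <- array(0L, d)
  idx <- which(cond)
  if (length(idx) == 0L) return(lab)
  coord <- arrayInd(idx, d)
  in_set <- array(FALSE, d); in_set[idx] <- TRUE
  nextlab <- 0L
  for (s in seq_along(idx)) {
    if (lab[idx[s]] != 0L) next
    nextlab <- nextlab + 1L
    queue <- matrix(coord[s, ], 1L)
    lab[idx[s]] <- nextlab
    while (nrow(queue) > 0L) {
      nb <- queue[rep(seq_len(nrow(queue)), each = nrow(offs)), ,
                  drop = FALSE] +
        offs[rep(seq_len(nrow(offs)), nrow(queue)), , drop = FALSE]
      ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] &
        nb[, 2] >= 1L & nb[, 2] <= d[2] &
        nb[, 3] >= 1L & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      new <- unique(lin[in_set[lin] & lab[lin] == 0L])
      lab[new] <- nextlab
      queue <- arrayInd(new, d)
    }
  }
  lab
}

#' Scale a cluster-extent threshold to the working voxel size
#'
#' The extent criterion is volumetric in spirit: `extent_1mm` voxels at
#' 1 mm^3 define a minimum cluster volume in mm^3, converted to a voxel
#' count at the working resolution.
#'
#' @param extent_1mm extent in voxels at 1 mm isotropic (default 200).
#' @param voxel_size_mm working voxel edge lengths (scalar or length 3).
#' @return Integer minimum voxel count (at least 1).
#' @export
scale_extent <- function(extent_1mm = 200, voxel_size_mm = 1) {
  vol <- prod(rep_len(as.numeric(voxel_size_mm), 3L))
  max(1L, as.integer(round(extent_1mm / vol)))
}

#' Threshold a t-map and extract clusters
#'
#' Suprathreshold voxels (`t > threshold`, positive tail; `|t|` with
#' `tail = "two.sided"`) are grouped into 3D connected components under the
#' chosen connectivity; components smaller than `min_extent` voxels are
#' discarded. Clusters come back ordered by decreasing size.
#'
#' @param tmap `taucl_volume` of kind `"tstat"`, or a numeric 3D array.
#' @param threshold finite t threshold.
#' @param min_extent minimum cluster size in voxels at the working
#'   resolution (use [scale_extent()] to convert the 1 mm criterion).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param tail `"positive"` or `"two.sided"`.
#' @param atlas optional `taucl_atlas` for per-cluster anatomical
#'   composition.
#' @return A `taucl_clusters` object: list with `clusters` (each having
#'   `id`, `voxels`, `size`, `peak_t`, `centroid_vox`, `composition`),
#'   `labels` (integer array), and provenance fields.
#' @export
threshold_and_cluster <- function(tmap, threshold, min_extent = 200L,
                                  connectivity = 26L,
                                  tail = c("positive", "two.sided"),
                                  atlas = NULL) {
  tail <- match.arg(tail)
  stopifnot(is.finite(threshold))
  tv <- if (is_volume(tmap)) tmap$values else tmap
  stat <- if (tail == "two.sided") abs(tv) else tv
  cond <- stat > threshold
  lab <- label_components(cond, connectivity)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_extent)
  # order kept clusters by decreasing size (ties: first-found label)
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  out_lab <- array(0L, dim(tv))
  clusters <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    vox <- which(lab == keep[i])
    out_lab[vox] <- i
    comp <- NULL
    if (!is.null(atlas)) {
      labs_here <- atlas$labels[vox]
      comp <- table(factor(labs_here, levels = c(0, atlas$name_map$label),
                           labels = c("unlabeled", atlas$name_map$name)))
      comp <- comp[comp > 0]
    }
    clusters[[i]] <- list(
      id = i, voxels = vox, size = length(vox),
      peak_t = max(stat[vox]),
      centroid_vox = colMeans(arrayInd(vox, dim(tv))),
      composition = comp)
  }
  structure(list(clusters = clusters, labels = out_lab,
                 threshold = threshold, min_extent = as.integer(min_extent),
                 connectivity = as.integer(connectivity), tail = tail,
                 grid = dim(tv)),
            class = "taucl_clusters")
}

#' @export
print.taucl_clusters <- function(x, ...) {
  cat(sprintf(
    "<taucl_clusters> %d cluster(s) (t > %.3f, extent >= %d, %d-connectivity)\n",
    length(x$clusters), x$threshold, x$min_extent, x$connectivity))
  for (cl in x$clusters)
    cat(sprintf("  #%d: %d voxels, peak %.2f%s\n", cl$id, cl$size, cl$peak_t,
                if (!is.null(cl$composition))
                  paste0(" [", paste(names(cl$composition),
                                     cl$composition, sep = ":",
                                     collapse = ", "), "]")
                else ""))
  invisible(x)
}

#' Union mask of all clusters in a set
#'
#' @param cs a `taucl_clusters` object.
#' @param ids optional cluster ids to include (default all).
#' @return Logical array of the t-map grid.
#' @export
cluster_mask <- function(cs, ids = NULL) {
  stopifnot(inherits(cs, "taucl_clusters"))
  m <- array(FALSE, cs$grid)
  for (cl in cs$clusters)
    if (is.null(ids) || cl$id %in% ids) m[cl$voxels] <- TRUE
  m
}

#' Cross-instance cluster consistency
#'
#' Dice overlap `2|A.B| / (|A| + |B|)` between the binarized cluster masks
#' of every pair of instances, plus a consensus map counting in how many
#' instances each voxel is part of a cluster.
#'
#' @param cluster_sets list (length >= 2) of `taucl_clusters` objects on a
#'   common grid.
#' @return List with `dice` (symmetric matrix) and `consensus`
#'   (integer array).
#' @export
cluster_consistency <- function(cluster_sets) {
  if (length(cluster_sets) < 2L)
    stop("need at least two cluster sets")
  masks <- lapply(cluster_sets, cluster_mask)
  d <- dim(masks[[1]])
  for (m in masks) check_same_grid(dim(m), d, "cluster-set grids")
  k <- length(masks)
  dice <- matrix(1, k, k)
  for (i in seq_len(k - 1)) for (jj in (i + 1):k) {
    a <- masks[[i]]; b <- masks[[jj]]
    denom <- sum(a) + sum(b)
    dice[i, jj] <- dice[jj, i] <-
      if (denom == 0) NA_real_ else 2 * sum(a & b) / denom
  }
  consensus <- Reduce(`+`, lapply(masks, function(m) array(as.integer(m), d)))
  list(dice = dice, consensus = consensus)
}
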