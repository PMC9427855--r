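# Image-level transforms: [0,1] min-max scaling for network input,
# reference-region SUVR for the linear analysis, masking, and Gaussian
# FWHM smoothing with a renormalized truncated kernel at the edges.

as_mask_array <- function(mask, dims) {
  m <- if (inherits(mask, "taucl_atlas")) mask$mask
  else if (is_volume(mask)) mask$values != 0
  else if (is.array(mask)) mask != 0
  else stop("mask must be an atlas, volume or array")
  check_same_grid(dim(m), dims, "mask and volume grids")
  m
}

#' Min-max scale a volume to \[0, 1\] within a brain mask
#'
#' The minimum and maximum are computed over in-mask voxels only, so that
#' background zeros do not pin the minimum; out-of-mask voxels are set to 0.
#' A constant in-mask image scales to all zeros with a warning rather than
#' failing, so batch runs survive degenerate inputs.
#'
#' @param v a `taucl_volume`.
#' @param mask brain mask (atlas, volume or logical array).
#' @return A `taucl_volume` of kind `"scaled"`, with attributes
#'   `scale_min` and `scale_max` recording the in-mask range for provenance.
#' @export
minmax_scale <- function(v, mask) {
  stopifnot(is_volume(v))
  m <- as_mask_array(mask, dim(v$values))
  if (!any(m)) stop("mask is empty")
  x <- v$values[m]
  lo <- min(x); hi <- max(x)
  out <- array(0, dim(v$values))
  if (hi > lo) {
    out[m] <- (x - lo) / (hi - lo)
  } else {
    warning("constant image inside mask; scaled output is all zeros")
  }
  res <- volume_like(v, out, kind = "scaled")
  attr(res, "scale_min") <- lo
  attr(res, "scale_max") <- hi
  res
}

#' Standardized uptake value ratio against a reference region
#'
#' Divides every voxel by the mean intensity over the atlas reference region
#' (cerebellar-cortex-like in the synthetic atlas), the conventional SUVR
#' normalization for tau-PET.
#'
#' @param v a `taucl_volume` of SUV values.
#' @param atlas a `taucl_atlas` with a region of role `"reference"`.
#' @return A `taucl_volume` of kind `"SUVR"` with attribute `reference_mean`.
#' @export
compute_suvr <- function(v, atlas) {
  stopifnot(is_volume(v))
  ref <- atlas_role_mask(atlas, "reference")
  check_same_grid(dim(ref), dim(v$values), "atlas and volume grids")
  if (!any(ref)) stop("reference region is empty")
  ref_mean <- mean(v$values[ref])
  if (!is.finite(ref_mean) || ref_mean <= 0)
    stop(sprintf("reference-region mean must be positive (got %g)", ref_mean))
  res <- volume_like(v, v$values / ref_mean, kind = "SUVR")
  attr(res, "reference_mean") <- ref_mean
  res
}

#' Zero a volume outside a mask
#'
#' @param v a `taucl_volume`.
#' @param mask mask (atlas, volume or logical array) on the same grid.
#' @return A `taucl_volume` with out-of-mask voxels set to 0.
#' @export
apply_mask <- function(v, mask) {
  stopifnot(is_volume(v))
  m <- as_mask_array(mask, dim(v$values))
  out <- v$values
  out[!m] <- 0
  volume_like(v, out)
}

# 1D smoothing matrix with a renormalized truncated Gaussian kernel: rows
# near the edge renormalize over the in-grid support, so no mass leaks into
# (or wraps from) the background.
gaussian_kernel_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  offs <- (-r):r
  g <- exp(-offs^2 / (2 * sigma_vox^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + offs
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- g[ok] / sum(g[ok])
  }
  K
}

apply_along_axis <- function(x, K, axis) {
  d <- dim(x)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  y <- K %*% matrix(xp, dp[1], dp[2] * dp[3])
  dim(y) <- dp
  aperm(y, order(perm))
}

#' Gaussian smoothing by FWHM
#'
#' Separable 3D Gaussian convolution. The kernel standard deviation per axis
#' is `fwhm_mm / (voxel_size_mm * 2 * sqrt(2 * log(2)))` voxels; at grid
#' edges the truncated kernel is renormalized (no wrap, no zero-leak).
#'
#' @param v a `taucl_volume`.
#' @param fwhm_mm full width at half maximum of the kernel in mm
#'   (default 2).
#' @return A smoothed `taucl_volume` of the same kind.
#' @export
gaussian_smooth <- function(v, fwhm_mm = 2) {
  stopifnot(is_volume(v), fwhm_mm > 0)
  sigma <- fwhm_mm / (v$voxel_size_mm * 2 * sqrt(2 * log(2)))
  x <- v$values
  d <- dim(x)
  for (axis in 1:3) {
    x <- apply_along_axis(x, gaussian_kernel_matrix(d[axis], sigma[axis]),
                          axis)
  }
  volume_like(v, x)
}
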