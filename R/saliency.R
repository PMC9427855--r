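# Gradient saliency: the magnitude of the exact derivative of the predicted
# Centiloid with respect to each input voxel, computed by backpropagation
# through the trained network at the observed input.

#' Compute a saliency map for one subject
#'
#' Evaluates `|d(prediction) / d(input voxel)|` at the observed input via
#' exact differentiation of the network (no smoothing is applied here).
#' Signed gradients are available with `absolute = FALSE` for sensitivity
#' analyses.
#'
#' @param instance a `taucl_instance` (or an object with an
#'   [input_gradient()] method, such as [affine_model()]).
#' @param v a `taucl_volume` of kind `"scaled"` matching the training grid.
#' @param absolute rectify the gradient sign (default TRUE).
#' @return A `taucl_volume` of kind `"saliency"` with attributes
#'   `subject_grad_signed` (logical) and `fwhm_mm` (`0`, unsmoothed).
#' @export
compute_saliency <- function(instance, v, absolute = TRUE) {
  g <- input_gradient(instance, v)
  if (absolute) g <- abs(g)
  out <- volume_like(v, g, kind = "saliency")
  attr(out, "signed") <- !absolute
  attr(out, "fwhm_mm") <- 0
  out
}

#' Linear surrogate model with a closed-form gradient
#'
#' An affine map `y = sum(w * x) + b` exposed through the same prediction /
#' gradient interface as a trained instance; its input gradient is exactly
#' `w` everywhere, which makes it a convenient reference when validating
#' attribution code.
#'
#' @param w numeric array of weights (the input grid shape).
#' @param b intercept.
#' @return A `taucl_affine_model`.
#' @export
affine_model <- function(w, b = 0) {
  stopifnot(is.array(w), length(dim(w)) == 3L)
  structure(list(w = w, b = b, input_dim = dim(w), target_scale = 1,
                 target_center = 0, fold = 0L),
            class = "taucl_affine_model")
}

#' @rdname input_gradient
#' @export
input_gradient.taucl_affine_model <- function(instance, x) {
  vals <- if (is_volume(x)) x$values else x
  check_same_grid(dim(vals), instance$input_dim, "input and model grids")
  instance$w
}

#' Mask and smooth saliency maps for analysis
#'
#' Each map is masked to the brain and then smoothed with a Gaussian kernel
#' (default 2 mm FWHM); `fwhm_mm = 0` masks only. The applied FWHM is
#' recorded on every map.
#'
#' @param maps a `taucl_volume` or list of them (kind `"saliency"`).
#' @param mask brain mask (atlas, volume or logical array).
#' @param fwhm_mm smoothing kernel FWHM in mm (default 2).
#' @return Prepared map(s), same structure as `maps`.
#' @export
prepare_saliency <- function(maps, mask, fwhm_mm = 2) {
  one <- function(m) {
    stopifnot(is_volume(m))
    out <- apply_mask(m, mask)
    if (fwhm_mm > 0) out <- gaussian_smooth(out, fwhm_mm)
    attr(out, "fwhm_mm") <- fwhm_mm
    attr(out, "signed") <- attr(m, "signed")
    out
  }
  if (is_volume(maps)) one(maps) else lapply(maps, one)
}

#' Saliency stacks for every instance and subject
#'
#' For each trained instance, computes one prepared (masked, smoothed)
#' saliency map per cohort subject, in cohort order.
#'
#' @param cohort cohort table.
#' @param volumes named list of scaled `taucl_volume`s covering every
#'   cohort subject.
#' @param instances list of `taucl_instance`s.
#' @param mask brain mask.
#' @param fwhm_mm smoothing FWHM in mm (default 2).
#' @param absolute rectify gradient signs (default TRUE).
#' @return A list (one element per instance) of lists of prepared maps,
#'   named by subject id.
#' @export
saliency_stack <- function(cohort, volumes, instances, mask, fwhm_mm = 2,
                           absolute = TRUE) {
  missing_ids <- setdiff(cohort$id, names(volumes))
  if (length(missing_ids) > 0)
    stop(sprintf("missing volumes for subjects: %s",
                 paste(missing_ids, collapse = ", ")))
  lapply(instances, function(inst) {
    maps <- lapply(cohort$id, function(id)
      compute_saliency(inst, volumes[[id]], absolute = absolute))
    names(maps) <- cohort$id
    prepare_saliency(maps, mask, fwhm_mm)
  })
}

#' Flatten maps to a subjects-by-voxels matrix over a mask
#'
#' @param maps list of `taucl_volume`s, one per subject (row order kept).
#' @param mask mask selecting the voxels (columns).
#' @return An `n x V` matrix with attribute `mask_index` (linear voxel
#'   indices of the columns).
#' @export
stack_to_matrix <- function(maps, mask) {
  m <- as_mask_array(mask, dim(maps[[1]]$values))
  idx <- which(m)
  Y <- t(vapply(maps, function(v) v$values[idx], numeric(length(idx))))
  attr(Y, "mask_index") <- idx
  Y
}
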