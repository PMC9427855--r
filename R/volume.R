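#' 3D image volume
#'
#' A `taucl_volume` wraps a 3D numeric array together with its voxel size,
#' a voxel-to-mm affine, and a tag saying what the values mean at the current
#' pipeline stage (`SUV`, `scaled`, `SUVR`, `saliency` or `tstat`).
#'
#' @param values numeric 3D array of finite values.
#' @param voxel_size_mm positive voxel edge lengths in mm (length 1 or 3).
#' @param affine 4x4 voxel-to-mm transform; default RAS+ diagonal scaling.
#' @param kind value kind, one of `"SUV"`, `"scaled"`, `"SUVR"`,
#'   `"saliency"`, `"tstat"`.
#' @return A `taucl_volume` object.
#' @export
new_volume <- function(values, voxel_size_mm = 1, affine = NULL,
                       kind = c("SUV", "scaled", "SUVR", "saliency", "tstat")) {
  kind <- match.arg(kind)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  if (!all(is.finite(values)))
    stop("volume values must all be finite")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be positive")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  structure(
    list(values = values, voxel_size_mm = voxel_size_mm,
         affine = affine, kind = kind),
    class = "taucl_volume"
  )
}

#' @export
print.taucl_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<taucl_volume> %dx%dx%d voxels @ %s mm, kind = %s\n",
              d[1], d[2], d[3],
              paste(format(x$voxel_size_mm, trim = TRUE), collapse = "x"),
              x$kind))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.taucl_volume <- function(x) dim(x$values)

is_volume <- function(x) inherits(x, "taucl_volume")

#' Replace the values of a volume, keeping its geometry
#'
#' @param v a `taucl_volume`.
#' @param values replacement array (same shape).
#' @param kind optional new value kind.
#' @return A `taucl_volume` with the same voxel size and affine.
#' @export
volume_like <- function(v, values, kind = v$kind) {
  stopifnot(is_volume(v))
  if (!identical(dim(values), dim(v$values)))
    stop("replacement values have a different shape")
  new_volume(values, voxel_size_mm = v$voxel_size_mm, affine = v$affine,
             kind = kind)
}

check_same_grid <- function(a_dim, b_dim, what = "grids") {
  if (!identical(as.integer(a_dim), as.integer(b_dim)))
    stop(sprintf("%s do not agree: %s vs %s", what,
                 paste(a_dim, collapse = "x"), paste(b_dim, collapse = "x")))
  invisible(TRUE)
}

#' Write a volume to a NIfTI-1 file
#'
#' @param v a `taucl_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(is_volume(v))
  img <- RNifti::asNifti(v$values)
  img <- RNifti::`sform<-`(img, structure(v$affine, code = 2L))
  RNifti::pixdim(img) <- v$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from a NIfTI-1 file
#'
#' @param path path to a NIfTI file.
#' @param kind value kind to tag the volume with.
#' @return A `taucl_volume`.
#' @export
read_volume <- function(path, kind = "SUV") {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  aff <- structure(RNifti::xform(img), code = NULL)
  new_volume(vals, voxel_size_mm = RNifti::pixdim(img)[1:3],
             affine = matrix(as.numeric(aff), 4, 4), kind = kind)
}
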