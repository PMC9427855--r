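# Synthetic phantom generator.
#
# Emulates the statistical structure the downstream analysis assumes: a cohort
# with a continuous amyloid Centiloid (CL) covariate, and 3D volumes in which
# a "fronto-parietal/cingulate-like" (FPC-like) region tracks CL mainly below
# a changepoint, two "medial-temporal-like" (MT-like) regions track CL mainly
# above it, and other regions carry no CL signal. The informativeness
# crossover near CL = 25 is planted analytically so it can be recovered by
# the saliency / occlusion analyses and checked against the construction.

#' Configuration for the synthetic phantom cohort
#'
#' Defaults define the reference desk-scale study conditions: a 32x40x32 grid
#' at 2 mm, 150 subjects with CL uniform on \[-10, 140\], an informativeness
#' changepoint at CL = 25, and Gaussian voxel noise.
#'
#' @param grid_shape three positive integers, the volume grid (voxels).
#' @param voxel_size_mm positive voxel edge length in mm.
#' @param n_subjects number of subjects in the cohort.
#' @param cl_low,cl_high bounds of the cohort Centiloid distribution
#'   (CL is drawn uniformly between them).
#' @param changepoint_cl Centiloid value at which regional informativeness
#'   crosses over; also the descriptive amyloid-positivity threshold.
#' @param effect_low_region amplitude (SUV) of the low-CL ("FPC-like")
#'   regional effect.
#' @param effect_high_region amplitude (SUV) of the high-CL ("MT-like")
#'   regional effect.
#' @param noise_sd voxel-wise Gaussian noise standard deviation (SUV).
#' @param baseline in-mask baseline intensity (SUV).
#' @param offtarget_amplitude amplitude (SUV) of the CL-independent
#'   off-target high-uptake region (meninges-like tracer binding). Pinning
#'   the image maximum to a CL-independent structure keeps per-image min-max
#'   scaling from leaking CL information into every background voxel.
#' @param logistic_tau_cl scale (CL units) of the sigmoidal high-CL ramp
#'   `g_high` (a normalized smooth hinge whose derivative is the logistic
#'   sigmoid): below the changepoint the ramp is nearly flat, above it the
#'   ramp rises nearly linearly to 1 at `cl_high`. This keeps the MT-like
#'   regions uninformative at low CL (so the FPC-like region dominates
#'   there) while leaving the full upper CL range identifiable from the
#'   volumes.
#' @param age_mean,age_sd cohort age distribution (years).
#' @param sex_p probability a subject is female.
#' @param prop_validation,prop_test split proportions; the remainder trains.
#' @param seed master seed for cohort sampling and volume noise.
#' @return A `taucl_synth_config` list.
#' @export
synthetic_config <- function(grid_shape = c(32L, 40L, 32L),
                             voxel_size_mm = 2,
                             n_subjects = 150L,
                             cl_low = -10, cl_high = 140,
                             changepoint_cl = 25,
                             effect_low_region = 0.4,
                             effect_high_region = 0.8,
                             noise_sd = 0.1,
                             baseline = 1.0,
                             offtarget_amplitude = 2.0,
                             logistic_tau_cl = 5,
                             age_mean = 71, age_sd = 7.7,
                             sex_p = 0.5,
                             prop_validation = 12 / 134,
                             prop_test = 13 / 134,
                             seed = 20260101L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0L),
            voxel_size_mm > 0, n_subjects >= 0,
            cl_low < cl_high,
            changepoint_cl >= cl_low, changepoint_cl <= cl_high,
            effect_low_region >= 0, effect_high_region >= 0,
            noise_sd >= 0, baseline >= 0, offtarget_amplitude >= 0,
            logistic_tau_cl > 0,
            sex_p >= 0, sex_p <= 1,
            prop_validation >= 0, prop_test >= 0,
            prop_validation + prop_test < 1)
  structure(
    list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
         n_subjects = as.integer(n_subjects),
         cl_low = cl_low, cl_high = cl_high,
         changepoint_cl = changepoint_cl,
         effect_low_region = effect_low_region,
         effect_high_region = effect_high_region,
         noise_sd = noise_sd, baseline = baseline,
         offtarget_amplitude = offtarget_amplitude,
         logistic_tau_cl = logistic_tau_cl,
         age_mean = age_mean, age_sd = age_sd, sex_p = sex_p,
         prop_validation = prop_validation, prop_test = prop_test,
         seed = as.integer(seed)),
    class = "taucl_synth_config"
  )
}

# CL response ramps. g_low saturates at the changepoint (informative below
# it); g_high is a sigmoidal ramp hinged at the changepoint (flat below,
# near-linear above, informative across the whole upper CL range). Both map
# CL to [0, 1].

#' @rdname cl_ramps
#' @param cl Centiloid value(s).
#' @param config a `taucl_synth_config`.
#' @export
g_low <- function(cl, config) {
  pmin(1, pmax(0, (cl - config$cl_low) /
                 (config$changepoint_cl - config$cl_low)))
}

#' Planted Centiloid response ramps
#'
#' `g_low` is a linear ramp saturating at the changepoint; `g_high` is a
#' sigmoidal ramp hinged at the changepoint: a softplus
#' `log(1 + exp((cl - changepoint) / tau))` (whose derivative is the
#' logistic sigmoid with scale `logistic_tau_cl`), shifted to 0 at `cl_low`
#' and normalized to 1 at `cl_high`. It is nearly flat below the
#' changepoint and nearly linear above it.
#' @name cl_ramps
#' @rdname cl_ramps
#' @export
g_high <- function(cl, config) {
  sp <- function(z) log1p(exp(-abs(z))) + pmax(z, 0)   # stable softplus
  u <- function(v) sp((v - config$changepoint_cl) / config$logistic_tau_cl)
  (u(cl) - u(config$cl_low)) / (u(config$cl_high) - u(config$cl_low))
}

default_region_table <- function() {
  # centers as fractions of the grid, radii as fractions of the smallest
  # grid dimension; painted as spheres inside an ellipsoidal brain mask
  data.frame(
    label  = 1:7,
    name   = c("cerebellar-ref", "fpc-like", "mt-left", "mt-right",
               "occipital-null", "frontal-null", "meninges-like"),
    role   = c("reference", "effect_low", "effect_high_left",
               "effect_high_right", "null", "null", "offtarget"),
    cx = c(0.50, 0.50, 0.30, 0.70, 0.50, 0.72, 0.50),
    cy = c(0.30, 0.62, 0.45, 0.45, 0.80, 0.68, 0.34),
    cz = c(0.38, 0.70, 0.38, 0.38, 0.42, 0.52, 0.82),
    r  = c(0.125, 0.155, 0.125, 0.125, 0.115, 0.115, 0.08),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic atlas
#'
#' Builds an ellipsoidal brain mask on the configured grid and paints seven
#' disjoint spherical regions into it: a cerebellar-like reference region, a
#' low-CL effect region (FPC-like), left and right high-CL effect regions
#' (MT-like), two null regions, and a CL-independent off-target high-uptake
#' region (meninges-like). Deterministic given the config.
#'
#' @param config a `taucl_synth_config`.
#' @param regions optional region table overriding the default layout
#'   (columns `label`, `name`, `role`, fractional centers `cx`, `cy`, `cz`
#'   and fractional radius `r`).
#' @return A `taucl_atlas`: list with integer `labels` array, logical `mask`
#'   array, `name_map` data frame and the config's voxel size.
#' @export
generate_atlas <- function(config, regions = default_region_table()) {
  gs <- config$grid_shape
  if (any(gs < 16L))
    stop("grid too small: each dimension must be at least 16 voxels")
  ax <- seq_len(gs[1]); ay <- seq_len(gs[2]); az <- seq_len(gs[3])
  ctr <- (gs + 1) / 2
  semi <- gs * 0.44
  # ellipsoidal brain mask
  dx2 <- ((ax - ctr[1]) / semi[1])^2
  dy2 <- ((ay - ctr[2]) / semi[2])^2
  dz2 <- ((az - ctr[3]) / semi[3])^2
  mask <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
  labels <- array(0L, gs)
  rmin <- min(gs)
  for (i in seq_len(nrow(regions))) {
    reg <- regions[i, ]
    cc <- c(reg$cx, reg$cy, reg$cz) * gs
    rad <- reg$r * rmin
    sx <- ((ax - cc[1]))^2; sy <- ((ay - cc[2]))^2; sz <- ((az - cc[3]))^2
    inside <- outer(outer(sx, sy, `+`), sz, `+`) <= rad^2
    if (!any(inside))
      stop(sprintf("grid too small to place region '%s'", reg$name))
    if (any(inside & !mask))
      stop(sprintf("region '%s' extends outside the brain mask", reg$name))
    if (any(labels[inside] != 0L))
      stop(sprintf("region '%s' overlaps a previously placed region",
                   reg$name))
    labels[inside] <- as.integer(reg$label)
  }
  structure(
    list(labels = labels, mask = mask,
         name_map = regions[, c("label", "name", "role")],
         voxel_size_mm = config$voxel_size_mm),
    class = "taucl_atlas"
  )
}

#' @export
print.taucl_atlas <- function(x, ...) {
  cat(sprintf("<taucl_atlas> %s voxels, %d in-mask, %d regions\n",
              paste(dim(x$labels), collapse = "x"), sum(x$mask),
              nrow(x$name_map)))
  print(cbind(x$name_map, voxels = tabulate(x$labels,
                                            nbins = max(x$name_map$label))))
  invisible(x)
}

# label vector for a role (possibly several labels, e.g. both MT regions)
atlas_labels_for_role <- function(atlas, role) {
  labs <- atlas$name_map$label[grepl(role, atlas$name_map$role)]
  if (length(labs) == 0L) stop(sprintf("no atlas region with role '%s'", role))
  labs
}

#' Logical mask of the atlas regions filling a role
#'
#' @param atlas a `taucl_atlas`.
#' @param role role string matched against the atlas `name_map` roles
#'   (e.g. `"effect_high"` matches both left and right MT-like regions).
#' @return Logical array of the atlas grid shape.
#' @export
atlas_role_mask <- function(atlas, role) {
  array(atlas$labels %in% atlas_labels_for_role(atlas, role),
        dim(atlas$labels))
}

#' Sample a synthetic cohort
#'
#' Draws per-subject Centiloid (uniform on the configured bounds), age
#' (normal) and sex (Bernoulli), and assigns train / validation / test splits
#' by the configured proportions. Reproducible from the config seed.
#'
#' @param config a `taucl_synth_config`.
#' @return A data frame with columns `id`, `cl`, `age`, `sex`, `split`,
#'   `fold` (fold is `NA` until a fold plan is made).
#' @export
sample_cohort <- function(config) {
  n <- config$n_subjects
  if (n == 0L) {
    return(data.frame(id = character(), cl = numeric(), age = numeric(),
                      sex = character(), split = character(),
                      fold = integer(), stringsAsFactors = FALSE))
  }
  with_seed(derive_seed(config$seed, "cohort"), {
    cl <- stats::runif(n, config$cl_low, config$cl_high)
    age <- stats::rnorm(n, config$age_mean, config$age_sd)
    sex <- ifelse(stats::runif(n) < config$sex_p, "F", "M")
    n_test <- round(config$prop_test * n)
    n_val <- round(config$prop_validation * n)
    if (n_test + n_val > n) stop("split proportions exceed the cohort size")
    split <- rep("train", n)
    idx <- sample.int(n)
    split[idx[seq_len(n_test)]] <- "test"
    if (n_val > 0) split[idx[n_test + seq_len(n_val)]] <- "validation"
    data.frame(
      id = sprintf("sub-%03d", seq_len(n)),
      cl = cl, age = age, sex = sex, split = split,
      fold = NA_integer_, stringsAsFactors = FALSE
    )
  })
}

#' Render one subject's phantom volume
#'
#' In-mask voxel values are
#' `baseline + effect_low_region * g_low(cl)` in the FPC-like region,
#' `baseline + effect_high_region * g_high(cl)` in the MT-like regions,
#' `baseline + offtarget_amplitude` in the off-target region (independent of
#' CL; this pins the image maximum so per-image min-max scaling carries no
#' CL information), `baseline` elsewhere, plus Gaussian noise truncated at
#' zero; out-of-mask voxels are exactly zero. The per-subject noise stream
#' is derived from `(config$seed, subject id)` so any volume can be
#' regenerated on its own.
#'
#' @param subject one row of a cohort table (needs `id` and `cl`).
#' @param atlas a `taucl_atlas` on the config grid.
#' @param config the `taucl_synth_config` used for the atlas.
#' @return A `taucl_volume` of kind `"SUV"`.
#' @export
render_volume <- function(subject, atlas, config) {
  check_same_grid(dim(atlas$labels), config$grid_shape,
                  "atlas and config grids")
  cl <- subject$cl
  gs <- config$grid_shape
  vals <- array(0, gs)
  vals[atlas$mask] <- config$baseline
  add_effect <- function(vals, role, amount) {
    # custom atlases may omit a role; absent roles simply contribute nothing
    if (amount != 0 && any(grepl(role, atlas$name_map$role))) {
      m <- atlas_role_mask(atlas, role)
      vals[m] <- vals[m] + amount
    }
    vals
  }
  vals <- add_effect(vals, "effect_low",
                     config$effect_low_region * g_low(cl, config))
  vals <- add_effect(vals, "effect_high",
                     config$effect_high_region * g_high(cl, config))
  vals <- add_effect(vals, "offtarget", config$offtarget_amplitude)
  if (config$noise_sd > 0) {
    noise <- with_seed(
      derive_seed(config$seed, paste0("volume/", subject$id)),
      stats::rnorm(sum(atlas$mask), 0, config$noise_sd)
    )
    vals[atlas$mask] <- vals[atlas$mask] + noise
  }
  vals[vals < 0] <- 0
  vals[!atlas$mask] <- 0
  new_volume(vals, voxel_size_mm = config$voxel_size_mm, kind = "SUV")
}

#' Render all volumes of a cohort
#'
#' @param cohort a cohort table from [sample_cohort()].
#' @param atlas a `taucl_atlas`.
#' @param config the matching `taucl_synth_config`.
#' @return A named list of `taucl_volume`s, in cohort order.
#' @export
render_cohort_volumes <- function(cohort, atlas, config) {
  vols <- lapply(seq_len(nrow(cohort)), function(i)
    render_volume(cohort[i, ], atlas, config))
  names(vols) <- cohort$id
  vols
}

#' Write a synthetic dataset to disk
#'
#' Writes one NIfTI-1 volume per subject plus the atlas, the cohort as TSV,
#' and a JSON manifest listing every file with its MD5 checksum.
#'
#' @param cohort cohort table.
#' @param volumes named list of `taucl_volume`s, one per subject.
#' @param atlas a `taucl_atlas`.
#' @param out_dir output directory (created if missing).
#' @return The manifest as a data frame (`file`, `kind`, `md5`), invisibly
#'   written to `manifest.json`.
#' @export
write_dataset <- function(cohort, volumes, atlas, out_dir) {
  if (!setequal(names(volumes), cohort$id) ||
      length(volumes) != nrow(cohort))
    stop("need exactly one volume per cohort subject")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0); kinds <- character(0)
  for (id in cohort$id) {
    f <- file.path(out_dir, paste0("vol_", id, ".nii.gz"))
    write_volume(volumes[[id]], f)
    files <- c(files, f); kinds <- c(kinds, "volume")
  }
  atlas_vol <- new_volume(array(as.numeric(atlas$labels), dim(atlas$labels)),
                          voxel_size_mm = atlas$voxel_size_mm, kind = "SUV")
  fa <- file.path(out_dir, "atlas.nii.gz")
  write_volume(atlas_vol, fa)
  files <- c(files, fa); kinds <- c(kinds, "atlas")
  ft <- file.path(out_dir, "cohort.tsv")
  utils::write.table(cohort, ft, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  missing <- !file.exists(c(files, ft))
  if (any(missing))
    stop(sprintf("failed to write: %s",
                 paste(c(files, ft)[missing], collapse = ", ")))
  # one manifest row per image (volumes + atlas); the cohort table is
  # recorded alongside with its own checksum
  manifest <- data.frame(file = basename(files), kind = kinds,
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(
    list(files = manifest,
         cohort = list(file = basename(ft),
                       md5 = unname(tools::md5sum(ft)))),
    file.path(out_dir, "manifest.json"),
    dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
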