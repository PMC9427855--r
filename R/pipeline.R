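# Configuration-driven end-to-end runs: generate -> preprocess -> CV-train ->
# saliency -> GLM -> occlusion, with a single master seed fanning out to
# named per-stage sub-seeds and a run report collecting the headline tables.

#' Assemble a pipeline configuration
#'
#' Nested module configurations plus the analysis thresholds, all defaulted
#' to the reference study conditions (FWE alpha 0.05, 200-voxel extent at
#' 1 mm scaled to the working voxel size, 2 mm saliency smoothing, Abeta
#' positivity / changepoint at CL 25). The master seed derives the
#' generator, fold and permutation seeds so stages are individually
#' re-runnable.
#'
#' @param seed master seed.
#' @param synth `taucl_synth_config` (default: desk-scale phantom with its
#'   seed derived from `seed`).
#' @param cnn `taucl_cnn_config` (its seed is derived from `seed` unless
#'   supplied explicitly).
#' @param K number of cross-validation folds.
#' @param alpha family-wise error level for the saliency / SUVR GLMs.
#' @param n_perm permutations for the maxT threshold.
#' @param extent_1mm cluster extent criterion in voxels at 1 mm isotropic.
#' @param fwhm_mm saliency smoothing FWHM (mm).
#' @param connectivity cluster connectivity (6, 18 or 26).
#' @param tail `"two.sided"` (default) or `"positive"` contrast tail for
#'   cluster detection.
#' @param span LOESS span for strength-of-association curves. The default
#'   0.3 gives a smoothing bandwidth narrow enough to resolve changes on
#'   the ~20 CL scale of the planted changepoint.
#' @param global global-signal handling for the saliency GLM:
#'   `"proportional"` (default) divides each subject's map by its in-mask
#'   mean before the fit -- gradient maps carry an arbitrary per-subject
#'   scale whose covariation with CL both inflates null-region
#'   associations and can cancel true regional ones; `"ancova"` adds the
#'   in-mask mean as a nuisance covariate; `"none"` fits raw values.
#' @param fill occlusion fill policy: `"tau_naive"` (default; voxel-wise
#'   mean over the lowest-CL decile, i.e. a no-pathology template, so
#'   occlusion erases disease-related information while staying on the
#'   data manifold), `"abneg_mean"` (mean over amyloid-negative subjects),
#'   `"cohort_mean"`, or a numeric fill value such as 0.
#' @param stages character vector of stages to run, a subset of
#'   `c("generate", "preprocess", "train", "saliency", "glm", "occlusion")`.
#' @param out_dir optional output directory for artifacts (NIfTI t-maps,
#'   cluster labels, TSV tables); `NULL` keeps everything in memory.
#' @return A `taucl_pipeline_config`.
#' @export
pipeline_config <- function(seed = 42L,
                            synth = NULL, cnn = NULL, K = 3L,
                            alpha = 0.05, n_perm = 499L,
                            extent_1mm = 200L, fwhm_mm = 2,
                            connectivity = 26L,
                            tail = c("two.sided", "positive"),
                            span = 0.3,
                            global = c("proportional", "ancova", "none"),
                            fill = "tau_naive",
                            stages = c("generate", "preprocess", "train",
                                       "saliency", "glm", "occlusion"),
                            out_dir = NULL) {
  tail <- match.arg(tail)
  global <- match.arg(global)
  if (is.null(synth)) synth <- synthetic_config(seed = derive_seed(seed, "synth"))
  if (is.null(cnn)) cnn <- cnn_config(seed = derive_seed(seed, "cnn"))
  stopifnot(inherits(synth, "taucl_synth_config"),
            inherits(cnn, "taucl_cnn_config"),
            K >= 1, alpha > 0, alpha <= 1, n_perm >= 100,
            is.null(out_dir) || is.character(out_dir))
  bad <- setdiff(stages, c("generate", "preprocess", "train", "saliency",
                           "glm", "occlusion"))
  if (length(bad) > 0)
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  structure(
    list(seed = as.integer(seed), synth = synth, cnn = cnn, K = as.integer(K),
         alpha = alpha, n_perm = as.integer(n_perm),
         extent_1mm = as.integer(extent_1mm), fwhm_mm = fwhm_mm,
         connectivity = as.integer(connectivity), tail = tail,
         span = span, global = global, fill = fill, stages = stages,
         out_dir = out_dir),
    class = "taucl_pipeline_config"
  )
}

resolve_fill <- function(fill, X, cl, threshold) {
  if (identical(fill, "tau_naive")) {
    k <- max(5L, ceiling(0.1 * length(cl)))
    rowMeans(X[, order(cl)[seq_len(k)], drop = FALSE])
  } else if (identical(fill, "abneg_mean")) {
    neg <- cl < threshold
    if (!any(neg)) stop("no amyloid-negative subjects for the fill template")
    rowMeans(X[, neg, drop = FALSE])
  } else if (identical(fill, "cohort_mean")) {
    rowMeans(X)
  } else {
    as.numeric(fill)
  }
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order, halting with an
#' informative error if a stage's inputs are missing (e.g. occlusion without
#' the GLM's clusters). Deterministic given the configuration.
#'
#' @param config a `taucl_pipeline_config`.
#' @param verbose print stage progress.
#' @return A `taucl_report`: per-stage status and timing, per-fold metrics,
#'   the best instance, cluster sets, occlusion tables and
#'   strength-of-association curves.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "taucl_pipeline_config"))
  st <- list(); res <- list(config = config)
  tick <- function(name, code) {
    t0 <- proc.time()[3]
    out <- code
    st[[name]] <<- list(status = "ok", seconds = unname(proc.time()[3] - t0))
    if (verbose) message(sprintf("[%s] done in %.1fs", name, st[[name]]$seconds))
    out
  }
  need <- function(what, stage, from) {
    if (is.null(what))
      stop(sprintf("stage '%s' requires outputs of stage '%s', which did not run",
                   stage, from))
    what
  }
  on <- function(s) s %in% config$stages

  if (on("generate")) {
    res$atlas <- tick("generate", {
      atlas <- generate_atlas(config$synth)
      res$cohort <- sample_cohort(config$synth)
      res$volumes <- render_cohort_volumes(res$cohort, atlas, config$synth)
      atlas
    })
  }
  if (on("preprocess")) {
    res$X <- tick("preprocess", {
      atlas <- need(res$atlas, "preprocess", "generate")
      res$scaled <- lapply(need(res$volumes, "preprocess", "generate"),
                            minmax_scale, mask = atlas)
      res$suvr <- lapply(res$volumes, compute_suvr, atlas = atlas)
      as_input_matrix(res$scaled)
    })
  }
  if (on("train")) {
    res$instances <- tick("train", {
      X <- need(res$X, "train", "preprocess")
      res$plan <- make_folds(res$cohort, K = config$K,
                              seed = derive_seed(config$seed, "folds"))
      instances <- train_cv(X, res$cohort, res$plan, config$cnn,
                            verbose = verbose)
      res$best <- select_best_instance(instances)
      instances
    })
  }
  if (on("saliency")) {
    res$saliency <- tick("saliency", {
      insts <- need(res$instances, "saliency", "train")
      saliency_stack(res$cohort, res$scaled, insts, res$atlas,
                     fwhm_mm = config$fwhm_mm)
    })
  }
  if (on("glm")) {
    res$glm <- tick("glm", {
      maps <- need(res$saliency, "glm", "saliency")
      atlas <- res$atlas
      design <- make_design(res$cohort)
      extent <- scale_extent(config$extent_1mm, config$synth$voxel_size_mm)
      run_glm <- function(Y, label, seed_key, global = "none") {
        dsg <- design
        if (identical(global, "proportional")) {
          Y <- Y / rowMeans(Y)
        } else if (identical(global, "ancova")) {
          dsg <- cbind(design, global_mean = rowMeans(Y))
          attr(dsg, "focus") <- attr(design, "focus")
        }
        thr <- fwe_threshold(Y, dsg, alpha = config$alpha,
                             n_perm = config$n_perm,
                             seed = derive_seed(config$seed, seed_key),
                             tail = config$tail)
        fit <- fit_voxelwise_glm(Y, dsg)
        tarr <- array(0, dim(atlas$labels))
        tarr[attr(Y, "mask_index")] <- fit$tstat
        list(threshold = thr, fit = fit,
             tmap = new_volume(tarr, config$synth$voxel_size_mm,
                               kind = "tstat"),
             clusters = threshold_and_cluster(
               tarr, thr, min_extent = extent,
               connectivity = config$connectivity, tail = config$tail,
               atlas = atlas))
      }
      best_idx <- res$best$fold
      sal_sets <- lapply(seq_along(maps), function(i)
        run_glm(stack_to_matrix(maps[[i]], atlas),
                sprintf("glm/saliency/%d", i), sprintf("perm/sal/%d", i),
                global = config$global))
      suvr_Y <- stack_to_matrix(res$suvr, atlas)
      list(saliency = sal_sets, best_saliency = sal_sets[[best_idx]],
           suvr = run_glm(suvr_Y, "glm/suvr", "perm/suvr"),
           consistency = if (length(sal_sets) >= 2)
             cluster_consistency(lapply(sal_sets, `[[`, "clusters")))
    })
  }
  if (on("occlusion")) {
    res$occlusion <- tick("occlusion", {
      glm_out <- need(res$glm, "occlusion", "glm")
      X <- res$X
      cs <- glm_out$best_saliency$clusters
      fill <- resolve_fill(config$fill, X, res$cohort$cl,
                           config$synth$changepoint_cl)
      col_of <- stats::setNames(seq_len(nrow(res$cohort)), res$cohort$id)
      bf <- res$plan$folds[[res$best$fold]]
      splits <- list(train = unname(col_of[bf$train]),
                     validation = unname(col_of[bf$validation]),
                     test = unname(col_of[res$plan$test]))
      per_cluster <- lapply(cs$clusters, function(cl) {
        m <- array(FALSE, cs$grid); m[cl$voxels] <- TRUE
        occlusion_r2(res$best, X, res$cohort$cl, splits, m, fill = fill)
      })
      all_mask <- cluster_mask(cs)
      occ_all <- occlusion_r2(res$best, X, res$cohort$cl, splits, all_mask,
                              fill = fill)
      curves <- lapply(cs$clusters, function(cl) {
        m <- array(FALSE, cs$grid); m[cl$voxels] <- TRUE
        strength_of_association(res$instances, X, res$cohort$cl, m,
                                span = config$span, fill = fill)
      })
      list(per_cluster = per_cluster, all_clusters = occ_all,
           curves = curves)
    })
  }

  res$stages <- st
  report <- structure(res, class = "taucl_report")
  if (!is.null(config$out_dir)) write_report_artifacts(report)
  report
}

instance_metric_table <- function(instances) {
  do.call(rbind, lapply(instances, function(it) data.frame(
    fold = it$fold, best_epoch = it$best_epoch,
    rmse_train = it$rmse_train, rmse_val = it$rmse_val,
    rmse_test = it$rmse_test %||% NA_real_,
    r2_train = it$r2_train, r2_val = it$r2_val,
    r2_test = it$r2_test %||% NA_real_)))
}

cluster_table <- function(cs, voxel_size_mm = 1) {
  if (length(cs$clusters) == 0)
    return(data.frame(id = integer(), size_voxels = integer(),
                      peak_t = numeric(), centroid_mm = character(),
                      top_regions = character()))
  do.call(rbind, lapply(cs$clusters, function(cl) data.frame(
    id = cl$id, size_voxels = cl$size, peak_t = cl$peak_t,
    centroid_mm = paste(round(cl$centroid_vox * voxel_size_mm, 1),
                        collapse = ","),
    top_regions = if (!is.null(cl$composition))
      paste(utils::head(names(sort(cl$composition, decreasing = TRUE)), 3),
            collapse = ";") else "")))
}

#' Render a human-readable run summary
#'
#' @param report a `taucl_report` from [run_pipeline()].
#' @return Character vector of markdown lines (also printed by the
#'   `print` method).
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "taucl_report"))
  lines <- c("# taucl pipeline report", "")
  if (length(report$stages) == 0) {
    return(c(lines, "No stages were executed."))
  }
  lines <- c(lines, "## Stages", vapply(names(report$stages), function(nm)
    sprintf("- %s: %s (%.1fs)", nm, report$stages[[nm]]$status,
            report$stages[[nm]]$seconds), character(1)), "")
  if (!is.null(report$instances)) {
    tb <- instance_metric_table(report$instances)
    lines <- c(lines, "## Cross-validation instances",
               paste(utils::capture.output(print(tb, row.names = FALSE)),
                     collapse = "\n"),
               sprintf("Best instance: fold %d (mean of val/test RMSE %.2f)",
                       report$best$fold,
                       mean(c(report$best$rmse_val, report$best$rmse_test))),
               "")
  }
  if (!is.null(report$glm)) {
    vs <- report$config$synth$voxel_size_mm
    lines <- c(lines, "## Saliency GLM clusters (best instance)",
               paste(utils::capture.output(print(
                 cluster_table(report$glm$best_saliency$clusters, vs),
                 row.names = FALSE)), collapse = "\n"), "")
    if (!is.null(report$glm$consistency)) {
      d <- report$glm$consistency$dice
      lines <- c(lines, sprintf(
        "Cross-instance cluster Dice: mean %.2f (range %.2f-%.2f)",
        mean(d[upper.tri(d)]), min(d[upper.tri(d)]), max(d[upper.tri(d)])), "")
    }
  }
  if (!is.null(report$occlusion)) {
    occ <- report$occlusion
    rows <- lapply(seq_along(occ$per_cluster), function(i) {
      tb <- occ$per_cluster[[i]]$table
      data.frame(cluster = as.character(i),
                 r2_train = tb$r2_post[tb$split == "train"],
                 r2_val = tb$r2_post[tb$split == "validation"],
                 r2_test = tb$r2_post[tb$split == "test"])
    })
    tb <- occ$all_clusters$table
    rows <- c(list(data.frame(cluster = "all",
                              r2_train = tb$r2_post[tb$split == "train"],
                              r2_val = tb$r2_post[tb$split == "validation"],
                              r2_test = tb$r2_post[tb$split == "test"])),
              rows)
    base <- occ$all_clusters$table
    lines <- c(lines, "## Post-occlusion out-of-sample R^2",
               sprintf("Baseline R^2 (train/val/test): %.2f / %.2f / %.2f",
                       base$r2_baseline[base$split == "train"],
                       base$r2_baseline[base$split == "validation"],
                       base$r2_baseline[base$split == "test"]),
               paste(utils::capture.output(
                 print(do.call(rbind, rows), row.names = FALSE)),
                 collapse = "\n"), "")
  }
  lines
}

#' @export
print.taucl_report <- function(x, ...) {
  cat(paste(render_report(x), collapse = "\n"), "\n")
  invisible(x)
}

write_report_artifacts <- function(report) {
  out <- report$config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  add <- function(f) files <<- c(files, f)
  if (!is.null(report$cohort)) {
    f <- file.path(out, "cohort.tsv")
    utils::write.table(report$cohort, f, sep = "\t", quote = FALSE,
                       row.names = FALSE); add(f)
  }
  if (!is.null(report$instances)) {
    f <- file.path(out, "instance_metrics.tsv")
    utils::write.table(instance_metric_table(report$instances), f,
                       sep = "\t", quote = FALSE, row.names = FALSE); add(f)
  }
  if (!is.null(report$glm)) {
    f <- file.path(out, "saliency_tmap_best.nii.gz")
    write_volume(report$glm$best_saliency$tmap, f); add(f)
    f <- file.path(out, "saliency_clusters_best.tsv")
    utils::write.table(cluster_table(report$glm$best_saliency$clusters,
                                     report$config$synth$voxel_size_mm),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    add(f)
  }
  if (!is.null(report$occlusion)) {
    occ <- report$occlusion
    rows <- do.call(rbind, c(
      lapply(seq_along(occ$per_cluster), function(i)
        cbind(cluster = i, occ$per_cluster[[i]]$table)),
      list(cbind(cluster = "all", occ$all_clusters$table))))
    f <- file.path(out, "occlusion_r2.tsv")
    utils::write.table(rows, f, sep = "\t", quote = FALSE,
                       row.names = FALSE); add(f)
    curves <- do.call(rbind, lapply(seq_along(occ$curves), function(i) {
      cv <- occ$curves[[i]]
      data.frame(cluster = i, grid_cl = cv$grid, mean = cv$mean,
                 sem = cv$sem)
    }))
    f <- file.path(out, "strength_curves.tsv")
    utils::write.table(curves, f, sep = "\t", quote = FALSE,
                       row.names = FALSE); add(f)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(files)
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' The file may set any scalar argument of [pipeline_config()] plus nested
#' `synth` and `cnn` blocks whose entries are passed to
#' [synthetic_config()] and [cnn_config()].
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `taucl_pipeline_config`.
#' @export
pipeline_config_from_file <- function(path) {
  spec <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  seed <- spec$seed %||% 42L
  synth <- if (!is.null(spec$synth)) {
    spec$synth$seed <- spec$synth$seed %||% derive_seed(seed, "synth")
    do.call(synthetic_config, spec$synth)
  }
  cnn <- if (!is.null(spec$cnn)) {
    spec$cnn$seed <- spec$cnn$seed %||% derive_seed(seed, "cnn")
    do.call(cnn_config, spec$cnn)
  }
  rest <- spec[setdiff(names(spec), c("synth", "cnn", "seed"))]
  do.call(pipeline_config,
          c(list(seed = seed, synth = synth, cnn = cnn), rest))
}
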