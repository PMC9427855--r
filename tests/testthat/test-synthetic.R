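test_that("atlas generation is deterministic and places disjoint in-mask regions", {
  cfg <- tiny_config()
  a1 <- generate_atlas(cfg)
  a2 <- generate_atlas(cfg)
  expect_identical(a1$labels, a2$labels)
  expect_true(all(a1$labels[!a1$mask] == 0L))
  # all roles present and nonempty
  for (role in c("reference", "effect_low", "effect_high", "null",
                 "offtarget")) {
    expect_gt(sum(atlas_role_mask(generate_atlas(synthetic_config()), role)),
              0)
  }
})

test_that("region voxel counts match a brute-force sphere enumeration", {
  cfg <- tiny_config()
  regions <- tiny_atlas_regions()
  at <- generate_atlas(cfg, regions)
  # brute-force voxel count for each sphere
  gs <- cfg$grid_shape
  vox <- as.matrix(expand.grid(x = seq_len(gs[1]), y = seq_len(gs[2]),
                               z = seq_len(gs[3])))
  for (i in 1:2) {
    cc <- as.numeric(regions[i, c("cx", "cy", "cz")]) * gs
    rad <- regions$r[i] * min(gs)
    expected <- sum(colSums((t(vox) - cc)^2) <= rad^2)
    expect_equal(sum(at$labels == regions$label[i]), expected)
  }
})

test_that("atlas errors name the failing region", {
  cfg <- tiny_config()
  bad <- tiny_atlas_regions()
  bad$cy[2] <- 0.02  # sphere pokes outside the ellipsoid mask
  expect_error(generate_atlas(cfg, bad), "b")
  expect_error(generate_atlas(synthetic_config(grid_shape = c(8, 8, 8))),
               "grid too small")
})

test_that("cohort sampling: schema, determinism, empty case, split sizes", {
  cfg <- tiny_config()
  co <- sample_cohort(cfg)
  expect_identical(names(co), c("id", "cl", "age", "sex", "split", "fold"))
  expect_equal(nrow(co), cfg$n_subjects)
  expect_false(any(duplicated(co$id)))
  expect_true(all(is.finite(co$cl)))
  expect_true(all(co$split %in% c("train", "validation", "test")))
  expect_identical(co, sample_cohort(cfg))
  empty <- sample_cohort(synthetic_config(n_subjects = 0L))
  expect_equal(nrow(empty), 0L)
  expect_identical(names(empty), names(co))
  # paper-proportioned splits at n = 134 reproduce 109/12/13
  co134 <- sample_cohort(synthetic_config(n_subjects = 134L))
  expect_equal(as.integer(table(co134$split)[c("train", "validation",
                                               "test")]),
               c(109L, 12L, 13L))
})

test_that("uniform CL above the positivity threshold matches the closed form", {
  # P(CL > 25 | U(-10, 140)) = 115/150
  cfg <- synthetic_config(n_subjects = 5000L, seed = 7L)
  co <- sample_cohort(cfg)
  p <- 115 / 150
  frac <- mean(co$cl > 25)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 5000))
})

test_that("rendered volumes follow the planted generative formula", {
  cfg <- tiny_config(noise_sd = 0, effect_low_region = 0,
                     effect_high_region = 0, offtarget_amplitude = 0)
  at <- generate_atlas(cfg, tiny_atlas_regions())
  co <- sample_cohort(cfg)
  v <- render_volume(co[1, ], at, cfg)
  expect_true(all(v$values[at$mask] == cfg$baseline))
  expect_true(all(v$values[!at$mask] == 0))

  # saturated high ramp: mean in effect region = baseline + amplitude
  cfg2 <- tiny_config(noise_sd = 0, effect_low_region = 0,
                      effect_high_region = 0.5, offtarget_amplitude = 0)
  regions <- tiny_atlas_regions()
  regions$role[2] <- "effect_high_left"
  at2 <- generate_atlas(cfg2, regions)
  subj <- data.frame(id = "s1", cl = cfg2$cl_high)  # g_high(cl_high) = 1
  v2 <- render_volume(subj, at2, cfg2)
  hi <- atlas_role_mask(at2, "effect_high")
  expect_equal(mean(v2$values[hi]), cfg2$baseline + 0.5, tolerance = 1e-12)
  expect_true(all(v2$values[at2$mask & !hi] == cfg2$baseline))
})

test_that("volumes are reproducible and masked for every subject", {
  cfg <- tiny_config()
  at <- generate_atlas(cfg, tiny_atlas_regions())
  co <- sample_cohort(cfg)
  vols1 <- render_cohort_volumes(co, at, cfg)
  vols2 <- render_cohort_volumes(co, at, cfg)
  expect_identical(vols1, vols2)
  for (v in vols1) expect_true(all(v$values[!at$mask] == 0))
  # per-subject seeds: a volume regenerated alone matches the batch
  expect_identical(render_volume(co[5, ], at, cfg), vols1[[co$id[5]]])
})

test_that("planted ramps express the informativeness crossover analytically", {
  cfg <- synthetic_config()
  eps <- 1e-4
  dlow <- function(cl) (g_low(cl + eps, cfg) - g_low(cl - eps, cfg)) / (2 * eps)
  dhigh <- function(cl) (g_high(cl + eps, cfg) - g_high(cl - eps, cfg)) / (2 * eps)
  lo_amp <- cfg$effect_low_region; hi_amp <- cfg$effect_high_region
  for (cl in c(-5, 0, 10)) # well below the changepoint
    expect_gt(lo_amp * dlow(cl), hi_amp * dhigh(cl))
  for (cl in c(40, 80, 120)) # well above
    expect_gt(hi_amp * dhigh(cl), lo_amp * dlow(cl))
  expect_true(all(g_high(seq(-10, 140, 5), cfg) >= 0))
  expect_true(all(g_high(seq(-10, 140, 5), cfg) <= 1))
})

test_that("null regions carry no CL signal", {
  cfg <- synthetic_config(n_subjects = 60L, seed = 33L)
  at <- generate_atlas(cfg)
  co <- sample_cohort(cfg)
  vols <- render_cohort_volumes(co, at, cfg)
  nm <- atlas_role_mask(at, "null")
  means <- vapply(vols, function(v) mean(v$values[nm]), numeric(1))
  expect_lt(abs(cor(means, co$cl)), 3 / sqrt(length(means)))
})

test_that("datasets round-trip through NIfTI and TSV", {
  cfg <- tiny_config(n_subjects = 3L)
  at <- generate_atlas(cfg, tiny_atlas_regions())
  co <- sample_cohort(cfg)
  vols <- render_cohort_volumes(co, at, cfg)
  out <- withr::local_tempdir()
  manifest <- write_dataset(co, vols, at, out)
  expect_equal(nrow(manifest), cfg$n_subjects + 1L)  # volumes + atlas
  v_back <- read_volume(file.path(out, paste0("vol_", co$id[2], ".nii.gz")))
  expect_equal(v_back$values, vols[[co$id[2]]]$values, tolerance = 1e-12)
  expect_equal(v_back$voxel_size_mm, rep(2, 3))
  co_back <- utils::read.delim(file.path(out, "cohort.tsv"),
                               stringsAsFactors = FALSE)
  expect_equal(co_back$id, co$id)
  expect_equal(co_back$cl, co$cl, tolerance = 1e-12)
  expect_equal(co_back$sex, co$sex)
  expect_error(write_dataset(co, vols[-1], at, out), "one volume per")
})
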