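test_that("min-max scaling maps the in-mask range onto [0, 1]", {
  d <- c(8L, 8L, 8L)
  mask <- array(TRUE, d)
  vals <- array(0, d); vals[1:3] <- c(2, 4, 6)
  mask[] <- FALSE; mask[1:3] <- TRUE
  v <- new_volume(vals, voxel_size_mm = 1)
  out <- minmax_scale(v, mask)
  expect_equal(out$values[1:3], c(0, 0.5, 1))
  expect_true(all(out$values[!mask] == 0))
  expect_equal(attr(out, "scale_min"), 2)
  expect_equal(attr(out, "scale_max"), 6)

  # any non-constant input attains 0 and 1 inside the mask
  v2 <- random_volume(d, seed = 4)
  out2 <- minmax_scale(v2, array(TRUE, d))
  expect_equal(min(out2$values), 0)
  expect_equal(max(out2$values), 1)
  expect_equal(out2$kind, "scaled")
})

test_that("min-max scaling of a constant image warns and returns zeros", {
  d <- c(6L, 6L, 6L)
  v <- new_volume(array(3, d), voxel_size_mm = 1)
  expect_warning(out <- minmax_scale(v, array(TRUE, d)), "constant")
  expect_true(all(out$values == 0))
})

test_that("min-max scaling is idempotent on non-constant images", {
  d <- c(8L, 8L, 8L)
  mask <- array(TRUE, d)
  v <- random_volume(d, seed = 9)
  once <- minmax_scale(v, mask)
  twice <- minmax_scale(once, mask)
  expect_equal(twice$values, once$values, tolerance = 1e-12)
})

test_that("SUVR normalization divides by the reference-region mean", {
  cfg <- tiny_config(noise_sd = 0, effect_low_region = 0,
                     offtarget_amplitude = 0)
  at <- generate_atlas(cfg, tiny_atlas_regions())
  # uniform image -> SUVR 1 everywhere in mask
  v <- new_volume(array(2, cfg$grid_shape), voxel_size_mm = 2)
  s <- compute_suvr(v, at)
  expect_true(all(abs(s$values - 1) < 1e-12))
  # known ratio
  vals <- array(2, cfg$grid_shape)
  ref <- atlas_role_mask(at, "reference")
  vals[1, 1, 1] <- 3
  s2 <- compute_suvr(new_volume(vals, voxel_size_mm = 2), at)
  expect_equal(s2$values[1, 1, 1], 1.5)
  # mean SUVR over the reference region is exactly 1
  v3 <- random_volume(cfg$grid_shape, seed = 2)
  v3$values <- v3$values + 1
  s3 <- compute_suvr(v3, at)
  expect_equal(mean(s3$values[ref]), 1, tolerance = 1e-12)
  # nonpositive reference mean is fatal
  v4 <- new_volume(array(0, cfg$grid_shape), voxel_size_mm = 2)
  expect_error(compute_suvr(v4, at), "positive")
})

test_that("masking zeroes exactly the out-of-mask voxels", {
  d <- c(6L, 7L, 6L)
  v <- random_volume(d, seed = 3)
  full <- apply_mask(v, array(TRUE, d))
  expect_equal(full$values, v$values)
  none <- apply_mask(v, array(FALSE, d))
  expect_true(all(none$values == 0))
  m <- array(runif(prod(d)) > 0.5, d)
  out <- apply_mask(v, m)
  expect_lte(sum(out$values != 0), sum(m))
  expect_error(apply_mask(v, array(TRUE, c(3, 3, 3))), "grids")
})

test_that("Gaussian smoothing: identity on constants, mass preservation", {
  d <- c(9L, 9L, 9L)
  v <- new_volume(array(5, d), voxel_size_mm = 1)
  out <- gaussian_smooth(v, fwhm_mm = 2)
  expect_lt(max(abs(out$values - 5)), 1e-10)
  # deep-interior image preserves its sum (2 kernel radii from every edge,
  # so neither the sources nor any reached row is edge-renormalized)
  d2 <- c(19L, 19L, 19L)
  vals <- array(0, d2); vals[9:11, 9:11, 9:11] <- runif(27)
  v2 <- new_volume(vals, voxel_size_mm = 1)
  out2 <- gaussian_smooth(v2, fwhm_mm = 2)  # kernel radius 4
  expect_lt(abs(sum(out2$values) - sum(vals)) / sum(vals), 1e-8)
})

test_that("impulse response equals the normalized separable Gaussian kernel", {
  d <- c(19L, 19L, 19L)
  ctr <- 10L
  vals <- array(0, d); vals[ctr, ctr, ctr] <- 1
  fwhm <- 2
  out <- gaussian_smooth(new_volume(vals, voxel_size_mm = 1), fwhm)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  offs <- -4:4                       # kernel truncation radius ceiling(4*sigma)
  g <- exp(-offs^2 / (2 * sigma^2)); g <- g / sum(g)
  # compare where the response is fully interior (no edge renormalization)
  inner <- ctr + (-3:3)
  expected <- outer(outer(g, g), g)[2:8, 2:8, 2:8]
  expect_lt(max(abs(out$values[inner, inner, inner] - expected)), 1e-6)
  # total mass is exactly preserved for an interior impulse
  expect_lt(abs(sum(out$values) - 1), 1e-10)
})

test_that("smoothing matches a brute-force dense 3D convolution", {
  d <- c(9L, 9L, 9L)
  v <- random_volume(d, seed = 11)
  fwhm <- 3
  out <- gaussian_smooth(v, fwhm)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(4 * sigma))
  offs <- (-r):r
  g1 <- exp(-offs^2 / (2 * sigma^2))
  # brute force with edge-renormalized truncated kernel
  brute <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    acc <- 0; wsum <- 0
    for (a in offs) for (b in offs) for (cc in offs) {
      ii <- i + a; jj <- j + b; kk <- k + cc
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
          kk >= 1 && kk <= d[3]) {
        # separable renormalization: weight = product of per-axis
        # renormalized 1D kernels
        wa <- g1[a + r + 1] / sum(g1[offs + i >= 1 & offs + i <= d[1]])
        wb <- g1[b + r + 1] / sum(g1[offs + j >= 1 & offs + j <= d[2]])
        wc <- g1[cc + r + 1] / sum(g1[offs + k >= 1 & offs + k <= d[3]])
        acc <- acc + wa * wb * wc * v$values[ii, jj, kk]
      }
    }
    brute[i, j, k] <- acc
  }
  expect_lt(max(abs(out$values - brute)), 1e-8)
})

test_that("smoothing axes commute (separability)", {
  d <- c(8L, 10L, 8L)
  v <- random_volume(d, seed = 21)
  sig <- 1.1
  K1 <- taucl:::gaussian_kernel_matrix(d[1], sig)
  K2 <- taucl:::gaussian_kernel_matrix(d[2], sig)
  ax <- taucl:::apply_along_axis
  a12 <- ax(ax(v$values, K1, 1), K2, 2)
  a21 <- ax(ax(v$values, K2, 2), K1, 1)
  expect_equal(a12, a21, tolerance = 1e-12)
})
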