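test_that("occlude_volume follows set semantics", {
  d <- c(6L, 6L, 6L)
  v <- random_volume(d, seed = 30)
  none <- occlude_volume(v, array(FALSE, d))
  expect_equal(none$values, v$values)
  m <- array(runif(prod(d)) > 0.6, d)
  out <- occlude_volume(v, m)
  expect_equal(sum(out$values != v$values), sum(v$values[m] != 0))
  expect_true(all(out$values[m] == 0))
  # occluding A then B equals occluding the union, for disjoint masks
  a <- array(FALSE, d); a[1:20] <- TRUE
  b <- array(FALSE, d); b[30:50] <- TRUE
  expect_equal(occlude_volume(occlude_volume(v, a), b)$values,
               occlude_volume(v, a | b)$values)
  # mean fill uses the in-region mean
  mf <- occlude_volume(v, a, fill = "mean")
  expect_equal(unique(mf$values[a]), mean(v$values[a]))
  expect_error(occlude_volume(v, array(TRUE, c(2, 2, 2))), "grids")
})

test_that("a zero-voxel occlusion leaves R2 at baseline", {
  inst <- random_instance(seed = 31)
  set.seed(31)
  X <- matrix(runif(512 * 10), 512, 10)
  attr(X, "input_dim") <- c(8L, 8L, 8L)
  y <- rnorm(10)
  res <- occlusion_r2(inst, X, y, list(all = 1:10),
                      array(FALSE, c(8L, 8L, 8L)))
  expect_equal(res$table$r2_post, res$table$r2_baseline)
  expect_equal(res$predictions$pred_full, res$predictions$pred_occluded)
})

test_that("loess_smooth reproduces lines and constants exactly", {
  set.seed(32)
  x <- sort(runif(40, 0, 10))
  grid <- seq(1, 9, length.out = 15)
  y_lin <- 2.5 * x - 4
  for (span in c(0.3, 0.5, 1)) {
    expect_lt(max(abs(loess_smooth(x, y_lin, span, grid) -
                        (2.5 * grid - 4))), 1e-8)
  }
  expect_equal(loess_smooth(x, rep(7, 40), 0.4, grid), rep(7, 15))
  expect_error(loess_smooth(rep(1, 10), rnorm(10), 0.5, grid), "degenerate")
})

test_that("loess_smooth matches a per-point weighted-least-squares oracle", {
  set.seed(33)
  x <- runif(60, -5, 5)
  y <- sin(x) + rnorm(60, 0, 0.2)
  grid <- seq(-4, 4, length.out = 21)
  span <- 0.5
  ours <- loess_smooth(x, y, span, grid)
  n <- length(x)
  q <- max(2L, ceiling(span * n))
  oracle <- vapply(grid, function(g) {
    d <- abs(x - g)
    h <- sort(d)[q]
    w <- pmax(0, 1 - (d / h)^3)^3
    fit <- stats::lm.wfit(cbind(1, x - g), y, w)
    fit$coefficients[1]
  }, numeric(1))
  expect_lt(max(abs(ours - oracle)), 1e-8)
})

test_that("strength curves: empty mask gives zero, constants pass through", {
  inst <- random_instance(seed = 34)
  set.seed(34)
  X <- matrix(runif(512 * 20), 512, 20)
  attr(X, "input_dim") <- c(8L, 8L, 8L)
  y <- runif(20, -10, 140)
  z <- strength_of_association(list(inst), X, y,
                               array(FALSE, c(8L, 8L, 8L)))
  expect_true(all(z$mean == 0))
  expect_true(all(z$sem == 0))
  # grid outside the observed CL range is clipped with a warning
  expect_warning(
    zc <- strength_of_association(list(inst), X, y,
                                  array(FALSE, c(8L, 8L, 8L)),
                                  grid = seq(-100, 100, by = 10)),
    "clipped")
  expect_true(all(zc$grid >= min(y) & zc$grid <= max(y)))
})

test_that("association-curve SEM is the cross-instance SD over sqrt(k)", {
  insts <- lapply(35:38, random_instance)
  set.seed(35)
  X <- matrix(runif(512 * 25), 512, 25)
  attr(X, "input_dim") <- c(8L, 8L, 8L)
  y <- runif(25, 0, 100)
  m <- array(FALSE, c(8L, 8L, 8L)); m[100:200] <- TRUE
  z <- strength_of_association(insts, X, y, m, grid = seq(10, 90, 10))
  expect_equal(z$sem, apply(z$per_instance, 2, sd) / sqrt(4))
  expect_equal(z$mean, colMeans(z$per_instance))
  expect_true(all(z$per_instance >= 0))
})

test_that("occluding a superset mask never helps (monotone information loss)", {
  cfg <- tiny_config(n_subjects = 24L, noise_sd = 0.05)
  regions <- tiny_atlas_regions()
  regions$role[2] <- "effect_high_left"
  at <- generate_atlas(cfg, regions)
  co <- sample_cohort(cfg)
  vols <- render_cohort_volumes(co, at, cfg)
  X <- as_input_matrix(lapply(vols, minmax_scale, mask = at))
  ccfg <- cnn_config(channels = c(4L, 8L), dense = 8L, max_epochs = 30L,
                     patience = 30L, seed = 41L)
  tr <- 1:18; va <- 19:24
  inst <- train_instance(X, co$cl, tr, va, ccfg, fold = 1)
  hi <- atlas_role_mask(at, "effect_high")
  sub <- hi & array(seq_len(prod(cfg$grid_shape)) %% 2 == 0, cfg$grid_shape)
  splits <- list(validation = va)
  r_sub <- occlusion_r2(inst, X, co$cl, splits, sub)$table$r2_post
  r_sup <- occlusion_r2(inst, X, co$cl, splits, hi)$table$r2_post
  expect_lte(r_sup, r_sub + 0.15)  # Monte-Carlo jitter allowance
})

test_that("sub-clusters partition their parent cluster exactly", {
  cfg <- tiny_config()
  at <- generate_atlas(cfg, tiny_atlas_regions())
  d <- cfg$grid_shape
  # a cluster straddling region b and unlabeled tissue
  reg_b <- which(at$labels == 2L)
  bg <- which(at$mask & at$labels == 0L)
  vox <- c(reg_b[1:18], bg[1:27])   # 60/40-style split across two labels
  cl <- list(voxels = vox)
  subs <- split_subclusters(cl, at)
  expect_setequal(names(subs), c("b", "residual"))
  expect_equal(sum(subs[["b"]]), 18)
  expect_equal(sum(subs[["residual"]]), 27)
  # union = parent, pairwise disjoint
  expect_equal(which(subs[["b"]] | subs[["residual"]]), sort(vox))
  expect_false(any(subs[["b"]] & subs[["residual"]]))
  # cluster wholly inside one region: a single identical sub-cluster
  cl2 <- list(voxels = reg_b[1:15])
  subs2 <- split_subclusters(cl2, at)
  expect_length(subs2, 1)
  expect_equal(which(subs2[["b"]]), sort(reg_b[1:15]))
})
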