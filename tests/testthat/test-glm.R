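test_that("voxel-wise OLS matches a brute-force normal-equations oracle", {
  set.seed(7)
  n <- 20; V <- 100
  cohort <- data.frame(cl = runif(n, -10, 140), age = rnorm(n, 70, 8),
                       sex = sample(c("F", "M"), n, replace = TRUE))
  X <- make_design(cohort)
  Y <- matrix(rnorm(n * V), n, V)
  fit <- fit_voxelwise_glm(Y, X)
  j <- match("cl", colnames(X))
  XtX_inv <- solve(t(X) %*% X)
  for (v in seq_len(V)) {
    beta <- XtX_inv %*% t(X) %*% Y[, v]
    expect_lt(max(abs(fit$beta[, v] - beta)), 1e-8)
    res <- Y[, v] - X %*% beta
    s2 <- sum(res^2) / (n - ncol(X))
    t_or <- beta[j] / sqrt(s2 * XtX_inv[j, j])
    expect_lt(abs(fit$tstat[v] - t_or), 1e-8)
  }
  expect_equal(fit$df, n - 4)
})

test_that("an exact linear dependence gives beta 1, zero residuals, infinite t", {
  set.seed(8)
  n <- 15
  cohort <- data.frame(cl = runif(n, 0, 100), age = rnorm(n, 70, 5),
                       sex = sample(c("F", "M"), n, replace = TRUE))
  X <- make_design(cohort)
  Y <- cbind(cohort$cl, rnorm(n))
  fit <- fit_voxelwise_glm(Y, X)
  expect_equal(fit$beta[match("cl", colnames(X)), 1], 1, tolerance = 1e-10)
  expect_true(is.infinite(fit$tstat[1]))
  expect_equal(fit$n_exact, 1L)
})

test_that("adding a constant to the dependent data only moves the intercept", {
  set.seed(9)
  n <- 25
  cohort <- data.frame(cl = runif(n), age = rnorm(n),
                       sex = sample(c("F", "M"), n, replace = TRUE))
  X <- make_design(cohort)
  Y <- matrix(rnorm(n * 10), n, 10)
  f1 <- fit_voxelwise_glm(Y, X)
  f2 <- fit_voxelwise_glm(Y + 5, X)
  expect_equal(f2$beta[1, ], f1$beta[1, ] + 5, tolerance = 1e-10)
  expect_equal(f2$beta[-1, ], f1$beta[-1, ], tolerance = 1e-10)
  expect_equal(f2$tstat, f1$tstat, tolerance = 1e-10)
})

test_that("rank-deficient designs fail naming the collinear column", {
  cohort <- data.frame(cl = 1:10, age = 2 * (1:10),
                       sex = rep(c("F", "M"), 5))
  expect_error(make_design(cohort), "age|cl")
})

test_that("null t statistics follow the Student t distribution", {
  set.seed(10)
  n <- 20; V <- 10000
  cohort <- data.frame(cl = runif(n), age = rnorm(n),
                       sex = sample(c("F", "M"), n, replace = TRUE))
  X <- make_design(cohort)
  Y <- matrix(rnorm(n * V), n, V)
  fit <- fit_voxelwise_glm(Y, X)
  ks <- stats::ks.test(fit$tstat, stats::pt, df = fit$df)
  expect_gt(ks$p.value, 0.01)
})

test_that("permutation maxT threshold: seeding, alpha monotonicity, boundary", {
  set.seed(11)
  n <- 16; V <- 50
  cohort <- data.frame(cl = runif(n), age = rnorm(n),
                       sex = sample(c("F", "M"), n, replace = TRUE))
  X <- make_design(cohort)
  Y <- matrix(rnorm(n * V), n, V)
  t1 <- fwe_threshold(Y, X, alpha = 0.05, n_perm = 199, seed = 4)
  t2 <- fwe_threshold(Y, X, alpha = 0.05, n_perm = 199, seed = 4)
  expect_identical(as.numeric(t1), as.numeric(t2))
  alphas <- c(0.01, 0.05, 0.2, 1)
  thr <- vapply(alphas, function(a)
    as.numeric(fwe_threshold(Y, X, alpha = a, n_perm = 199, seed = 4)),
    numeric(1))
  expect_true(all(diff(thr) <= 0))
  # alpha = 1 gives the minimum of the null maxima
  expect_equal(thr[4], min(attr(t1, "null_max_t")))
})

test_that("tiny cohorts fall back to exhaustive permutation enumeration", {
  set.seed(12)
  n <- 5
  cohort <- data.frame(cl = runif(n), age = rnorm(n),
                       sex = c("F", "M", "F", "M", "F"))
  X <- stats::model.matrix(~cl, data = cohort)
  attr(X, "focus") <- "cl"
  Y <- matrix(rnorm(n * 10), n, 10)
  expect_warning(thr <- fwe_threshold(Y, X, n_perm = 500, seed = 1),
                 "exhaustively")
  expect_equal(attr(thr, "n_perm"), factorial(5) - 1)
})

test_that("clustering honors threshold, extent and connectivity", {
  d <- c(12L, 12L, 12L)
  tv <- array(0, d)
  # blob A: 3x3x3 cube plus a tail = 28 voxels; blob B: 2x2x2 = 8 voxels
  tv[2:4, 2:4, 2:4] <- 5
  tv[5, 5, 5] <- 5          # corner-touching tail (26-connectivity only)
  tv[9:10, 9:10, 9:10] <- 6
  cs26 <- threshold_and_cluster(tv, 3, min_extent = 5, connectivity = 26)
  expect_length(cs26$clusters, 2)
  expect_equal(vapply(cs26$clusters, `[[`, integer(1), "size"), c(28L, 8L))
  expect_equal(cs26$clusters[[2]]$peak_t, 6)
  cs6 <- threshold_and_cluster(tv, 3, min_extent = 5, connectivity = 6)
  expect_equal(vapply(cs6$clusters, `[[`, integer(1), "size"), c(27L, 8L))
  # extent filter discards a 199-voxel blob at min_extent 200
  blob <- array(0, c(10L, 10L, 10L)); blob[1:199] <- 4
  expect_length(threshold_and_cluster(blob, 3, min_extent = 200)$clusters, 0)
  expect_length(threshold_and_cluster(blob, 3, min_extent = 199)$clusters, 1)
  # no suprathreshold voxels -> empty set
  expect_length(threshold_and_cluster(array(0, d), 3)$clusters, 0)
})

test_that("connected components match a brute-force flood fill", {
  flood_oracle <- function(cond, conn) {
    d <- dim(cond); lab <- array(0L, d); nl <- 0L
    offs <- taucl:::neighbor_offsets(conn)
    for (start in which(cond)) {
      if (lab[start] != 0L) next
      nl <- nl + 1L
      stack <- start
      while (length(stack)) {
        v <- stack[length(stack)]; stack <- stack[-length(stack)]
        if (lab[v] != 0L) next
        lab[v] <- nl
        cc <- arrayInd(v, d)
        for (r in seq_len(nrow(offs))) {
          nb <- cc + offs[r, ]
          if (all(nb >= 1) && all(nb <= d)) {
            lin <- nb[1] + (nb[2] - 1) * d[1] + (nb[3] - 1) * d[1] * d[2]
            if (cond[lin] && lab[lin] == 0L) stack <- c(stack, lin)
          }
        }
      }
    }
    lab
  }
  set.seed(13)
  for (conn in c(6L, 18L, 26L)) {
    cond <- array(runif(9 * 9 * 9) < 0.3, c(9L, 9L, 9L))
    ours <- taucl:::label_components(cond, conn)
    oracle <- flood_oracle(cond, conn)
    # same partition up to label renaming
    expect_equal(ours > 0, oracle > 0)
    tab <- table(ours[ours > 0], oracle[oracle > 0])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("cluster Dice and consensus follow set arithmetic", {
  d <- c(8L, 8L, 8L)
  mk <- function(idx) {
    tv <- array(0, d); tv[idx] <- 10
    threshold_and_cluster(tv, 1, min_extent = 1)
  }
  a <- mk(1:100); b <- mk(51:150); cident <- mk(1:100); disj <- mk(201:300)
  cons <- cluster_consistency(list(a, b))
  expect_equal(cons$dice[1, 2], 0.5)
  expect_equal(cluster_consistency(list(a, cident))$dice[1, 2], 1)
  expect_equal(cluster_consistency(list(a, disj))$dice[1, 2], 0)
  expect_equal(sum(cons$consensus == 2), 50)
  expect_equal(sum(cons$consensus >= 1), 150)
  expect_error(cluster_consistency(list(a)), "two")
})

test_that("extent thresholds scale with voxel volume", {
  expect_equal(scale_extent(200, 1), 200L)
  expect_equal(scale_extent(200, 2), 25L)
  expect_equal(scale_extent(200, c(1, 1, 2)), 100L)
  expect_equal(scale_extent(1, 10), 1L)  # floor at one voxel
})
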