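# 3D convolutional network regressor, written directly on BLAS matrix
# primitives. Convolutions are evaluated by gathering 3x3x3 input patches
# into an im2col matrix and multiplying by the flattened kernel bank; the
# backward pass scatters patch gradients back with a grouped row-sum. This
# keeps the whole network differentiable in closed form, which the saliency
# module relies on (exact input gradients, no framework).

#' Configuration of the 3D CNN regressor
#'
#' A compact encoder in the spirit of the contracting half of a U-net:
#' stride-2 3x3x3 convolution stages with widening channels, global average
#' pooling, and a small dense head producing one scalar. Trained with
#' RMSprop on mean squared error; the epoch with the best validation RMSE
#' is kept.
#'
#' @param channels integer vector of channel widths, one per conv stage
#'   (at least 2 stages).
#' @param head `"gap"` (default) global-average-pools the last feature
#'   map; `"flatten"` keeps position-specific weights into the dense
#'   layers (spatially selective read-out, more parameters).
#' @param dense widths of the hidden dense layers after the head.
#' @param activation `"relu"` (default) or `"softplus"`.
#' @param lr RMSprop learning rate.
#' @param rho RMSprop decay.
#' @param weight_decay L2 penalty on convolution and dense weights (not
#'   biases). Shrinks weights that do not reduce the loss -- in particular
#'   parasitic weights on uninformative voxels, which would otherwise leave
#'   diffuse structure in gradient saliency maps.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param target_scaling `"standardize"` (default) rescales the Centiloid
#'   target to zero mean / unit variance of the training split before
#'   optimization; predictions are always returned in Centiloid units.
#' @param seed integer seed controlling initialization and batch order.
#' @return A `taucl_cnn_config` list.
#' @export
cnn_config <- function(channels = c(8L, 16L, 32L, 64L),
                       head = c("gap", "flatten"),
                       dense = 32L,
                       activation = c("relu", "softplus"),
                       lr = 3e-3, rho = 0.9, weight_decay = 1e-4,
                       batch_size = 24L,
                       max_epochs = 100L,
                       patience = 20L,
                       target_scaling = c("standardize", "none"),
                       seed = 1L) {
  activation <- match.arg(activation)
  head <- match.arg(head)
  target_scaling <- match.arg(target_scaling)
  stopifnot(length(channels) >= 2L, all(channels > 0),
            all(dense > 0) || length(dense) == 0L,
            lr > 0, rho > 0, rho < 1, weight_decay >= 0, batch_size >= 1,
            max_epochs >= 1, patience >= 1)
  structure(
    list(channels = as.integer(channels), head = head,
         dense = as.integer(dense),
         kernel = 3L, stride = 2L, activation = activation,
         optimizer = "rmsprop", lr = lr, rho = rho, eps = 1e-8,
         weight_decay = weight_decay,
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         patience = as.integer(patience),
         target_scaling = target_scaling, seed = as.integer(seed)),
    class = "taucl_cnn_config"
  )
}

act_fun <- function(name) {
  switch(name,
         relu = list(f = function(z) { z[z < 0] <- 0; z },
                     grad = function(z) (z > 0) + 0),
         softplus = list(f = function(z) log1p(exp(-abs(z))) + pmax(z, 0),
                         grad = function(z) stats::plogis(z)),
         stop(sprintf("unknown activation '%s'", name)))
}

# im2col index table for a 3x3x3 stride-2 pad-1 convolution on grid `in_dim`.
# Row p gives, for output position p (column-major), the 27 linear indices of
# its input patch into an input vector augmented with one trailing zero row
# (index nvox+1 stands for padding).
conv_indices <- function(in_dim, kernel = 3L, stride = 2L, pad = 1L) {
  out_dim <- (in_dim + 2L * pad - kernel) %/% stride + 1L
  nvox <- prod(in_dim)
  og <- as.matrix(expand.grid(o1 = seq_len(out_dim[1]),
                              o2 = seq_len(out_dim[2]),
                              o3 = seq_len(out_dim[3])))
  base <- sweep((og - 1L) * stride, 2L, rep(pad, 3), `-`)  # 0-based - pad
  offs <- as.matrix(expand.grid(t1 = seq_len(kernel) - 1L,
                                t2 = seq_len(kernel) - 1L,
                                t3 = seq_len(kernel) - 1L))
  ind <- matrix(nvox + 1L, nrow(og), nrow(offs))
  for (kk in seq_len(nrow(offs))) {
    i1 <- base[, 1] + offs[kk, 1] + 1L
    i2 <- base[, 2] + offs[kk, 2] + 1L
    i3 <- base[, 3] + offs[kk, 3] + 1L
    ok <- i1 >= 1L & i1 <= in_dim[1] & i2 >= 1L & i2 <= in_dim[2] &
      i3 >= 1L & i3 <= in_dim[3]
    ind[ok, kk] <- i1[ok] + (i2[ok] - 1L) * in_dim[1] +
      (i3[ok] - 1L) * in_dim[1] * in_dim[2]
  }
  list(ind = ind, out_dim = out_dim, nvox_in = nvox)
}

# Build the layer stack for a given input grid. Weights: He-scaled normal
# for the conv/dense stages, small final layer.
build_network <- function(input_dim, config, seed) {
  set.seed(as.integer(seed %% 2147483647))
  layers <- list()
  in_dim <- as.integer(input_dim)
  cin <- 1L
  for (cout in config$channels) {
    ix <- conv_indices(in_dim, config$kernel, config$stride)
    fan_in <- 27L * cin
    layers[[length(layers) + 1L]] <- list(
      type = "conv",
      W = matrix(stats::rnorm(fan_in * cout, 0, sqrt(2 / fan_in)),
                 fan_in, cout),
      b = numeric(cout),
      ind_vec = as.vector(ix$ind), npos = nrow(ix$ind),
      nvox_in = ix$nvox_in, cin = cin, cout = cout,
      out_dim = ix$out_dim)
    in_dim <- ix$out_dim
    cin <- cout
  }
  head <- config$head %||% "gap"
  layers[[length(layers) + 1L]] <- list(type = head, npos = prod(in_dim),
                                        channels = cin)
  width <- if (head == "flatten") prod(in_dim) * cin else cin
  for (w in config$dense) {
    layers[[length(layers) + 1L]] <- list(
      type = "dense", activated = TRUE,
      W = matrix(stats::rnorm(width * w, 0, sqrt(2 / width)), width, w),
      b = numeric(w))
    width <- w
  }
  layers[[length(layers) + 1L]] <- list(
    type = "dense", activated = FALSE,
    W = matrix(stats::rnorm(width, 0, sqrt(1 / width)), width, 1L),
    b = numeric(1L))
  list(layers = layers, input_dim = as.integer(input_dim),
       activation = config$activation)
}

# Forward pass over a batch. `X` is (nvox x B). Returns predictions (length
# B) and, if `keep` is TRUE, per-layer caches for the backward pass.
net_forward <- function(net, X, keep = FALSE) {
  act <- act_fun(net$activation)
  B <- ncol(X)
  caches <- if (keep) vector("list", length(net$layers))
  # conv-stage input: (nvox_in + 1) x (cin * B), trailing zero pad row
  cur <- rbind(X, 0)
  g <- NULL
  for (li in seq_along(net$layers)) {
    ly <- net$layers[[li]]
    if (ly$type == "conv") {
      G <- cur[ly$ind_vec, , drop = FALSE]        # (npos*27) x (cin*B)
      dim(G) <- c(ly$npos, 27L, ly$cin, B)
      G <- aperm(G, c(1, 4, 2, 3))
      dim(G) <- c(ly$npos * B, 27L * ly$cin)
      Z <- G %*% ly$W
      Z <- Z + rep(ly$b, each = nrow(Z))
      A <- act$f(Z)
      if (keep) caches[[li]] <- list(G = G, Z = Z)
      nxt <- array(A, c(ly$npos, B, ly$cout))
      nxt <- aperm(nxt, c(1, 3, 2))
      dim(nxt) <- c(ly$npos, ly$cout * B)
      cur <- rbind(nxt, 0)
    } else if (ly$type == "gap") {
      A <- cur[-nrow(cur), , drop = FALSE]        # npos x (channels*B)
      dim(A) <- c(ly$npos, ly$channels, B)
      g <- t(colMeans(A))                         # B x channels
      if (keep) caches[[li]] <- list()
    } else if (ly$type == "flatten") {
      A <- cur[-nrow(cur), , drop = FALSE]        # npos x (channels*B)
      dim(A) <- c(ly$npos * ly$channels, B)
      g <- t(A)                                   # B x (npos*channels)
      if (keep) caches[[li]] <- list()
    } else {                                      # dense
      Z <- g %*% ly$W
      Z <- Z + rep(ly$b, each = nrow(Z))
      if (keep) caches[[li]] <- list(g_in = g, Z = Z)
      g <- if (ly$activated) act$f(Z) else Z
    }
  }
  list(pred = as.numeric(g), caches = caches, B = B)
}

# Backward pass from d(loss)/d(pred). Returns per-layer parameter gradients
# and (optionally) the gradient with respect to the input batch.
net_backward <- function(net, fw, dpred, want_input_grad = FALSE,
                         want_param_grad = TRUE) {
  act <- act_fun(net$activation)
  B <- fw$B
  grads <- vector("list", length(net$layers))
  dg <- matrix(dpred, B, 1L)
  dcur <- NULL  # gradient flowing into a conv stage's output feature map
  for (li in rev(seq_along(net$layers))) {
    ly <- net$layers[[li]]
    cache <- fw$caches[[li]]
    if (ly$type == "dense") {
      dZ <- if (ly$activated) dg * act$grad(cache$Z) else dg
      if (want_param_grad)
        grads[[li]] <- list(W = crossprod(cache$g_in, dZ), b = colSums(dZ))
      dg <- dZ %*% t(ly$W)
    } else if (ly$type == "gap") {
      # dg: B x channels -> spread over positions
      dA <- dg[rep(seq_len(B), each = ly$npos), , drop = FALSE] / ly$npos
      dcur <- dA                                   # (npos*B) x channels
    } else if (ly$type == "flatten") {
      dA <- t(dg)                                  # (npos*channels) x B
      dim(dA) <- c(ly$npos, ly$channels, B)
      dA <- aperm(dA, c(1, 3, 2))
      dim(dA) <- c(ly$npos * B, ly$channels)
      dcur <- dA
    } else {                                       # conv
      dZ <- dcur * act$grad(cache$Z)               # (npos*B) x cout
      if (want_param_grad)
        grads[[li]] <- list(W = crossprod(cache$G, dZ), b = colSums(dZ))
      last_conv <- li == 1L
      if (!last_conv || want_input_grad) {
        dG <- dZ %*% t(ly$W)                       # (npos*B) x (27*cin)
        dim(dG) <- c(ly$npos, B, 27L, ly$cin)
        dG <- aperm(dG, c(1, 3, 4, 2))
        dim(dG) <- c(ly$npos * 27L, ly$cin * B)
        rs <- rowsum(dG, ly$ind_vec)
        dXz <- matrix(0, ly$nvox_in + 1L, ly$cin * B)
        dXz[as.integer(rownames(rs)), ] <- rs
        dX <- dXz[-nrow(dXz), , drop = FALSE]      # nvox_in x (cin*B)
        if (!last_conv) {
          # reorder to the (npos*B) x cout layout of the upstream stage
          dim(dX) <- c(ly$nvox_in, ly$cin, B)
          dX <- aperm(dX, c(1, 3, 2))
          dim(dX) <- c(ly$nvox_in * B, ly$cin)
          dcur <- dX
        } else {
          grads$input <- dX                        # nvox x B (cin = 1)
        }
      }
    }
  }
  grads
}

rmsprop_step <- function(net, grads, state, config) {
  for (li in seq_along(net$layers)) {
    if (is.null(grads[[li]]) || is.null(grads[[li]]$W)) next
    for (nm in c("W", "b")) {
      g <- grads[[li]][[nm]]
      if (nm == "b") g <- as.numeric(g)
      else if (config$weight_decay > 0)
        g <- g + config$weight_decay * net$layers[[li]][[nm]]
      v <- state[[li]][[nm]]
      if (is.null(v)) v <- g * 0
      v <- config$rho * v + (1 - config$rho) * g^2
      state[[li]][[nm]] <- v
      net$layers[[li]][[nm]] <- net$layers[[li]][[nm]] -
        config$lr * g / (sqrt(v) + config$eps)
    }
  }
  list(net = net, state = state)
}

#' Stack scaled volumes into an input matrix
#'
#' @param volumes list of `taucl_volume`s on a common grid.
#' @return A `nvox x n` matrix with attribute `input_dim`.
#' @export
as_input_matrix <- function(volumes) {
  stopifnot(length(volumes) > 0)
  d <- dim(volumes[[1]]$values)
  X <- vapply(volumes, function(v) {
    check_same_grid(dim(v$values), d, "volume grids")
    as.vector(v$values)
  }, numeric(prod(d)))
  attr(X, "input_dim") <- d
  X
}

net_predict_scaledless <- function(net, X, batch = 64L) {
  n <- ncol(X)
  out <- numeric(n)
  for (s in seq(1L, n, by = batch)) {
    idx <- s:min(n, s + batch - 1L)
    out[idx] <- net_forward(net, X[, idx, drop = FALSE])$pred
  }
  out
}

#' Train one cross-validation instance of the CNN
#'
#' Minimizes mean squared error on the training split with RMSprop,
#' monitoring validation RMSE each epoch; the parameters from the best
#' validation epoch are kept (early stopping after `patience` stale
#' epochs). Fully deterministic given the config seed and fold id.
#'
#' @param X input matrix from [as_input_matrix()] (columns are subjects,
#'   values scaled to \[0, 1\]).
#' @param y Centiloid targets, one per column of `X`.
#' @param train_idx,val_idx column indices of the training and validation
#'   subjects.
#' @param config a `taucl_cnn_config`.
#' @param fold integer fold id (seeds the instance; recorded).
#' @return A `taucl_instance`: network parameters, config, fold id,
#'   per-epoch `history`, and `rmse_train`, `rmse_val`, `r2_train`,
#'   `r2_val` (test metrics are attached by [evaluate_instance()]).
#' @export
train_instance <- function(X, y, train_idx, val_idx, config, fold = 1L) {
  stopifnot(length(train_idx) > 0, length(val_idx) > 0,
            length(y) == ncol(X))
  input_dim <- attr(X, "input_dim")
  if (is.null(input_dim)) stop("X must come from as_input_matrix()")
  y_tr <- y[train_idx]
  if (config$target_scaling == "standardize") {
    ctr <- mean(y_tr); scl <- stats::sd(y_tr)
    if (!is.finite(scl) || scl == 0) scl <- 1
  } else {
    ctr <- 0; scl <- 1
  }
  yt <- (y - ctr) / scl
  net <- build_network(input_dim, config,
                       derive_seed(config$seed, paste0("init/", fold)))
  state <- vector("list", length(net$layers))
  best <- list(rmse = Inf, layers = net$layers, epoch = 0L)
  wait <- 0L
  hist_epoch <- integer(0); hist_train <- numeric(0); hist_val <- numeric(0)
  rng_seed <- derive_seed(config$seed, paste0("batches/", fold))
  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(rng_seed + epoch,
                     sample(train_idx, length(train_idx)))
    ep_loss <- 0
    for (s in seq(1L, length(ord), by = config$batch_size)) {
      idx <- ord[s:min(length(ord), s + config$batch_size - 1L)]
      fw <- net_forward(net, X[, idx, drop = FALSE], keep = TRUE)
      err <- fw$pred - yt[idx]
      if (!all(is.finite(err)))
        stop(sprintf(
          "non-finite loss in fold %s at epoch %d; try a lower learning rate",
          fold, epoch))
      ep_loss <- ep_loss + sum(err^2)
      grads <- net_backward(net, fw, 2 * err / length(idx))
      upd <- rmsprop_step(net, grads, state, config)
      net <- upd$net; state <- upd$state
    }
    val_pred <- net_predict_scaledless(net, X[, val_idx, drop = FALSE])
    val_rmse <- rmse(yt[val_idx], val_pred) * scl
    hist_epoch <- c(hist_epoch, epoch)
    hist_train <- c(hist_train, sqrt(ep_loss / length(ord)) * scl)
    hist_val <- c(hist_val, val_rmse)
    if (val_rmse < best$rmse - 1e-10) {
      best <- list(rmse = val_rmse, layers = net$layers, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  net$layers <- best$layers
  inst <- structure(
    list(net = net, config = config, fold = as.integer(fold),
         input_dim = input_dim, target_center = ctr, target_scale = scl,
         best_epoch = best$epoch,
         history = data.frame(epoch = hist_epoch, rmse_train = hist_train,
                              rmse_val = hist_val)),
    class = "taucl_instance")
  tr_pred <- predict_batch(inst, X[, train_idx, drop = FALSE])
  va_pred <- predict_batch(inst, X[, val_idx, drop = FALSE])
  inst$rmse_train <- rmse(y[train_idx], tr_pred)
  inst$rmse_val <- rmse(y[val_idx], va_pred)
  inst$r2_train <- r_squared(y[train_idx], tr_pred)
  inst$r2_val <- r_squared(y[val_idx], va_pred)
  inst
}

#' @export
print.taucl_instance <- function(x, ...) {
  cat(sprintf(
    "<taucl_instance> fold %d, best epoch %d: RMSE train %.2f / val %.2f%s\n",
    x$fold, x$best_epoch, x$rmse_train, x$rmse_val,
    if (!is.null(x$rmse_test)) sprintf(" / test %.2f", x$rmse_test) else ""))
  invisible(x)
}

#' Predict Centiloid for a batch of volumes
#'
#' A pure function of the learned parameters and the inputs: predictions
#' come back in Centiloid units regardless of internal target scaling.
#'
#' @param instance a `taucl_instance`.
#' @param X input matrix (`nvox x n`), a list of volumes, or a single
#'   `taucl_volume`.
#' @return Numeric vector of predictions.
#' @export
predict_batch <- function(instance, X) {
  if (is_volume(X)) X <- as_input_matrix(list(X))
  if (is.list(X)) X <- as_input_matrix(X)
  if (nrow(X) != prod(instance$input_dim))
    stop(sprintf("input has %d voxels; the instance was trained on %s",
                 nrow(X), paste(instance$input_dim, collapse = "x")))
  net_predict_scaledless(instance$net, X) * instance$target_scale +
    instance$target_center
}

#' Attach hold-out test metrics to an instance
#'
#' @param instance a `taucl_instance`.
#' @param X input matrix.
#' @param y Centiloid targets for `X`'s columns.
#' @param test_idx column indices of the test subjects.
#' @return The instance with `rmse_test` and `r2_test` filled in.
#' @export
evaluate_instance <- function(instance, X, y, test_idx) {
  pred <- predict_batch(instance, X[, test_idx, drop = FALSE])
  instance$rmse_test <- rmse(y[test_idx], pred)
  instance$r2_test <- r_squared(y[test_idx], pred)
  instance
}

#' Train all folds of a cross-validation plan
#'
#' @param X input matrix from [as_input_matrix()].
#' @param cohort cohort table aligned with the columns of `X`.
#' @param plan a `taucl_fold_plan` from [make_folds()].
#' @param config a `taucl_cnn_config`.
#' @param verbose print per-fold progress.
#' @return List of `taucl_instance`s (one per fold), each with test
#'   metrics attached.
#' @export
train_cv <- function(X, cohort, plan, config, verbose = FALSE) {
  stopifnot(ncol(X) == nrow(cohort))
  col_of <- stats::setNames(seq_len(nrow(cohort)), cohort$id)
  test_idx <- unname(col_of[plan$test])
  lapply(seq_len(plan$K), function(k) {
    f <- plan$folds[[k]]
    inst <- train_instance(X, cohort$cl,
                           unname(col_of[f$train]),
                           unname(col_of[f$validation]),
                           config, fold = k)
    inst <- evaluate_instance(inst, X, cohort$cl, test_idx)
    if (verbose) print(inst)
    inst
  })
}

#' Exact gradient of the prediction with respect to the input
#'
#' Backpropagates a unit output gradient through the network, yielding
#' d(prediction in CL)/d(input voxel) for one volume. This is the raw
#' (signed) quantity underlying saliency maps.
#'
#' @param instance a `taucl_instance` (methods exist for other objects with
#'   closed-form gradients, e.g. [affine_model()]).
#' @param x a `taucl_volume` or numeric array matching the training grid.
#' @return Numeric array of the input grid shape.
#' @export
input_gradient <- function(instance, x) UseMethod("input_gradient")

#' @rdname input_gradient
#' @export
input_gradient.taucl_instance <- function(instance, x) {
  vals <- if (is_volume(x)) x$values else x
  check_same_grid(dim(vals), instance$input_dim, "input and training grids")
  X <- matrix(as.vector(vals), ncol = 1L)
  fw <- net_forward(instance$net, X, keep = TRUE)
  if (!all(is.finite(fw$pred)))
    stop(sprintf("non-finite prediction in fold %d", instance$fold))
  gr <- net_backward(instance$net, fw, 1, want_input_grad = TRUE,
                     want_param_grad = FALSE)
  g <- gr$input * instance$target_scale
  if (!all(is.finite(g)))
    stop(sprintf("non-finite input gradient in fold %d", instance$fold))
  array(g, instance$input_dim)
}
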