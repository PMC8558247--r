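#' Configuration of the convolutional autoencoder classifier
#'
#' The default architecture: four convolution layers (64, 128, 256 kernels of
#' 4x4 and a fusing 64-kernel 1x1 layer), stride 1, zero 'same' padding, ReLU,
#' no pooling; dropout 0.2 on the flattened encoder output; a two-layer
#' stacked autoencoder (hidden sizes 400 and 100, sigmoid units, inputs to
#' each autoencoder standardised with statistics fitted on training data);
#' and a softmax head. Training uses cross-entropy with an L2 weight penalty
#' and the AdaDelta optimizer under an accuracy-gated learning-rate schedule:
#' below `lr_thresholds[1]` training accuracy the first rate applies, between
#' the thresholds the second, above `lr_thresholds[2]` the third.
#'
#' AdaDelta's update is self-normalising, so by default (`lr_mode =
#' "relative"`) the schedule contributes its *shape* (1, 1/2, 1/100 of the
#' first value) and the actual AdaDelta step multiplier is `base_step` times
#' that shape. A per-coordinate-normalised optimizer walks low-gradient trunk
#' coordinates as fast as informative ones, so a conservative base step
#' (default 0.1) keeps the convolutional features stable while the
#' head learns; `lr_mode = "absolute"` uses the raw schedule values as step
#' multipliers instead.
#'
#' @param conv_layers list of `c(n_kernels, kernel_size)` pairs.
#' @param dropout_rate dropout probability on the encoder output, in `[0, 1)`.
#' @param l2_lambda L2 weight-penalty coefficient.
#' @param sae_hidden hidden sizes of the two stacked-autoencoder layers.
#' @param n_classes number of emotion classes (2: low/high).
#' @param batch_size minibatch size.
#' @param epochs supervised fine-tuning epochs.
#' @param pretrain_epochs unsupervised epochs per autoencoder layer.
#' @param warmup_epochs supervised epochs run before SAE pretraining, so that
#'   the encoder the SAE reconstructs is not purely random.
#' @param lr_thresholds two accuracy thresholds of the schedule.
#' @param lr_values three positive, non-increasing learning rates.
#' @param lr_mode `"relative"` or `"absolute"` (see Details).
#' @param base_step AdaDelta step multiplier at the schedule's first branch
#'   (relative mode only).
#' @param adadelta_rho,adadelta_eps AdaDelta decay and conditioning constants.
#' @param sparsity logical; add a KL sparsity penalty to SAE pretraining.
#' @param sparsity_target,sparsity_weight target mean activation and penalty
#'   weight of the optional sparsity term.
#' @param seed integer seed controlling initialisation, dropout, shuffling.
#' @return object of class `cae_config`.
#' @export
cae_config <- function(conv_layers = list(c(64, 4), c(128, 4), c(256, 4), c(64, 1)),
                       dropout_rate = 0.2, l2_lambda = 1e-4,
                       sae_hidden = c(400, 100), n_classes = 2,
                       batch_size = 128, epochs = 100, pretrain_epochs = 20,
                       warmup_epochs = 5,
                       lr_thresholds = c(0.7, 0.85),
                       lr_values = c(1e-4, 5e-5, 1e-6),
                       lr_mode = c("relative", "absolute"), base_step = 0.1,
                       adadelta_rho = 0.95, adadelta_eps = 1e-6,
                       sparsity = FALSE, sparsity_target = 0.05,
                       sparsity_weight = 1.0, seed = 1) {
  lr_mode <- match.arg(lr_mode)
  if (!is.list(conv_layers) || length(conv_layers) < 1L)
    stopf("`conv_layers` must be a non-empty list of c(n_kernels, kernel_size)")
  for (cl in conv_layers)
    if (length(cl) != 2L || !is_count(cl[1L]) || !is_count(cl[2L]))
      stopf("each conv layer must be c(n_kernels, kernel_size) of positive integers")
  if (!is_number(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1)
    stopf("`dropout_rate` must lie in [0, 1)")
  if (!is_number(l2_lambda) || l2_lambda < 0) stopf("`l2_lambda` must be >= 0")
  if (length(sae_hidden) != 2L || !all(vapply(sae_hidden, is_count, TRUE)))
    stopf("`sae_hidden` must be two positive integers")
  if (!is_count(n_classes) || n_classes < 2) stopf("`n_classes` must be >= 2")
  if (length(lr_thresholds) != 2L || lr_thresholds[1L] >= lr_thresholds[2L])
    stopf("`lr_thresholds` must be two increasing accuracies")
  if (length(lr_values) != 3L || any(lr_values <= 0) || any(diff(lr_values) > 0))
    stopf("`lr_values` must be three positive, non-increasing rates")
  if (!is_count(batch_size)) stopf("`batch_size` must be a positive integer")
  for (nm in c("epochs", "pretrain_epochs", "warmup_epochs"))
    if (!is_number(get(nm)) || get(nm) < 0 || get(nm) != round(get(nm)))
      stopf("`%s` must be a non-negative integer", nm)
  structure(list(conv_layers = conv_layers, dropout_rate = dropout_rate,
                 l2_lambda = l2_lambda, sae_hidden = as.integer(sae_hidden),
                 n_classes = as.integer(n_classes),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 warmup_epochs = as.integer(warmup_epochs),
                 lr_thresholds = as.numeric(lr_thresholds),
                 lr_values = as.numeric(lr_values), lr_mode = lr_mode,
                 base_step = base_step,
                 adadelta_rho = adadelta_rho, adadelta_eps = adadelta_eps,
                 sparsity = isTRUE(sparsity),
                 sparsity_target = sparsity_target,
                 sparsity_weight = sparsity_weight,
                 seed = as.integer(seed)),
            class = "cae_config")
}

## ---- elementary ops ---------------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Numerically stable softmax
#'
#' `p_i = exp(z_i) / sum_j exp(z_j)`, computed with a per-row max shift so the
#' result is invariant to adding a constant to every score.
#'
#' @param z numeric vector of scores, or a matrix with one score row per sample.
#' @return probabilities of the same shape; each (row) sums to 1.
#' @export
softmax_prob <- function(z) {
  if (is.vector(z)) {
    e <- exp(z - max(z))
    return(e / sum(e))
  }
  e <- exp(z - apply(z, 1L, max))
  e / rowSums(e)
}

#' Mean cross-entropy loss
#'
#' `-(1/N) sum_n sum_i y_ni log(p_ni)` over a batch, with a probability floor
#' of `1e-12` inside the logarithm so that a confidently wrong prediction
#' yields a large finite loss rather than an infinity.
#'
#' @param prob n x k matrix of predicted class probabilities.
#' @param labels n x k one-hot matrix, or an integer vector of 0-based class
#'   indices.
#' @return non-negative scalar loss.
#' @export
cross_entropy_loss <- function(prob, labels) {
  prob <- rbind(prob)
  if (is.vector(labels) && !is.matrix(labels)) {
    y <- matrix(0, nrow(prob), ncol(prob))
    y[cbind(seq_len(nrow(prob)), as.integer(labels) + 1L)] <- 1
    labels <- y
  }
  if (!all(dim(prob) == dim(labels)))
    stopf("probability and label shapes differ (%s vs %s)",
          paste(dim(prob), collapse = "x"), paste(dim(labels), collapse = "x"))
  -mean(rowSums(labels * log(pmax(prob, 1e-12))))
}

#' Accuracy-gated learning rate
#'
#' Piecewise-constant schedule: the first rate below the first accuracy
#' threshold, the second between the thresholds, the third above the second
#' threshold.
#'
#' @param train_accuracy training accuracy in `[0, 1]`.
#' @param config a [cae_config()].
#' @return the scheduled learning rate.
#' @export
schedule_learning_rate <- function(train_accuracy, config = cae_config()) {
  if (!is_number(train_accuracy) || train_accuracy < 0 || train_accuracy > 1)
    stopf("`train_accuracy` must lie in [0, 1]")
  th <- config$lr_thresholds
  if (train_accuracy < th[1L]) config$lr_values[1L]
  else if (train_accuracy <= th[2L]) config$lr_values[2L]
  else config$lr_values[3L]
}

lr_multiplier <- function(rate, config) {
  if (config$lr_mode == "relative")
    config$base_step * rate / config$lr_values[1L]
  else rate
}

## ---- convolution machinery --------------------------------------------------

# kernel offsets for 'same' zero padding at stride 1 (keras convention:
# an even kernel pads one less on the leading side)
conv_offsets <- function(k) {
  lo <- -((k - 1L) %/% 2L)
  seq.int(lo, lo + k - 1L)
}

# per-offset source cell for every output cell; 0 marks zero padding.
# `sign = -1` gives the inverse shifts used when back-propagating.
conv_sources <- function(k, g, sign = 1L) {
  p0 <- 0:(g * g - 1L)
  x <- p0 %% g + 1L
  y <- p0 %/% g + 1L
  out <- list()
  for (dy in conv_offsets(k)) for (dx in conv_offsets(k)) {
    sx <- x + sign * dx; sy <- y + sign * dy
    src <- ifelse(sx >= 1L & sx <= g & sy >= 1L & sy <= g, sx + g * (sy - 1L), 0L)
    out[[length(out) + 1L]] <- as.integer(src)
  }
  out
}

gather_rows <- function(src, n, g2) {
  idx <- rep((seq_len(n) - 1L) * g2, each = g2) + rep(src, times = n)
  idx[rep(src == 0L, times = n)] <- n * g2 + 1L
  idx
}

# batch row-index cache: shift geometry is fixed per (k, grid, batch size)
.conv_cache <- new.env(parent = emptyenv())

cached_rows <- function(kind, k, g, n, srcs) {
  key <- paste(kind, k, g, n, sep = "_")
  val <- .conv_cache[[key]]
  if (is.null(val)) {
    val <- lapply(srcs, gather_rows, n = n, g2 = g * g)
    .conv_cache[[key]] <- val
  }
  val
}

conv_forward <- function(A, layer, geom, n, g2, activation = "relu",
                         keep_gather = FALSE) {
  g <- as.integer(sqrt(g2))
  rows <- cached_rows("f", layer$k, g, n, geom$src)
  Apad <- rbind(A, 0)
  Z <- matrix(layer$b, n * g2, length(layer$b), byrow = TRUE)
  G <- if (keep_gather) vector("list", length(layer$W)) else NULL
  for (o in seq_along(layer$W)) {
    Go <- Apad[rows[[o]], , drop = FALSE]
    Z <- Z + Go %*% layer$W[[o]]
    if (keep_gather) G[[o]] <- Go
  }
  out <- if (activation == "relu") pmax(Z, 0) else Z
  list(out = out, G = G, Z = Z)
}

conv_backward <- function(dOut, layer, fwd, geom, n, g2, activation = "relu") {
  dZ <- if (activation == "relu") dOut * (fwd$Z > 0) else dOut
  g <- as.integer(sqrt(g2))
  rows_inv <- cached_rows("b", layer$k, g, n, geom$inv)
  cin <- nrow(layer$W[[1L]])
  dA <- matrix(0, n * g2, cin)
  dW <- vector("list", length(layer$W))
  for (o in seq_along(layer$W)) {
    dW[[o]] <- crossprod(fwd$G[[o]], dZ)
    contrib <- rbind(dZ %*% t(layer$W[[o]]), 0)
    dA <- dA + contrib[rows_inv[[o]], , drop = FALSE]
  }
  list(dA = dA, dW = dW, db = colSums(dZ))
}

# (n*g2) x C channel matrix -> n x (g2*C) flat matrix, cell-fastest order
flatten_maps <- function(A, n, g2) {
  C <- ncol(A)
  matrix(aperm(array(A, dim = c(g2, n, C)), c(2L, 1L, 3L)), nrow = n)
}

unflatten_maps <- function(F, n, g2) {
  C <- ncol(F) / g2
  matrix(aperm(array(F, dim = c(n, g2, C)), c(2L, 1L, 3L)), ncol = C)
}

# feature_cube_set (or raw array) -> (n*g2) x depth matrix
cubes_to_input <- function(x) {
  v <- if (inherits(x, "feature_cube_set")) x$values else x
  if (length(dim(v)) == 3L) v <- array(v, dim = c(1L, dim(v)))
  if (length(dim(v)) != 4L || dim(v)[2L] != dim(v)[3L])
    stopf("cube values must be an n x g x g x depth array")
  d <- dim(v)
  list(A0 = matrix(aperm(v, c(2L, 3L, 1L, 4L)), ncol = d[4L]),
       n = d[1L], g = d[2L], depth = d[4L])
}

## ---- parameters -------------------------------------------------------------

#' Initialise the parameters of the classifier
#'
#' He-initialised convolution kernels, Xavier-initialised dense layers, zero
#' biases, identity input standardisation (replaced when the stacked
#' autoencoder is pretrained). Deterministic in `seed`.
#'
#' @param config a [cae_config()].
#' @param input_depth number of band planes of the input cubes.
#' @param grid_size spatial grid side (default 9).
#' @param seed integer seed; defaults to the config's.
#' @return nested parameter list (`conv`, `sae`, `norm`, `softmax`).
#' @export
cae_init_params <- function(config, input_depth, grid_size = 9,
                            seed = config$seed) {
  if (!is_count(input_depth)) stopf("`input_depth` must be a positive integer")
  set.seed(seed)
  g2 <- grid_size^2
  cin <- input_depth
  conv <- list()
  for (cl in config$conv_layers) {
    cout <- cl[1L]; k <- cl[2L]
    sdev <- sqrt(2 / (k * k * cin))
    W <- lapply(seq_len(k * k), function(o)
      matrix(stats::rnorm(cin * cout, sd = sdev), cin, cout))
    conv[[length(conv) + 1L]] <- list(W = W, b = numeric(cout), k = k)
    cin <- cout
  }
  flat_dim <- g2 * cin
  h <- config$sae_hidden
  xavier <- function(din, dout) matrix(stats::rnorm(din * dout, sd = sqrt(1 / din)),
                                       din, dout)
  sae <- list(l1 = list(W = xavier(flat_dim, h[1L]), b = numeric(h[1L])),
              l2 = list(W = xavier(h[1L], h[2L]), b = numeric(h[2L])))
  norm <- list(l1 = list(mu = numeric(flat_dim), sd = rep(1, flat_dim)),
               l2 = list(mu = numeric(h[1L]), sd = rep(1, h[1L])))
  softmax <- list(W = xavier(h[2L], config$n_classes),
                  b = numeric(config$n_classes))
  list(conv = conv, sae = sae, norm = norm, softmax = softmax,
       grid_size = as.integer(grid_size), input_depth = as.integer(input_depth),
       flat_dim = as.integer(flat_dim))
}

params_geometry <- function(params) {
  lapply(params$conv, function(l)
    list(src = conv_sources(l$k, params$grid_size),
         inv = conv_sources(l$k, params$grid_size, sign = -1L)))
}

## ---- encoder ----------------------------------------------------------------

#' Run the convolutional encoder
#'
#' Applies the convolution stack (stride 1, zero 'same' padding, ReLU, no
#' pooling) and flattens the result; under the default architecture a 9x9x4
#' cube becomes a vector of length 9*9*64 = 5184 regardless of content.
#'
#' @param params parameters from [cae_init_params()] or a trained model's
#'   `$params`.
#' @param x a `feature_cube_set`, an n x g x g x depth array, or a single
#'   g x g x depth cube.
#' @param activation `"relu"` (default) or `"identity"`.
#' @return n x flat-length matrix of encoder features.
#' @export
cae_encode <- function(params, x, activation = "relu") {
  if (!is.null(params$params)) params <- params$params
  inp <- cubes_to_input(x)
  if (inp$g != params$grid_size)
    stopf("cube grid %d does not match encoder grid %d", inp$g, params$grid_size)
  if (inp$depth != params$input_depth)
    stopf("cube depth %d does not match encoder input depth %d",
          inp$depth, params$input_depth)
  geom <- params_geometry(params)
  A <- inp$A0
  g2 <- inp$g^2
  for (i in seq_along(params$conv))
    A <- conv_forward(A, params$conv[[i]], geom[[i]], inp$n, g2, activation)$out
  flatten_maps(A, inp$n, g2)
}

## ---- AdaDelta ---------------------------------------------------------------

adadelta_step <- function(params, grads, state, lr, rho, eps) {
  if (is.numeric(params)) {
    if (is.null(state)) state <- list(Eg = params * 0, Ed = params * 0)
    state$Eg <- rho * state$Eg + (1 - rho) * grads^2
    delta <- -sqrt(state$Ed + eps) / sqrt(state$Eg + eps) * grads * lr
    state$Ed <- rho * state$Ed + (1 - rho) * delta^2
    return(list(p = params + delta, s = state))
  }
  if (is.null(state)) state <- list()
  nms <- names(grads)
  for (i in seq_along(grads)) {
    if (is.null(grads[[i]])) next
    key <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
    st <- if (is.character(key) || key <= length(state)) state[[key]] else NULL
    r <- adadelta_step(params[[key]], grads[[i]], st, lr, rho, eps)
    params[[key]] <- r$p
    state[[key]] <- r$s
  }
  list(p = params, s = state)
}

## ---- stacked autoencoder pretraining ---------------------------------------

train_autoencoder <- function(X, hidden, epochs, batch_size, config) {
  din <- ncol(X); n <- nrow(X)
  enc <- list(W = matrix(stats::rnorm(din * hidden, sd = sqrt(1 / din)), din, hidden),
              b = numeric(hidden))
  dec <- list(W = matrix(stats::rnorm(hidden * din, sd = sqrt(1 / hidden)), hidden, din),
              b = numeric(din))
  params <- list(enc = enc, dec = dec)
  state <- NULL
  history <- numeric(0)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      B <- X[idx, , drop = FALSE]
      m <- nrow(B)
      H <- sigmoid(sweep(B %*% params$enc$W, 2L, params$enc$b, "+"))
      R <- sweep(H %*% params$dec$W, 2L, params$dec$b, "+")
      E <- R - B
      loss <- mean(E^2)
      dR <- 2 * E / (m * din)
      gdecW <- crossprod(H, dR); gdecb <- colSums(dR)
      dH <- dR %*% t(params$dec$W)
      if (config$sparsity) {
        rho <- config$sparsity_target
        rho_hat <- pmin(pmax(colMeans(H), 1e-8), 1 - 1e-8)
        dH <- dH + config$sparsity_weight *
          matrix((-rho / rho_hat + (1 - rho) / (1 - rho_hat)) / m,
                 m, hidden, byrow = TRUE)
        loss <- loss + config$sparsity_weight *
          sum(rho * log(rho / rho_hat) + (1 - rho) * log((1 - rho) / (1 - rho_hat)))
      }
      dZ <- dH * H * (1 - H)
      gencW <- crossprod(B, dZ); gencb <- colSums(dZ)
      grads <- list(enc = list(W = gencW, b = gencb),
                    dec = list(W = gdecW, b = gdecb))
      r <- adadelta_step(params, grads, state, 1.0,
                         config$adadelta_rho, config$adadelta_eps)
      params <- r$p; state <- r$s
      ep_loss <- ep_loss + loss; nb <- nb + 1L
    }
    history <- c(history, ep_loss / nb)
  }
  list(enc = params$enc, dec = params$dec, recon_history = history)
}

fit_norm <- function(X) {
  list(mu = colMeans(X),
       sd = pmax(sqrt(pmax(colMeans(X^2) - colMeans(X)^2, 0)), 1e-6))
}

apply_norm <- function(X, nrm) sweep(sweep(X, 2L, nrm$mu, "-"), 2L, nrm$sd, "/")

# batch normalisation (no learnable scale/shift): training mode standardises
# by the minibatch statistics; inference uses the running averages kept in
# the parameter list
bn_forward <- function(X, nrm = NULL) {
  if (!is.null(nrm)) return(list(Xhat = apply_norm(X, nrm)))
  st <- fit_norm(X)
  list(Xhat = apply_norm(X, st), mu = st$mu, sd = st$sd)
}

bn_backward <- function(dXhat, Xhat, sd) {
  adj <- sweep(dXhat, 2L, colMeans(dXhat), "-") -
    sweep(Xhat, 2L, colMeans(dXhat * Xhat), "*")
  sweep(adj, 2L, sd, "/")
}

update_running <- function(nrm, mu, sd, momentum = 0.9) {
  list(mu = momentum * nrm$mu + (1 - momentum) * mu,
       sd = momentum * nrm$sd + (1 - momentum) * sd)
}

#' Greedy layer-wise pretraining of the stacked autoencoder
#'
#' Trains the first autoencoder (input -> h1 -> input) to reconstruct the
#' standardised encoder features, freezes it, then trains the second
#' (h1 -> h2 -> h1) on the first layer's codes, again standardised. Hidden
#' units are sigmoid; decoders are linear and discarded after pretraining.
#' Reconstruction uses mean squared error under AdaDelta.
#'
#' @param encoded n x flat-length matrix of encoder outputs.
#' @param config a [cae_config()].
#' @param seed integer seed (defaults to the config's).
#' @return list with `sae` (encoder layers `l1`, `l2`), `norm`
#'   (standardisation statistics per layer) and `recon_history` (per-epoch
#'   reconstruction loss per autoencoder).
#' @export
pretrain_sae <- function(encoded, config = cae_config(), seed = config$seed) {
  if (!is.matrix(encoded) || nrow(encoded) < 2L)
    stopf("`encoded` must be a matrix with at least 2 rows")
  set.seed(seed)
  n1 <- fit_norm(encoded)
  X1 <- apply_norm(encoded, n1)
  ae1 <- train_autoencoder(X1, config$sae_hidden[1L], config$pretrain_epochs,
                           config$batch_size, config)
  H1 <- sigmoid(sweep(X1 %*% ae1$enc$W, 2L, ae1$enc$b, "+"))
  n2 <- fit_norm(H1)
  X2 <- apply_norm(H1, n2)
  ae2 <- train_autoencoder(X2, config$sae_hidden[2L], config$pretrain_epochs,
                           config$batch_size, config)
  list(sae = list(l1 = ae1$enc, l2 = ae2$enc),
       norm = list(l1 = n1, l2 = n2),
       recon_history = list(l1 = ae1$recon_history, l2 = ae2$recon_history))
}

## ---- full network -----------------------------------------------------------

net_forward <- function(params, geom, A0, n, g2, config, dropout_mask = NULL,
                        train_mode = FALSE) {
  conv_caches <- vector("list", length(params$conv))
  A <- A0
  for (i in seq_along(params$conv)) {
    conv_caches[[i]] <- conv_forward(A, params$conv[[i]], geom[[i]], n, g2,
                                     keep_gather = train_mode)
    A <- conv_caches[[i]]$out
  }
  F <- flatten_maps(A, n, g2)
  Fd <- if (is.null(dropout_mask)) F else F * dropout_mask
  bn1 <- bn_forward(Fd, if (train_mode) NULL else params$norm$l1)
  H1 <- sigmoid(sweep(bn1$Xhat %*% params$sae$l1$W, 2L, params$sae$l1$b, "+"))
  bn2 <- bn_forward(H1, if (train_mode) NULL else params$norm$l2)
  H2 <- sigmoid(sweep(bn2$Xhat %*% params$sae$l2$W, 2L, params$sae$l2$b, "+"))
  S <- sweep(H2 %*% params$softmax$W, 2L, params$softmax$b, "+")
  P <- softmax_prob(S)
  list(P = P, conv = conv_caches, bn1 = bn1, bn2 = bn2, H1 = H1, H2 = H2,
       dropout_mask = dropout_mask, train_mode = train_mode)
}

net_backward <- function(params, geom, fwd, Y, n, g2, config) {
  l2 <- config$l2_lambda
  dS <- (fwd$P - Y) / n
  gsW <- crossprod(fwd$H2, dS) + l2 * params$softmax$W
  gsb <- colSums(dS)
  dH2 <- dS %*% t(params$softmax$W)
  dZ2 <- dH2 * fwd$H2 * (1 - fwd$H2)
  g2W <- crossprod(fwd$bn2$Xhat, dZ2) + l2 * params$sae$l2$W
  g2b <- colSums(dZ2)
  dX2 <- dZ2 %*% t(params$sae$l2$W)
  dH1 <- if (fwd$train_mode) bn_backward(dX2, fwd$bn2$Xhat, fwd$bn2$sd)
         else sweep(dX2, 2L, params$norm$l2$sd, "/")
  dZ1 <- dH1 * fwd$H1 * (1 - fwd$H1)
  g1W <- crossprod(fwd$bn1$Xhat, dZ1) + l2 * params$sae$l1$W
  g1b <- colSums(dZ1)
  dX1 <- dZ1 %*% t(params$sae$l1$W)
  dF <- if (fwd$train_mode) bn_backward(dX1, fwd$bn1$Xhat, fwd$bn1$sd)
        else sweep(dX1, 2L, params$norm$l1$sd, "/")
  if (!is.null(fwd$dropout_mask)) dF <- dF * fwd$dropout_mask
  dA <- unflatten_maps(dF, n, g2)
  gconv <- vector("list", length(params$conv))
  for (i in rev(seq_along(params$conv))) {
    bk <- conv_backward(dA, params$conv[[i]], fwd$conv[[i]], geom[[i]], n, g2)
    dWpen <- bk$dW
    for (o in seq_along(dWpen))
      dWpen[[o]] <- dWpen[[o]] + l2 * params$conv[[i]]$W[[o]]
    gconv[[i]] <- list(W = dWpen, b = bk$db)
    dA <- bk$dA
  }
  list(conv = gconv,
       sae = list(l1 = list(W = g1W, b = g1b), l2 = list(W = g2W, b = g2b)),
       norm = NULL,
       softmax = list(W = gsW, b = gsb))
}

l2_penalty <- function(params, l2) {
  if (l2 <= 0) return(0)
  s <- sum(vapply(params$conv, function(l) sum(vapply(l$W, function(w) sum(w^2), 0)), 0))
  s <- s + sum(params$sae$l1$W^2) + sum(params$sae$l2$W^2) + sum(params$softmax$W^2)
  0.5 * l2 * s
}

run_supervised_epochs <- function(params, geom, state, A0_all, Y, labels,
                                  n, g2, config, n_epochs, phase, prev_acc) {
  flat_dim <- params$flat_dim
  history <- data.frame()
  for (ep in seq_len(n_epochs)) {
    rate <- schedule_learning_rate(prev_acc, config)
    mult <- lr_multiplier(rate, config)
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0L; nb <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      m <- length(idx)
      rows <- rep((idx - 1L) * g2, each = g2) + rep(seq_len(g2), times = m)
      A0 <- A0_all[rows, , drop = FALSE]
      mask <- if (config$dropout_rate > 0)
        matrix((stats::runif(m * flat_dim) >= config$dropout_rate) /
                 (1 - config$dropout_rate), m, flat_dim)
      else NULL
      fwd <- net_forward(params, geom, A0, m, g2, config, dropout_mask = mask,
                         train_mode = TRUE)
      loss <- cross_entropy_loss(fwd$P, Y[idx, , drop = FALSE]) +
        l2_penalty(params, config$l2_lambda)
      pred <- max.col(fwd$P, ties.method = "first") - 1L
      grads <- net_backward(params, geom, fwd, Y[idx, , drop = FALSE], m, g2, config)
      r <- adadelta_step(params, grads, state, mult,
                         config$adadelta_rho, config$adadelta_eps)
      params <- r$p; state <- r$s
      # running batch-norm statistics for inference, fitted on train data only
      params$norm$l1 <- update_running(params$norm$l1, fwd$bn1$mu, fwd$bn1$sd)
      params$norm$l2 <- update_running(params$norm$l2, fwd$bn2$mu, fwd$bn2$sd)
      ep_loss <- ep_loss + loss
      ep_correct <- ep_correct + sum(pred == labels[idx])
      nb <- nb + 1L
    }
    prev_acc <- ep_correct / n
    history <- rbind(history,
                     data.frame(phase = phase, epoch = ep,
                                loss = ep_loss / nb, accuracy = prev_acc,
                                lr = rate))
  }
  list(params = params, state = state, history = history, prev_acc = prev_acc)
}

#' Train the convolutional autoencoder classifier
#'
#' End-to-end training on labelled feature cubes: a short supervised warm-up
#' of the whole network, greedy layer-wise pretraining of the stacked
#' autoencoder on the warmed-up encoder's outputs (input standardisation
#' statistics fitted there, on training data only), then supervised
#' fine-tuning of encoder, SAE and softmax head with cross-entropy, dropout
#' on the encoder output, an L2 weight penalty, AdaDelta and the
#' accuracy-gated learning-rate schedule (re-evaluated each epoch from the
#' previous epoch's training accuracy). Deterministic under a fixed config
#' seed.
#'
#' @param cubes a labelled `feature_cube_set` containing both classes.
#' @param config a [cae_config()].
#' @return object of class `trained_cae`: `params`, `config`, `history`
#'   (per-epoch phase/loss/accuracy/learning-rate), `recon_history`, `seed`.
#' @export
train_cae <- function(cubes, config = cae_config()) {
  if (!inherits(cubes, "feature_cube_set")) stopf("`cubes` must be a feature_cube_set")
  labels <- cubes$labels
  if (length(unique(labels)) < 2L)
    stopf("training data contains a single class; need both")
  if (any(!labels %in% c(0L, 1L)) && config$n_classes == 2L)
    stopf("labels must be 0/1 for binary classification")
  inp <- cubes_to_input(cubes)
  n <- inp$n; g2 <- inp$g^2
  params <- cae_init_params(config, inp$depth, grid_size = inp$g,
                            seed = derive_seeds(config$seed, 4L)[1L])
  geom <- params_geometry(params)
  Y <- matrix(0, n, config$n_classes)
  Y[cbind(seq_len(n), labels + 1L)] <- 1

  seeds <- derive_seeds(config$seed, 4L)
  state <- NULL
  history <- data.frame()
  prev_acc <- 0

  set.seed(seeds[2L])
  if (config$warmup_epochs > 0L) {
    r <- run_supervised_epochs(params, geom, state, inp$A0, Y, labels, n, g2,
                               config, config$warmup_epochs, "warmup", prev_acc)
    params <- r$params; state <- r$state
    history <- rbind(history, r$history); prev_acc <- r$prev_acc
  }

  recon_history <- NULL
  if (config$pretrain_epochs > 0L) {
    encoded <- cae_encode(params, cubes)
    pre <- pretrain_sae(encoded, config, seed = seeds[3L])
    params$sae <- pre$sae
    params$norm <- pre$norm
    recon_history <- pre$recon_history
    state$sae <- NULL  # fresh optimizer state for the re-initialised layers
  }

  set.seed(seeds[4L])
  if (config$epochs > 0L) {
    r <- run_supervised_epochs(params, geom, state, inp$A0, Y, labels, n, g2,
                               config, config$epochs, "finetune", prev_acc)
    params <- r$params; state <- r$state
    history <- rbind(history, r$history); prev_acc <- r$prev_acc
  }

  structure(list(params = params, config = config, history = history,
                 recon_history = recon_history, classes = 0:1,
                 seed = config$seed),
            class = "trained_cae")
}

#' @export
print.trained_cae <- function(x, ...) {
  last <- if (nrow(x$history) > 0L) utils::tail(x$history, 1L) else NULL
  cat(sprintf("<trained_cae> %d conv layers, SAE %s; %d epochs trained%s\n",
              length(x$params$conv),
              paste(x$config$sae_hidden, collapse = "/"),
              nrow(x$history),
              if (is.null(last)) "" else
                sprintf(", final train accuracy %.3f", last$accuracy)))
  invisible(x)
}

#' Predict emotion classes for feature cubes
#'
#' Forward pass with dropout inactive; the predicted class is the argmax of
#' the softmax probabilities, with exact ties resolved to the lower class
#' index.
#'
#' @param object a `trained_cae`.
#' @param cubes a `feature_cube_set` or cube array matching the training
#'   geometry.
#' @param ... unused.
#' @return list with `class` (integer 0/1 vector) and `prob` (n x k matrix).
#' @export
predict.trained_cae <- function(object, cubes, ...) {
  inp <- cubes_to_input(cubes)
  if (inp$g != object$params$grid_size || inp$depth != object$params$input_depth)
    stopf("cube shape %dx%dx%d does not match the trained model (%dx%dx%d)",
          inp$g, inp$g, inp$depth, object$params$grid_size,
          object$params$grid_size, object$params$input_depth)
  geom <- params_geometry(object$params)
  fwd <- net_forward(object$params, geom, inp$A0, inp$n, inp$g^2,
                     object$config, dropout_mask = NULL)
  list(class = max.col(fwd$P, ties.method = "first") - 1L, prob = fwd$P)
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint holds parameters, the config snapshot and the seed; loading
#' fails loudly if the file is not a checkpoint.
#'
#' @param model a `trained_cae`.
#' @param path checkpoint file.
#' @return `path` (save) or the restored `trained_cae` (load).
#' @export
save_cae <- function(model, path) {
  if (!inherits(model, "trained_cae")) stopf("`model` must be a trained_cae")
  saveRDS(list(format = "eegcae_checkpoint", model = model), path, version = 2)
  invisible(path)
}

#' @rdname save_cae
#' @export
load_cae <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "eegcae_checkpoint"))
    stopf("'%s' is not an eegcae model checkpoint", path)
  obj$model
}
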