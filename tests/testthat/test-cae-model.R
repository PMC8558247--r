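test_that("softmax matches direct evaluation and is shift invariant", {
  expect_equal(softmax_prob(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax_prob(c(1, 2, 3)),
               exp(1:3) / sum(exp(1:3)), tolerance = 1e-12)
  expect_equal(round(softmax_prob(c(1, 2, 3)), 4), c(0.0900, 0.2447, 0.6652))
  z <- c(-2.2, 0.4, 5.1)
  expect_equal(softmax_prob(z), softmax_prob(z + 123.456), tolerance = 1e-12)
  # extreme scores stay finite thanks to the max shift
  expect_equal(sum(softmax_prob(c(1e4, 0))), 1)
  # matrix input: one distribution per row
  m <- softmax_prob(rbind(c(0, 0), c(1, 2, 3)[1:2]))
  expect_equal(rowSums(m), c(1, 1))
})

test_that("cross-entropy matches its closed forms", {
  perfect <- rbind(c(1, 0), c(0, 1))
  expect_equal(cross_entropy_loss(perfect, c(0L, 1L)), 0, tolerance = 1e-9)
  uniform <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(cross_entropy_loss(uniform, c(0L, 1L)), log(2), tolerance = 1e-12)
  two <- rbind(c(0.5, 0.5), c(0.25, 0.75))
  expect_equal(cross_entropy_loss(two, c(0L, 0L)),
               -(log(0.5) + log(0.25)) / 2, tolerance = 1e-12)
  expect_equal(cross_entropy_loss(two, c(0L, 0L)), 1.0397, tolerance = 1e-4)
  # probability floor keeps a zero-probability true class finite
  expect_lt(cross_entropy_loss(rbind(c(0, 1)), 0L), 28)
})

test_that("the learning-rate schedule follows its accuracy gates", {
  cc <- cae_config()
  expect_equal(schedule_learning_rate(0.50, cc), 1e-4)
  expect_equal(schedule_learning_rate(0.80, cc), 5e-5)
  expect_equal(schedule_learning_rate(0.90, cc), 1e-6)
  # boundary conventions: below first gate / at second gate
  expect_equal(schedule_learning_rate(0.6999, cc), 1e-4)
  expect_equal(schedule_learning_rate(0.85, cc), 5e-5)
  expect_equal(schedule_learning_rate(0.8501, cc), 1e-6)
  expect_error(schedule_learning_rate(1.2, cc), "\\[0, 1\\]")
})

test_that("encoder output length is 5184 under the published architecture", {
  cc <- cae_config()
  p <- cae_init_params(cc, input_depth = 4, seed = 2)
  x <- array(rnorm(9 * 9 * 4), dim = c(9, 9, 4))
  out <- cae_encode(p, x)
  expect_equal(dim(out), c(1L, 9L * 9L * 64L))
  expect_equal(ncol(out), 5184L)
  # zero input with zero biases encodes to zero
  z <- cae_encode(p, array(0, dim = c(9, 9, 4)))
  expect_true(all(z == 0))
  # depth mismatch fails
  expect_error(cae_encode(p, array(0, dim = c(9, 9, 3))), "depth")
})

test_that("a ones kernel with identity activation sums the input patch", {
  cc <- cae_config(conv_layers = list(c(1, 3)), sae_hidden = c(2, 2))
  p <- cae_init_params(cc, input_depth = 1, grid_size = 3, seed = 1)
  p$conv[[1]]$W <- lapply(p$conv[[1]]$W, function(w) w * 0 + 1)
  p$conv[[1]]$b <- 0
  x <- array(matrix(1:9, 3, 3), dim = c(3, 3, 1))
  out <- cae_encode(p, x, activation = "identity")
  # centre cell sees the whole 3x3 input
  centre <- matrix(out, 3, 3)[2, 2]
  expect_equal(centre, sum(1:9))
  # corner cell sees only its in-grid 2x2 neighbourhood
  expect_equal(matrix(out, 3, 3)[1, 1], sum(x[1:2, 1:2, 1]))
})

test_that("the batched encoder matches a brute-force sliding-window oracle", {
  cc <- cae_config(conv_layers = list(c(3, 4), c(5, 3), c(2, 1)),
                   sae_hidden = c(4, 2))
  p <- cae_init_params(cc, input_depth = 2, grid_size = 5, seed = 8)
  set.seed(9)
  for (i in 1:5) {
    x <- array(rnorm(5 * 5 * 2), dim = c(5, 5, 2))
    expect_equal(as.vector(cae_encode(p, x)), brute_force_encode(p, x),
                 tolerance = 1e-10)
  }
  # batched evaluation equals per-sample evaluation
  xs <- array(rnorm(3 * 5 * 5 * 2), dim = c(3, 5, 5, 2))
  batch <- cae_encode(p, xs)
  for (i in 1:3)
    expect_equal(batch[i, ], as.vector(cae_encode(p, xs[i, , , , drop = TRUE])),
                 tolerance = 1e-12)
})

test_that("analytic gradients match numerical differentiation", {
  cc <- cae_config(conv_layers = list(c(3, 3), c(2, 1)), sae_hidden = c(5, 4),
                   l2_lambda = 1e-3, dropout_rate = 0, seed = 9)
  p <- cae_init_params(cc, input_depth = 2, grid_size = 3, seed = 9)
  set.seed(10)
  n <- 6; g2 <- 9
  A0 <- matrix(rnorm(n * g2 * 2), n * g2, 2)
  y <- c(0L, 1L, 0L, 1L, 1L, 0L)
  Y <- matrix(0, n, 2); Y[cbind(1:n, y + 1L)] <- 1
  geom <- eegcae:::params_geometry(p)
  # training-mode forward: per-minibatch batch-norm statistics in the graph
  lossfn <- function(pp) {
    fwd <- eegcae:::net_forward(pp, geom, A0, n, g2, cc, train_mode = TRUE)
    cross_entropy_loss(fwd$P, Y) + eegcae:::l2_penalty(pp, cc$l2_lambda)
  }
  fwd <- eegcae:::net_forward(p, geom, A0, n, g2, cc, train_mode = TRUE)
  gr <- eegcae:::net_backward(p, geom, fwd, Y, n, g2, cc)
  h <- 1e-5
  pick <- function(get, set, ana, k = 6) {
    v <- get(p)
    for (i in sample(seq_along(v), min(k, length(v)))) {
      p1 <- set(p, replace(v, i, v[i] + h))
      p2 <- set(p, replace(v, i, v[i] - h))
      expect_equal(ana[i], (lossfn(p1) - lossfn(p2)) / (2 * h), tolerance = 1e-4)
    }
  }
  pick(function(p) p$softmax$W, function(p, v) { p$softmax$W[] <- v; p }, gr$softmax$W)
  pick(function(p) p$sae$l1$W, function(p, v) { p$sae$l1$W[] <- v; p }, gr$sae$l1$W)
  pick(function(p) p$sae$l2$b, function(p, v) { p$sae$l2$b <- v; p }, gr$sae$l2$b)
  pick(function(p) p$conv[[1]]$W[[4]],
       function(p, v) { p$conv[[1]]$W[[4]][] <- v; p }, gr$conv[[1]]$W[[4]])
  pick(function(p) p$conv[[2]]$W[[1]],
       function(p, v) { p$conv[[2]]$W[[1]][] <- v; p }, gr$conv[[2]]$W[[1]])
})

test_that("SAE pretraining reduces reconstruction error and is deterministic", {
  set.seed(20)
  X <- matrix(rnorm(80 * 30), 80, 30) %*% matrix(rnorm(30 * 30, sd = .3), 30, 30)
  cc <- cae_config(conv_layers = list(c(2, 3)), sae_hidden = c(10, 5),
                   pretrain_epochs = 15, batch_size = 40, seed = 6)
  a <- pretrain_sae(X, cc)
  b <- pretrain_sae(X, cc)
  expect_identical(a$sae, b$sae)
  expect_lt(tail(a$recon_history$l1, 1), a$recon_history$l1[1])
  expect_lt(tail(a$recon_history$l2, 1), a$recon_history$l2[1])
})

test_that("a rank-1 batch is reconstructed almost perfectly", {
  set.seed(21)
  u <- rnorm(20)
  X <- outer(rnorm(120), u)  # all rows proportional to u
  cc <- cae_config(conv_layers = list(c(2, 3)), sae_hidden = c(8, 4),
                   pretrain_epochs = 300, batch_size = 20, seed = 7)
  pre <- pretrain_sae(X, cc)
  X1 <- eegcae:::apply_norm(X, pre$norm$l1)
  H <- eegcae:::sigmoid(sweep(X1 %*% pre$sae$l1$W, 2, pre$sae$l1$b, "+"))
  # a 1-dimensional code suffices; residual far below the input variance
  expect_lt(tail(pre$recon_history$l1, 1), 0.01 * mean(X1^2))
})

test_that("training is seed-reproducible and predict is consistent", {
  cubes <- small_cubes()
  cc <- tiny_cae_config()
  m1 <- train_cae(cubes, cc)
  m2 <- train_cae(cubes, cc)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  p <- predict(m1, cubes)
  expect_equal(unname(rowSums(p$prob)), rep(1, length(p$class)), tolerance = 1e-12)
  expect_true(all(p$class %in% 0:1))
  # prediction is deterministic (dropout off at inference)
  p2 <- predict(m1, cubes)
  expect_identical(p, p2)
  # history bookkeeping matches the configured epochs
  expect_equal(nrow(m1$history), cc$warmup_epochs + cc$epochs)
  expect_error(train_cae(subset_cubes(cubes, which(cubes$labels == 0)), cc),
               "single class")
})

test_that("exact probability ties resolve to the lower class", {
  # max.col with ties.method "first" picks class 0 at (0.5, 0.5)
  P <- rbind(c(0.5, 0.5))
  expect_equal(max.col(P, ties.method = "first") - 1L, 0L)
})

test_that("checkpoints round-trip and reject foreign files", {
  cubes <- small_cubes()
  m <- train_cae(cubes, tiny_cae_config(epochs = 1, pretrain_epochs = 1))
  path <- withr::local_tempfile(fileext = ".rds")
  save_cae(m, path)
  back <- load_cae(path)
  expect_identical(back$params, m$params)
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(load_cae(bad), "checkpoint")
})
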