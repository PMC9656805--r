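test_that("reshape_for_cnn lays vectors on the documented grid", {
  expect_equal(cnn_grid_dims(4), list(h = 2L, w = 2L))
  expect_equal(cnn_grid_dims(15), list(h = 3L, w = 5L))
  expect_equal(cnn_grid_dims(5), list(h = 2L, w = 3L))
  g <- reshape_for_cnn(1:4)
  expect_equal(g, matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE))
  g5 <- reshape_for_cnn(1:5)
  expect_equal(dim(g5), c(2, 3))
  expect_equal(g5[2, 3], 0)               # zero tail pad
  expect_equal(as.numeric(t(g5))[1:5], 1:5)
  # batched variant agrees with the single-vector rule
  B <- reshape_for_cnn(rbind(1:5, 6:10))
  expect_equal(dim(B), c(2, 3, 1, 2))
  expect_equal(B[, , 1, 1], g5)
  expect_error(cnn_grid_dims(0), "at least one")
})

test_that("forward pass yields 8 logits on admissible grids", {
  for (m in c(4, 15, 16, 72)) {
    d <- cnn_grid_dims(m)
    model <- cnn_init(cnn_config(seed = 5), d$h, d$w)
    X <- reshape_for_cnn(matrix(rnorm(3 * m), 3, m))
    out <- cnn_forward(model, X)
    expect_equal(dim(out$logits), c(3, 8))
    expect_true(all(is.finite(out$logits)))
  }
})

test_that("degenerate final layer gives uniform logits, ties to class 0", {
  d <- cnn_grid_dims(12)
  model <- cnn_init(cnn_config(seed = 6), d$h, d$w)
  model$fc$W[] <- 0
  model$fc$b[] <- 0
  X <- matrix(rnorm(48), 4, 12)
  lg <- cnn_forward(model, reshape_for_cnn(X))$logits
  expect_equal(lg, matrix(0, 4, 8))
  expect_equal(predict(model, X), rep(0L, 4))
})

test_that("training is reproducible given the config seed", {
  set.seed(71)
  X <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 3), 30))
  y <- rep(0:1, each = 30)
  cfg <- cnn_config(epochs = 8, n_classes = 2, seed = 17)
  m1 <- cnn_train(X, y, cfg)
  m2 <- cnn_train(X, y, cfg)
  expect_identical(m1$fc$W, m2$fc$W)
  expect_identical(m1$conv[[3]]$W, m2$conv[[3]]$W)
  expect_identical(predict(m1, X), predict(m2, X))
  # and it learns the separable toy problem
  expect_gt(mean(predict(m1, X) == y), 0.9)
})

test_that("architecture defaults match the fixed design", {
  cfg <- cnn_config()
  expect_equal(cfg$conv_channels, c(16L, 32L, 32L))
  expect_equal(cfg$kernel, 2L)
  expect_equal(cfg$stride, 1L)
  expect_equal(cfg$padding, 1L)
  expect_equal(cfg$pool_after, c(1L, 2L))
  expect_equal(cfg$dropout, 0.5)
  expect_equal(cfg$learning_rate, 0.01)
  expect_equal(cfg$epochs, 20L)
  expect_equal(cfg$batch_size, 40L)
  d <- cnn_grid_dims(4)
  model <- cnn_init(cnn_config(seed = 1), d$h, d$w)
  expect_equal(dim(model$conv[[1]]$W), c(2, 2, 1, 16))
  expect_equal(dim(model$conv[[2]]$W), c(2, 2, 16, 32))
  expect_equal(dim(model$conv[[3]]$W), c(2, 2, 32, 32))
  # spatial trace for 2x2 input: conv->3x3, pool->1x1, conv->2x2,
  # pool->1x1, conv->2x2; flatten = 2*2*32
  expect_equal(model$n_flat, 128)
})

test_that("gradients match finite differences (no dropout)", {
  set.seed(72)
  X <- matrix(rnorm(10 * 6), 10, 6)
  y <- sample(0:1, 10, TRUE)
  cfg <- cnn_config(epochs = 1, batch_size = 10, n_classes = 2, seed = 9,
                    dropout = 0)
  d <- cnn_grid_dims(ncol(X))
  model <- cnn_init(cfg, d$h, d$w)
  Xb <- reshape_for_cnn(X)
  loss_of <- function(m) {
    fwd <- cnn_forward(m, Xb, training = TRUE)
    P <- exp(fwd$logits - apply(fwd$logits, 1, max))
    P <- P / rowSums(P)
    -mean(log(P[cbind(1:10, y + 1)]))
  }
  lr <- 1e-6
  st <- graspADL:::.cnn_step(model, Xb, y, lr = lr)
  eps <- 1e-5
  # fully connected weights
  g_fc <- (model$fc$W - st$model$fc$W) / lr
  for (k in 1:3) {
    i <- sample(nrow(model$fc$W), 1); j <- sample(2, 1)
    mp <- model; mp$fc$W[i, j] <- mp$fc$W[i, j] + eps
    mm <- model; mm$fc$W[i, j] <- mm$fc$W[i, j] - eps
    expect_equal(g_fc[i, j], (loss_of(mp) - loss_of(mm)) / (2 * eps),
                 tolerance = 1e-4)
  }
  # first conv layer weights (through pool/BN/ReLU twice)
  g_c1 <- (model$conv[[1]]$W - st$model$conv[[1]]$W) / lr
  for (k in 1:3) {
    ii <- c(sample(2, 1), sample(2, 1), 1, sample(16, 1))
    mp <- model
    mp$conv[[1]]$W[ii[1], ii[2], ii[3], ii[4]] <-
      mp$conv[[1]]$W[ii[1], ii[2], ii[3], ii[4]] + eps
    mm <- model
    mm$conv[[1]]$W[ii[1], ii[2], ii[3], ii[4]] <-
      mm$conv[[1]]$W[ii[1], ii[2], ii[3], ii[4]] - eps
    expect_equal(g_c1[ii[1], ii[2], ii[3], ii[4]],
                 (loss_of(mp) - loss_of(mm)) / (2 * eps), tolerance = 1e-4)
  }
})
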