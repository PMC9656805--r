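# Small convolutional network for grasp-feature grids.
#
# Architecture (fixed by default, overridable via cnn_config):
#   conv(1 -> 16, 2x2, stride 1, pad 1) + batch-norm + ReLU + maxpool 2x2
#   conv(16 -> 32, 2x2, stride 1, pad 1) + batch-norm + ReLU + maxpool 2x2
#   conv(32 -> 32, 2x2, stride 1, pad 1) + batch-norm + ReLU
#   flatten -> linear(-> n_classes), 50% dropout on the output during
#   training (the dropout sits after the linear map by design).
# Trained with plain SGD on the softmax cross-entropy, lr 0.01, 20 epochs,
# batches of 40. Everything is vectorised base R: feature grids are tiny
# (a few rows/columns), so matrix multiplications dominate and no compiled
# tensor library is needed.
#
# Activations are arrays (H, W, C, B). Convolutions use the shifted-slice
# formulation: a 2x2/stride-1 convolution is the sum of four shifted
# pointwise channel mixes, each a single matrix product.

#' CNN configuration
#'
#' Defaults follow the fixed architecture above.
#'
#' @param conv_channels Output channels of the three conv layers.
#' @param kernel Conv kernel edge (2).
#' @param stride Conv stride (1).
#' @param padding Conv zero padding (1).
#' @param pool_after Layers followed by 2x2/stride-2 max pooling.
#' @param dropout Dropout probability on the logits during training.
#' @param learning_rate,epochs,batch_size SGD hyperparameters.
#' @param n_classes Number of output classes.
#' @param seed Integer seed for weight init and batch shuffling.
#' @return List of class `cnn_config`.
#' @export
cnn_config <- function(conv_channels = c(16L, 32L, 32L), kernel = 2L,
                       stride = 1L, padding = 1L, pool_after = c(1L, 2L),
                       dropout = 0.5, learning_rate = 0.01, epochs = 20L,
                       batch_size = 40L, n_classes = 8L, seed = 1L) {
  stopifnot(length(conv_channels) == 3, kernel == 2L, stride == 1L,
            padding == 1L, dropout >= 0, dropout < 1, learning_rate > 0,
            epochs >= 1, batch_size >= 2, n_classes >= 2)
  structure(list(conv_channels = as.integer(conv_channels), kernel = 2L,
                 stride = 1L, padding = 1L,
                 pool_after = as.integer(pool_after), dropout = dropout,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 n_classes = as.integer(n_classes), seed = as.integer(seed)),
            class = "cnn_config")
}

#' Lay a feature vector onto a near-square 2D grid
#'
#' Row-major fill of an h x w grid with `h = floor(sqrt(m))` and
#' `w = ceiling(m / h)`; trailing cells are zero-padded. This is the
#' deterministic convention used to feed feature vectors to the 2x2
#' convolutions.
#'
#' @param sample Numeric vector (length m >= 1), or a matrix of samples in
#'   rows.
#' @return For a vector, an h x w matrix; for a matrix, an array
#'   (h, w, 1, n_samples).
#' @export
reshape_for_cnn <- function(sample) {
  if (is.matrix(sample)) {
    d <- cnn_grid_dims(ncol(sample))
    out <- array(0, c(d$h, d$w, 1L, nrow(sample)))
    padded <- cbind(sample,
                    matrix(0, nrow(sample), d$h * d$w - ncol(sample)))
    # row-major per sample: fill transposed grid then transpose via aperm
    out[, , 1L, ] <- aperm(array(t(padded), c(d$w, d$h, nrow(sample))),
                           c(2, 1, 3))
    return(out)
  }
  m <- length(sample)
  d <- cnn_grid_dims(m)
  matrix(c(sample, numeric(d$h * d$w - m)), d$h, d$w, byrow = TRUE)
}

#' Grid dimensions used by [reshape_for_cnn()]
#' @param m Feature vector length.
#' @return List with `h` and `w`.
#' @export
cnn_grid_dims <- function(m) {
  if (m < 1) stop("feature vector must have at least one component")
  h <- max(1L, floor(sqrt(m)))
  w <- as.integer(ceiling(m / h))
  list(h = as.integer(h), w = w)
}

# ---- layer primitives -----------------------------------------------------

.conv_fwd <- function(A, W, b) {
  d <- dim(A); H <- d[1]; Wd <- d[2]; Cin <- d[3]; B <- d[4]
  Ho <- H + 1L; Wo <- Wd + 1L        # k=2, s=1, p=1
  Ap <- array(0, c(H + 2L, Wd + 2L, Cin, B))
  Ap[2:(H + 1), 2:(Wd + 1), , ] <- A
  Cout <- dim(W)[4]
  acc <- matrix(0, Ho * Wo * B, Cout)
  for (di in 0:1) for (dj in 0:1) {
    S <- Ap[di + seq_len(Ho), dj + seq_len(Wo), , , drop = FALSE]
    Sm <- matrix(aperm(S, c(1, 2, 4, 3)), ncol = Cin)
    acc <- acc + Sm %*% matrix(W[di + 1, dj + 1, , ], Cin, Cout)
  }
  acc <- sweep(acc, 2, b, "+")
  out <- aperm(array(acc, c(Ho, Wo, B, Cout)), c(1, 2, 4, 3))
  list(out = out, Ap = Ap)
}

.conv_bwd <- function(dOut, cache, W) {
  Ap <- cache$Ap
  dp <- dim(Ap); Cin <- dp[3]; B <- dp[4]
  d <- dim(dOut); Ho <- d[1]; Wo <- d[2]; Cout <- d[3]
  dOutm <- matrix(aperm(dOut, c(1, 2, 4, 3)), ncol = Cout)
  dW <- array(0, dim(W)); db <- colSums(dOutm)
  dAp <- array(0, dp)
  for (di in 0:1) for (dj in 0:1) {
    S <- Ap[di + seq_len(Ho), dj + seq_len(Wo), , , drop = FALSE]
    Sm <- matrix(aperm(S, c(1, 2, 4, 3)), ncol = Cin)
    dW[di + 1, dj + 1, , ] <- crossprod(Sm, dOutm)
    dSm <- dOutm %*% t(matrix(W[di + 1, dj + 1, , ], Cin, Cout))
    dS <- aperm(array(dSm, c(Ho, Wo, B, Cin)), c(1, 2, 4, 3))
    dAp[di + seq_len(Ho), dj + seq_len(Wo), , ] <-
      dAp[di + seq_len(Ho), dj + seq_len(Wo), , , drop = FALSE] + dS
  }
  H <- dp[1] - 2L; Wd <- dp[2] - 2L
  list(dA = dAp[2:(H + 1), 2:(Wd + 1), , , drop = FALSE], dW = dW, db = db)
}

.bn_fwd <- function(A, bn, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(A); C <- d[3]
  Am <- matrix(aperm(A, c(1, 2, 4, 3)), ncol = C)   # rows: H*W*B
  if (training) {
    mu <- colMeans(Am)
    va <- colMeans(Am^2) - mu^2                     # biased batch variance
    nr <- nrow(Am)
    unb <- if (nr > 1) va * nr / (nr - 1) else va
    bn$running_mean <- (1 - momentum) * bn$running_mean + momentum * mu
    bn$running_var <- (1 - momentum) * bn$running_var + momentum * unb
  } else {
    mu <- bn$running_mean
    va <- bn$running_var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(Am, 2, mu, "-"), 2, istd, "*")
  ym <- sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
  out <- aperm(array(ym, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(out = out, bn = bn, cache = list(xhat = xhat, istd = istd, dims = d))
}

.bn_bwd <- function(dOut, cache, bn) {
  d <- cache$dims; C <- d[3]
  dym <- matrix(aperm(dOut, c(1, 2, 4, 3)), ncol = C)
  xhat <- cache$xhat; istd <- cache$istd
  N <- nrow(dym)
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, bn$gamma, "*")
  # dx = istd * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)), per channel
  dxm <- sweep(sweep(dxhat, 2, colMeans(dxhat), "-") -
                 xhat * rep(colMeans(dxhat * xhat), each = N),
               2, istd, "*")
  dA <- aperm(array(dxm, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(dA = dA, dgamma = dgamma, dbeta = dbeta)
}

.pool_fwd <- function(A) {
  d <- dim(A); H <- d[1]; W <- d[2]
  Hp <- H %/% 2L; Wp <- W %/% 2L
  if (Hp < 1 || Wp < 1) {
    stop("feature map ", H, "x", W, " too small for 2x2 max pooling")
  }
  r <- seq.int(1L, by = 2L, length.out = Hp)
  cc <- seq.int(1L, by = 2L, length.out = Wp)
  S <- list(A[r, cc, , , drop = FALSE], A[r + 1, cc, , , drop = FALSE],
            A[r, cc + 1, , , drop = FALSE], A[r + 1, cc + 1, , , drop = FALSE])
  M <- pmax(S[[1]], S[[2]], S[[3]], S[[4]])
  claimed <- array(FALSE, dim(M))
  masks <- vector("list", 4)
  for (k in 1:4) {
    mk <- (S[[k]] == M) & !claimed
    claimed <- claimed | mk
    masks[[k]] <- mk
  }
  list(out = M, masks = masks, in_dim = d, r = r, cc = cc)
}

.pool_bwd <- function(dOut, cache) {
  dA <- array(0, cache$in_dim)
  r <- cache$r; cc <- cache$cc
  off <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (k in 1:4) {
    dA[r + off[[k]][1], cc + off[[k]][2], , ] <-
      dA[r + off[[k]][1], cc + off[[k]][2], , , drop = FALSE] +
      dOut * cache$masks[[k]]
  }
  dA
}

# ---- model ---------------------------------------------------------------

.bn_new <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C),
       running_mean = rep(0, C), running_var = rep(1, C))
}

#' Initialise CNN parameters for a given input grid
#'
#' Errors (naming the minimum usable feature count) when the grid cannot
#' survive the two 2x2 poolings.
#'
#' @param cfg A [cnn_config()].
#' @param h,w Input grid dimensions from [cnn_grid_dims()].
#' @return List of class `cnn_model` with weights, batch-norm state and
#'   the flattened size.
#' @export
cnn_init <- function(cfg, h, w) {
  ch <- c(1L, cfg$conv_channels)
  # spatial trace: conv(k2,s1,p1) adds 1; pool halves (floor)
  dims <- c(h, w)
  for (l in 1:3) {
    dims <- dims + 1L
    if (l %in% cfg$pool_after) {
      dims <- dims %/% 2L
      if (any(dims < 1L)) {
        stop("input grid ", h, "x", w, " too small to survive 2x2 pooling; ",
             "need a feature vector of length >= 2")
      }
    }
  }
  set.seed(cfg$seed)
  conv <- lapply(1:3, function(l) {
    fan_in <- 4L * ch[l]
    list(W = array(rnorm(4 * ch[l] * ch[l + 1], sd = sqrt(2 / fan_in)),
                   c(2, 2, ch[l], ch[l + 1])),
         b = rep(0, ch[l + 1]))
  })
  n_flat <- dims[1] * dims[2] * ch[4]
  fc <- list(W = matrix(rnorm(n_flat * cfg$n_classes,
                              sd = sqrt(1 / n_flat)),
                        n_flat, cfg$n_classes),
             b = rep(0, cfg$n_classes))
  structure(list(conv = conv, bn = lapply(cfg$conv_channels, .bn_new),
                 fc = fc, cfg = cfg, in_h = h, in_w = w, n_flat = n_flat),
            class = "cnn_model")
}

#' Forward pass of the CNN
#'
#' @param model A `cnn_model`.
#' @param X Input array (h, w, 1, batch) from [reshape_for_cnn()].
#' @param training Logical; training mode uses batch statistics and
#'   dropout, evaluation mode uses running statistics and no dropout.
#' @return List with `logits` (batch x n_classes), the possibly updated
#'   `model` (running batch-norm state) and, in training mode, the caches
#'   needed by the backward pass.
#' @export
cnn_forward <- function(model, X, training = FALSE) {
  cfg <- model$cfg
  A <- X
  caches <- list()
  for (l in 1:3) {
    cv <- .conv_fwd(A, model$conv[[l]]$W, model$conv[[l]]$b)
    bnr <- .bn_fwd(cv$out, model$bn[[l]], training)
    model$bn[[l]] <- bnr$bn
    relu_mask <- bnr$out > 0
    A <- bnr$out * relu_mask
    pool_cache <- NULL
    if (l %in% cfg$pool_after) {
      pl <- .pool_fwd(A)
      A <- pl$out
      pool_cache <- pl[c("masks", "in_dim", "r", "cc")]
    }
    caches[[l]] <- list(conv = cv["Ap"], bn = bnr$cache,
                        relu_mask = relu_mask, pool = pool_cache,
                        out_dim = dim(A))
  }
  B <- dim(A)[4]
  Xf <- t(matrix(A, ncol = B))          # batch x n_flat (column-major flat)
  logits <- sweep(Xf %*% model$fc$W, 2, model$fc$b, "+")
  drop_mask <- NULL
  if (training && cfg$dropout > 0) {
    drop_mask <- matrix(
      (runif(length(logits)) >= cfg$dropout) / (1 - cfg$dropout),
      nrow(logits), ncol(logits))
    logits <- logits * drop_mask
  }
  list(logits = logits, model = model,
       caches = if (training) list(layers = caches, Xf = Xf,
                                   drop_mask = drop_mask,
                                   conv_out_dim = dim(A)))
}

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# One SGD step on a batch; returns updated model and the batch loss.
.cnn_step <- function(model, X, y01, lr) {
  fwd <- cnn_forward(model, X, training = TRUE)
  model <- fwd$model
  P <- .softmax(fwd$logits)
  B <- nrow(P)
  loss <- -mean(log(pmax(P[cbind(seq_len(B), y01 + 1L)], 1e-12)))
  dlog <- P
  dlog[cbind(seq_len(B), y01 + 1L)] <- dlog[cbind(seq_len(B), y01 + 1L)] - 1
  dlog <- dlog / B
  if (!is.null(fwd$caches$drop_mask)) dlog <- dlog * fwd$caches$drop_mask
  Xf <- fwd$caches$Xf
  dWfc <- crossprod(Xf, dlog)
  dbfc <- colSums(dlog)
  dXf <- dlog %*% t(model$fc$W)
  dA <- array(t(dXf), fwd$caches$conv_out_dim)
  for (l in 3:1) {
    cch <- fwd$caches$layers[[l]]
    if (!is.null(cch$pool)) dA <- .pool_bwd(dA, cch$pool)
    dA <- dA * cch$relu_mask
    bnb <- .bn_bwd(dA, cch$bn, model$bn[[l]])
    cvb <- .conv_bwd(bnb$dA, cch$conv, model$conv[[l]]$W)
    model$bn[[l]]$gamma <- model$bn[[l]]$gamma - lr * bnb$dgamma
    model$bn[[l]]$beta <- model$bn[[l]]$beta - lr * bnb$dbeta
    model$conv[[l]]$W <- model$conv[[l]]$W - lr * cvb$dW
    model$conv[[l]]$b <- model$conv[[l]]$b - lr * cvb$db
    dA <- cvb$dA
  }
  model$fc$W <- model$fc$W - lr * dWfc
  model$fc$b <- model$fc$b - lr * dbfc
  list(model = model, loss = loss)
}

#' Train the CNN on a feature matrix
#'
#' @param X Numeric n x m matrix (standardized features).
#' @param y Integer class labels (0-based).
#' @param cfg A [cnn_config()]; `cfg$seed` fixes weight initialisation and
#'   batch order, making training run-to-run reproducible on one machine.
#' @return Fitted `cnn_model` (with an attached `loss_history`).
#' @export
cnn_train <- function(X, y, cfg = cnn_config()) {
  X <- as.matrix(X); y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y >= 0), all(y < cfg$n_classes))
  d <- cnn_grid_dims(ncol(X))
  model <- cnn_init(cfg, d$h, d$w)      # seeds the RNG
  n <- nrow(X)
  losses <- numeric(0)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    for (s in seq.int(1L, n, by = cfg$batch_size)) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
      if (length(idx) < 2L) next       # batch-norm needs >= 2 samples
      Xb <- reshape_for_cnn(X[idx, , drop = FALSE])
      st <- .cnn_step(model, Xb, y[idx], cfg$learning_rate)
      model <- st$model
      losses <- c(losses, st$loss)
    }
  }
  attr(model, "loss_history") <- losses
  model
}

#' Predict classes with a trained CNN
#'
#' Evaluation mode: frozen batch-norm statistics, no dropout. Argmax ties
#' are broken toward the lowest class index.
#'
#' @param object A fitted `cnn_model`.
#' @param newdata Feature matrix (n x m).
#' @param ... Unused.
#' @return Integer vector of 0-based class predictions.
#' @export
predict.cnn_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  n <- nrow(newdata)
  out <- integer(n)
  step <- 256L
  for (s in seq.int(1L, n, by = step)) {
    idx <- s:min(s + step - 1L, n)
    Xb <- reshape_for_cnn(newdata[idx, , drop = FALSE])
    lg <- cnn_forward(object, Xb, training = FALSE)$logits
    out[idx] <- max.col(lg, ties.method = "first") - 1L
  }
  out
}
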