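# RBF-kernel support vector classification.
#
# Multiclass handling is one-vs-one with majority voting (ties broken by
# the lowest class index), the convention of the mainstream SVM libraries.
# The binary subproblems are solved by the deterministic SMO solver in
# src/svm_smo.cpp, so fitted models and predictions are bit-reproducible.

#' SVM configuration
#'
#' @param C Regularization weight (> 0, default 10).
#' @param gamma RBF kernel width, or `"scale"` for `1 / (m * var(X))`
#'   (variance pooled over all entries of the training matrix).
#' @param eps SMO stopping tolerance (KKT violation gap).
#' @return List of class `svm_config`.
#' @export
svm_config <- function(C = 10, gamma = "scale", eps = 1e-3) {
  stopifnot(C > 0)
  if (is.numeric(gamma)) stopifnot(gamma > 0)
  structure(list(C = C, gamma = gamma, eps = eps), class = "svm_config")
}

.resolve_gamma <- function(gamma, X) {
  if (is.numeric(gamma)) return(gamma)
  if (identical(gamma, "scale")) {
    v <- mean(X^2) - mean(X)^2        # population variance of all entries
    if (v < 1e-12) v <- 1
    return(1 / (ncol(X) * v))
  }
  stop("gamma must be a positive number or \"scale\"")
}

.rbf_kernel <- function(A, B, gamma) {
  exp(-gamma * row_sq_dist(A, B))
}

#' Fit a multiclass RBF-SVM
#'
#' @param X Numeric n x m matrix (standardized features).
#' @param y Integer class labels (0-based).
#' @param config An [svm_config()].
#' @return Object of class `svm_rbf` with one binary SMO solution per
#'   class pair.
#' @export
svm_rbf <- function(X, y, config = svm_config()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y))
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least two classes to fit an SVM")
  gamma <- .resolve_gamma(config$gamma, X)
  pairs <- utils::combn(classes, 2)
  models <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    c1 <- pairs[1, p]; c2 <- pairs[2, p]
    idx <- which(y == c1 | y == c2)
    yy <- ifelse(y[idx] == c1, 1L, -1L)
    Xi <- X[idx, , drop = FALSE]
    K <- .rbf_kernel(Xi, Xi, gamma)
    sol <- smo_solve(K, yy, config$C, config$eps)
    sv <- which(sol$alpha > 1e-8)
    models[[p]] <- list(c1 = c1, c2 = c2, sv_x = Xi[sv, , drop = FALSE],
                        coef = sol$alpha[sv] * yy[sv], b = sol$b,
                        converged = sol$converged)
  }
  structure(list(models = models, classes = classes, gamma = gamma,
                 config = config),
            class = "svm_rbf")
}

#' Predict classes with a fitted RBF-SVM
#'
#' @param object A fitted `svm_rbf`.
#' @param newdata Numeric matrix with the training columns.
#' @param ... Unused.
#' @return Integer vector of predicted class labels (0-based).
#' @export
predict.svm_rbf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  votes <- matrix(0L, nrow(newdata), length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (mdl in object$models) {
    f <- as.numeric(.rbf_kernel(newdata, mdl$sv_x, object$gamma) %*%
                      mdl$coef) + mdl$b
    winner <- ifelse(f > 0, mdl$c1, mdl$c2)
    for (cls in c(mdl$c1, mdl$c2)) {
      votes[, as.character(cls)] <- votes[, as.character(cls)] +
        (winner == cls)
    }
  }
  # ties resolved toward the lowest class index by which.max
  object$classes[apply(votes, 1, which.max)]
}

#' Binary decision values of the one-vs-one subproblems
#'
#' Mainly for tests: exposes `f(x)` for each class pair.
#'
#' @param object A fitted `svm_rbf`.
#' @param newdata Feature matrix.
#' @return Matrix n x n_pairs of decision values.
#' @export
decision_values <- function(object, newdata) {
  newdata <- as.matrix(newdata)
  out <- vapply(object$models, function(mdl) {
    as.numeric(.rbf_kernel(newdata, mdl$sv_x, object$gamma) %*% mdl$coef) +
      mdl$b
  }, numeric(nrow(newdata)))
  matrix(out, nrow = nrow(newdata))
}
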