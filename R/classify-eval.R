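# Cross-validated evaluation: fold construction, confusion-matrix metrics
# and the SVM / CNN evaluation drivers.

#' Assign samples to k cross-validation folds
#'
#' Two split units are supported. `row_stratified` (default) shuffles
#' within each class and deals rows round-robin, preserving class
#' proportions within one sample per fold; it mirrors the common practice
#' of splitting at the sampling-point level, but note that frames from one
#' trial then appear on both sides of a split. `group_by_trial` keeps all
#' rows of a trial in one fold (no trial straddles folds), the
#' conservative choice when trials contain near-duplicate frames.
#'
#' @param fm A `feature_matrix`.
#' @param k Number of folds (default 5).
#' @param mode `"row_stratified"` or `"group_by_trial"`.
#' @param seed Integer seed; the assignment is deterministic given it.
#' @return Integer vector of fold ids (1..k), one per row.
#' @export
make_folds <- function(fm, k = 5L, mode = c("row_stratified",
                                            "group_by_trial"),
                       seed = 1L) {
  mode <- match.arg(mode)
  k <- as.integer(k)
  stopifnot(inherits(fm, "feature_matrix"), k >= 2)
  n <- nrow(fm$values)
  set.seed(as.integer(seed))
  fold <- integer(n)
  if (mode == "row_stratified") {
    for (cls in unique(fm$labels)) {
      idx <- which(fm$labels == cls)
      if (length(idx) < k) {
        stop("class ", cls, " has ", length(idx),
             " samples; need at least k = ", k, " for stratified folds")
      }
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    grp <- unique(fm$groups)
    grp <- grp[sample.int(length(grp))]
    gfold <- rep_len(seq_len(k), length(grp))
    fold <- gfold[match(fm$groups, grp)]
  }
  # every training split must still contain every class
  for (f in seq_len(k)) {
    tr_classes <- unique(fm$labels[fold != f])
    if (length(setdiff(unique(fm$labels), tr_classes)) > 0) {
      stop("fold ", f, " would leave a class absent from training")
    }
  }
  fold
}

#' Accuracy and macro precision/recall/F1 from a confusion matrix
#'
#' Rows are the true classes, columns the predicted classes. Per class:
#' precision = diagonal / column sum, recall = diagonal / row sum, F1 =
#' harmonic mean; macro metrics are unweighted means over classes. A class
#' with a zero denominator contributes 0 to the macro average, with a
#' warning.
#'
#' @param confusion Square matrix of non-negative counts.
#' @return Named list: `accuracy`, `macro_precision`, `macro_recall`,
#'   `macro_f1` (all in \[0, 1\]).
#' @export
compute_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop("confusion must be square")
  if (any(confusion < 0)) stop("confusion counts must be non-negative")
  diagc <- diag(confusion)
  rowc <- rowSums(confusion)
  colc <- colSums(confusion)
  prec <- ifelse(colc > 0, diagc / colc, 0)
  rec <- ifelse(rowc > 0, diagc / rowc, 0)
  if (any(colc == 0) || any(rowc == 0)) {
    warning("class(es) with zero denominator contribute 0 to macro metrics")
  }
  denom <- prec + rec
  f1 <- ifelse(denom > 0, 2 * prec * rec / denom, 0)
  list(accuracy = sum(diagc) / sum(confusion),
       macro_precision = mean(prec), macro_recall = mean(rec),
       macro_f1 = mean(f1))
}

.empty_confusion <- function(n_classes) {
  matrix(0, n_classes, n_classes,
         dimnames = list(true = seq_len(n_classes) - 1L,
                         predicted = seq_len(n_classes) - 1L))
}

.eval_result <- function(per_fold, confusion, folds, config, model_kind) {
  agg <- compute_metrics(confusion)
  structure(list(model = model_kind,
                 per_fold = per_fold,
                 mean = as.list(colMeans(
                   do.call(rbind, lapply(per_fold, unlist)))),
                 pooled = agg, confusion = confusion, folds = folds,
                 config = config),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result: %s, %d folds>\n", x$model, length(x$per_fold)))
  cat(sprintf(
    "  mean over folds: acc %.1f%%, macroP %.1f%%, macroR %.1f%%, macroF1 %.1f%%\n",
    100 * x$mean$accuracy, 100 * x$mean$macro_precision,
    100 * x$mean$macro_recall, 100 * x$mean$macro_f1))
  cat(sprintf(
    "  pooled:          acc %.1f%%, macroP %.1f%%, macroR %.1f%%, macroF1 %.1f%%\n",
    100 * x$pooled$accuracy, 100 * x$pooled$macro_precision,
    100 * x$pooled$macro_recall, 100 * x$pooled$macro_f1))
  invisible(x)
}

# Shared CV driver: fit_fun(Xtr, ytr) -> model; predictions via predict().
.cv_eval <- function(fm, folds, fit_fun, config, model_kind,
                     standardize_scope = c("fold", "global"),
                     n_classes = 8L) {
  standardize_scope <- match.arg(standardize_scope)
  stopifnot(inherits(fm, "feature_matrix"),
            length(folds) == nrow(fm$values))
  if (standardize_scope == "global") fm <- standardize(fm)
  ks <- sort(unique(folds))
  per_fold <- vector("list", length(ks))
  confusion <- .empty_confusion(n_classes)
  for (f in seq_along(ks)) {
    te <- folds == ks[f]
    tr <- !te
    if (length(unique(fm$labels[tr])) < 2) {
      stop("fold ", ks[f], ": training split is degenerate (single class)")
    }
    if (standardize_scope == "fold") {
      sfm <- standardize(fm, fit_rows = which(tr))
    } else {
      sfm <- fm
    }
    model <- fit_fun(sfm$values[tr, , drop = FALSE], fm$labels[tr])
    pred <- predict(model, sfm$values[te, , drop = FALSE])
    tab <- table(factor(fm$labels[te], levels = 0:(n_classes - 1)),
                 factor(pred, levels = 0:(n_classes - 1)))
    cm <- matrix(as.numeric(tab), n_classes, n_classes,
                 dimnames = dimnames(confusion))
    confusion <- confusion + cm
    per_fold[[f]] <- compute_metrics(cm)
  }
  names(per_fold) <- paste0("fold", ks)
  .eval_result(per_fold, confusion, folds, config, model_kind)
}

#' Cross-validated evaluation of the RBF-SVM
#'
#' Per fold: feature standardization is fitted on the training rows only
#' (default; set `standardize_scope = "global"` to reproduce protocols
#' that standardize once on all data before splitting), an RBF-SVM is
#' fitted on the training rows and evaluated on the held-out rows.
#'
#' @param fm A `feature_matrix` (unstandardized).
#' @param folds Fold assignment from [make_folds()].
#' @param config An [svm_config()].
#' @param standardize_scope `"fold"` (leak-free, default) or `"global"`.
#' @param n_classes Number of classes (default 8).
#' @return An `eval_result`: per-fold and mean metrics, pooled metrics and
#'   the summed 8x8 confusion matrix.
#' @export
train_eval_svm <- function(fm, folds, config = svm_config(),
                           standardize_scope = c("fold", "global"),
                           n_classes = 8L) {
  .cv_eval(fm, folds,
           fit_fun = function(X, y) svm_rbf(X, y, config),
           config = config, model_kind = "svm",
           standardize_scope = match.arg(standardize_scope),
           n_classes = n_classes)
}

#' Cross-validated evaluation of the CNN
#'
#' @inheritParams train_eval_svm
#' @param config A [cnn_config()]; its seed fixes weight initialisation
#'   and batch order per fold.
#' @return An `eval_result`.
#' @export
train_eval_cnn <- function(fm, folds, config = cnn_config(),
                           standardize_scope = c("fold", "global"),
                           n_classes = 8L) {
  .cv_eval(fm, folds,
           fit_fun = function(X, y) cnn_train(X, y, config),
           config = config, model_kind = "cnn",
           standardize_scope = match.arg(standardize_scope),
           n_classes = n_classes)
}
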