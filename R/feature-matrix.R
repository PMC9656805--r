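# Feature matrix assembly and standardisation.
#
# A feature_matrix holds the n x m value matrix, the 0-based class label
# of every row, the trial (group) identifier of every row, and — once
# standardize() has been called — the per-column mean/sd fitted on the
# designated rows.

#' Compute the requested feature blocks for one trial
#'
#' @param trial A `trial_recording` in HCS (preprocessed).
#' @param M Hand length for this trial's subject.
#' @param features Character vector of block names among AFA, ATD, DPUV,
#'   NPTD, JA, FHA, FTE, MAV, RMS, VAR, WL, DFT.
#' @param window Window length for the windowed blocks (default 15).
#' @param dft_bins Kept DFT bins (default 8).
#' @return Named list of feature blocks in the requested order.
#' @export
feature_blocks <- function(trial, M, features, window = 15L, dft_bins = 8L) {
  features <- match.arg(features,
                        c("AFA", "ATD", "DPUV", "NPTD", "JA", "FHA", "FTE",
                          "MAV", "RMS", "VAR", "WL", "DFT"),
                        several.ok = TRUE)
  td_wanted <- intersect(features, c("MAV", "RMS", "VAR", "WL"))
  td <- if (length(td_wanted)) windowed_td_features(trial, M, window)
  out <- list()
  for (f in features) {
    out[[f]] <- if (f %in% c("MAV", "RMS", "VAR", "WL")) {
      td[[f]]
    } else if (f == "DFT") {
      dft_features(trial, M, window, dft_bins)
    } else {
      geometric_block(trial, f, M)
    }
  }
  out
}

# Average a per-frame block over the same non-overlapping windows used by
# the per-window blocks, so mixed-rate blocks share rows.
.window_average <- function(values, window) {
  starts <- .window_starts(nrow(values), window)
  out <- matrix(0, length(starts), ncol(values),
                dimnames = list(NULL, colnames(values)))
  for (k in seq_along(starts)) {
    out[k, ] <- colMeans(values[starts[k] + 0:(window - 1L), , drop = FALSE])
  }
  out
}

#' Column-concatenate feature blocks of one trial
#'
#' Blocks computed at different rates are reconciled: when any per-window
#' block is present, per-frame blocks are averaged within each window so
#' that all blocks share per-window rows.
#'
#' @param blocks Named list of blocks from [feature_blocks()] (one trial).
#' @param window Window length used for reconciliation.
#' @return Matrix with one row per sample and attribute `rate`.
#' @export
assemble_blocks <- function(blocks, window = 15L) {
  stopifnot(length(blocks) >= 1)
  rates <- vapply(blocks, attr, "", "rate")
  target <- if (any(rates == "per_window")) "per_window" else "per_frame"
  vals <- lapply(seq_along(blocks), function(i) {
    v <- blocks[[i]]
    if (target == "per_window" && rates[i] == "per_frame") {
      v <- .window_average(v, window)
    }
    unclass(v)
  })
  nr <- vapply(vals, nrow, 1L)
  if (length(unique(nr)) != 1) {
    stop("cannot align blocks with differing row counts: ",
         paste(sprintf("%s=%d", names(blocks), nr), collapse = ", "))
  }
  out <- do.call(cbind, vals)
  attr(out, "rate") <- target
  out
}

#' Build the classification matrix from preprocessed trials
#'
#' Runs [feature_blocks()] + [assemble_blocks()] on every trial and stacks
#' the rows, attaching the 0-based class label and the trial identifier of
#' every sample. Purely geometric feature sets yield one sample per frame;
#' any windowed block switches all blocks to one sample per window.
#'
#' @param trials List of `trial_recording`s in HCS.
#' @param M_by_subject Named list/vector of hand lengths keyed by
#'   subject_id ([hand_length()] objects or numbers).
#' @param features Feature block names (see [feature_blocks()]).
#' @param window,dft_bins Windowing parameters.
#' @return Object of class `feature_matrix`: list with `values` (n x m),
#'   `labels` (0-based integer), `groups` (character trial ids),
#'   `column_names`, `standardization` (NULL until [standardize()]).
#' @export
build_feature_matrix <- function(trials, M_by_subject, features,
                                 window = 15L, dft_bins = 8L) {
  stopifnot(length(trials) >= 1)
  parts <- vector("list", length(trials))
  labels <- groups <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    M <- M_by_subject[[tr$subject_id]]
    if (is.null(M)) stop("no hand length for subject ", tr$subject_id)
    v <- assemble_blocks(
      feature_blocks(tr, M, features, window, dft_bins), window)
    parts[[i]] <- v
    labels[[i]] <- rep(task_index(tr$task_label), nrow(v))
    groups[[i]] <- rep(sprintf("%s/%s#%d", tr$subject_id, tr$task_label,
                               tr$trial_index), nrow(v))
  }
  cn <- colnames(parts[[1]])
  if (!all(vapply(parts, function(p) identical(colnames(p), cn), TRUE))) {
    stop("trials produced differing feature columns; cannot align")
  }
  values <- do.call(rbind, parts)
  structure(list(values = values, labels = unlist(labels),
                 groups = unlist(groups), column_names = cn,
                 standardization = NULL),
            class = "feature_matrix")
}

#' Construct a feature matrix from raw components
#'
#' @param values Numeric n x m matrix.
#' @param labels Integer class labels (0-based), length n.
#' @param groups Character group/trial ids, length n (defaults to one group
#'   per row).
#' @return A `feature_matrix`.
#' @export
feature_matrix <- function(values, labels,
                           groups = as.character(seq_len(nrow(values)))) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(labels), nrow(values) == length(groups))
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  }
  structure(list(values = values, labels = as.integer(labels),
                 groups = as.character(groups),
                 column_names = colnames(values), standardization = NULL),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features, %d classes%s\n",
              nrow(x$values), ncol(x$values), length(unique(x$labels)),
              if (is.null(x$standardization)) "" else " (standardized)"))
  invisible(x)
}

#' Standardize feature columns to zero mean, unit variance
#'
#' Mean and sample sd are fitted on `fit_rows` only and applied to all
#' rows; the fitted parameters are stored on the result so the same
#' transform can be applied to new data. Zero-variance columns become
#' all-zero with a warning (they carry no information but keep the layout).
#'
#' @param fm A `feature_matrix`.
#' @param fit_rows Integer/logical row subset to fit on (default: all).
#' @return The standardized `feature_matrix` with `$standardization` set
#'   (list with `mean`, `sd` per column; `sd` as fitted, before the
#'   zero-variance guard).
#' @export
standardize <- function(fm, fit_rows = seq_len(nrow(fm$values))) {
  stopifnot(inherits(fm, "feature_matrix"))
  v <- fm$values
  mu <- colMeans(v[fit_rows, , drop = FALSE])
  sdev <- apply(v[fit_rows, , drop = FALSE], 2, sd)
  zero_var <- !is.finite(sdev) | sdev < 1e-12
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance column(s) set to all-zeros: ",
            paste(head(fm$column_names[zero_var], 5), collapse = ", "),
            if (sum(zero_var) > 5) ", ..." else "")
  }
  scale_by <- ifelse(zero_var, 1, sdev)
  out <- sweep(sweep(v, 2, mu, "-"), 2, scale_by, "/")
  out[, zero_var] <- 0
  fm$values <- out
  fm$standardization <- list(mean = mu, sd = sdev, zero_variance = zero_var)
  fm
}

#' Row-subset a feature matrix
#' @param fm A `feature_matrix`.
#' @param rows Row indices (integer or logical).
#' @return The subsetted `feature_matrix` (standardization dropped).
#' @export
fm_subset <- function(fm, rows) {
  feature_matrix(fm$values[rows, , drop = FALSE], fm$labels[rows],
                 fm$groups[rows])
}
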