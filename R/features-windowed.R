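# Windowed time-domain and frequency-domain features.
#
# Channels are the 72 joint-coordinate columns of an HCS trial (palm center
# and basis columns are constant in HCS and carry no information), divided
# by the hand length M. Windows are non-overlapping runs of `window`
# frames (default 15 = 0.5 s at 30 fps); a trailing partial window is
# dropped, so every windowed block has floor(n_frames / window) rows.

.window_starts <- function(n, window) {
  n_win <- n %/% window
  if (n_win < 1) {
    stop("trial has ", n, " frames; need at least one full window of ",
         window)
  }
  seq.int(1L, by = window, length.out = n_win)
}

.windowed_channels <- function(trial, M, window) {
  validate_trial(trial)
  window <- as.integer(window)
  if (window < 2L) stop("window must be >= 2")
  m <- .as_M(M)
  x <- trial$frames[, HCS_FEATURE_COLS, drop = FALSE] / m
  starts <- .window_starts(nrow(x), window)
  list(x = x, starts = starts, window = window,
       channel_names = paste0("c", HCS_FEATURE_COLS))
}

#' Windowed time-domain features: MAV, RMS, VAR, WL
#'
#' Per channel and per non-overlapping window of `window` frames, computes
#' the mean absolute value, root mean square, sample variance (denominator
#' N-1) and waveform length (sum of absolute first differences within the
#' window). Coordinates are normalised by M first.
#'
#' @param trial A `trial_recording` in HCS.
#' @param M Hand length ([hand_length()] or positive number).
#' @param window Window length in frames (default 15 = 0.5 s at 30 fps).
#' @return Named list of four feature blocks (`MAV`, `RMS`, `VAR`, `WL`),
#'   each a floor(n/window) x 72 matrix with `rate = "per_window"`.
#' @export
windowed_td_features <- function(trial, M, window = 15L) {
  w <- .windowed_channels(trial, M, window)
  n_win <- length(w$starts)
  nc <- ncol(w$x)
  mav <- rms <- va <- wl <- matrix(0, n_win, nc)
  for (k in seq_len(n_win)) {
    idx <- w$starts[k] + 0:(w$window - 1L)
    seg <- w$x[idx, , drop = FALSE]
    mav[k, ] <- colMeans(abs(seg))
    rms[k, ] <- sqrt(colMeans(seg^2))
    mu <- colMeans(seg)
    va[k, ] <- colSums((seg - rep(mu, each = w$window))^2) / (w$window - 1)
    wl[k, ] <- colSums(abs(seg[-1, , drop = FALSE] -
                             seg[-w$window, , drop = FALSE]))
  }
  blocks <- list(MAV = mav, RMS = rms, VAR = va, WL = wl)
  for (nm in names(blocks)) {
    colnames(blocks[[nm]]) <- paste0(nm, ".", w$channel_names)
    blocks[[nm]] <- .block(blocks[[nm]], nm, "per_window")
  }
  blocks
}

#' Windowed discrete Fourier transform magnitudes
#'
#' Per channel and per non-overlapping window, the magnitudes `|X[k]|` of
#' the DFT for bins `k = 0 .. kept_bins - 1`. For real input the spectrum
#' is conjugate-symmetric, so only the non-redundant low bins are kept
#' (default 8 of a 15-frame window).
#'
#' @inheritParams windowed_td_features
#' @param kept_bins Number of leading DFT bins to keep (must be
#'   `<= window`).
#' @return Feature block, floor(n/window) x (72 * kept_bins), per_window.
#' @export
dft_features <- function(trial, M, window = 15L, kept_bins = 8L) {
  kept_bins <- as.integer(kept_bins)
  if (kept_bins < 1L || kept_bins > window) {
    stop("kept_bins must be in 1..window (", window, "), got ", kept_bins)
  }
  w <- .windowed_channels(trial, M, window)
  n_win <- length(w$starts)
  nc <- ncol(w$x)
  out <- matrix(0, n_win, nc * kept_bins)
  for (k in seq_len(n_win)) {
    idx <- w$starts[k] + 0:(w$window - 1L)
    X <- stats::mvfft(w$x[idx, , drop = FALSE])   # window x channels
    mag <- Mod(X[seq_len(kept_bins), , drop = FALSE])
    out[k, ] <- as.numeric(mag)   # bin-major within channel blocks
  }
  colnames(out) <- paste0("DFT.", rep(w$channel_names, each = kept_bins),
                          ".k", rep(seq_len(kept_bins) - 1L, nc))
  .block(out, "DFT", "per_window")
}
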