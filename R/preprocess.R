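# Preprocessing: rigid motion, change of basis into the hand coordinate
# system, and median filtering.
#
# The change of basis is the mechanism that removes gross arm motion: at
# every frame the basis triad (h, n, b) stored with the data forms the
# columns of the transition matrix A, and every position point p is mapped
# to inverse(A) %*% (p - C). Because A is orthonormal the inverse is the
# transpose; a fallback exact solve() covers frames whose stored basis
# needed more than a tolerance correction.

#' Construct a rigid transform (rotation + translation)
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1 within 1e-6).
#' @param translation 3-vector in mm.
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    stop("rotation is not orthonormal within 1e-6")
  }
  if (abs(det(rotation) - 1) > 1e-6) {
    stop("rotation determinant must be +1 (got ", format(det(rotation)), ")")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Random rotation matrix (uniform over SO(3))
#'
#' QR-based Haar sampling; used by tests and the synthetic generator.
#'
#' @return 3 x 3 rotation matrix with determinant +1.
#' @export
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Apply one rigid transform to a frame-row matrix (in place on positions
# and directions). `transforms` may be a single rigid_transform or a list
# of per-frame transforms.
.apply_rigid_rows <- function(frames, transforms) {
  per_frame <- !inherits(transforms, "rigid_transform")
  if (per_frame) stopifnot(length(transforms) == nrow(frames))
  out <- frames
  for (i in seq_len(nrow(frames))) {
    tr <- if (per_frame) transforms[[i]] else transforms
    R <- tr$rotation; tvec <- tr$translation
    pos <- matrix(frames[i, POSITION_COLS], nrow = 3)
    out[i, POSITION_COLS] <- as.numeric(R %*% pos + tvec)
    dir <- matrix(frames[i, DIRECTION_COLS], nrow = 3)
    out[i, DIRECTION_COLS] <- as.numeric(R %*% dir)
  }
  out
}

#' Apply a rigid transform to a trial in the global frame
#'
#' Position points map as `x -> R x + t`; the stored basis direction
#' vectors rotate without translation. Stands in for any fixed
#' sensor-to-world calibration (e.g. a robot-arm mount): by construction it
#' has no effect on hand-frame features.
#'
#' @param trial A `trial_recording` in GCS.
#' @param transform A `rigid_transform`, or a list of one transform per
#'   frame (time-varying gross motion).
#' @return Transformed `trial_recording`, still in GCS.
#' @export
apply_rigid_transform <- function(trial, transform) {
  validate_trial(trial)
  if (trial$coordinate_frame != "GCS") {
    stop("apply_rigid_transform expects a trial in GCS")
  }
  if (inherits(transform, "rigid_transform")) {
    # validated at construction
  } else if (is.list(transform)) {
    stopifnot(all(vapply(transform, inherits, TRUE, "rigid_transform")))
  } else {
    stop("transform must be a rigid_transform or a list of them")
  }
  trial$frames <- .apply_rigid_rows(trial$frames, transform)
  trial
}

#' Transform a trial into the hand coordinate system
#'
#' Per frame, builds the change-of-basis matrix `A = [h n b]` from the
#' stored basis triad (re-orthonormalised by projection), then maps every
#' position point `p` to `t(A) %*% (p - C)`. The palm center becomes the
#' origin and the basis block the canonical axes, exactly; gross rigid
#' motion of the whole hand is thereby removed and only grasp shape
#' remains.
#'
#' @param trial A `trial_recording` in GCS.
#' @return The trial in HCS (`coordinate_frame = "HCS"`).
#' @export
to_hcs <- function(trial) {
  validate_trial(trial)
  if (trial$coordinate_frame == "HCS") return(trial)
  fr <- trial$frames
  out <- fr
  for (i in seq_len(nrow(fr))) {
    h <- fr[i, .point_cols$h]; n <- fr[i, .point_cols$n]
    C <- fr[i, .point_cols$C]
    onb <- tryCatch(.orthonormalize_basis(h, n), error = function(e) {
      stop(sprintf("frame %d: %s", i, conditionMessage(e)))
    })
    A <- cbind(onb$h, onb$n, onb$b)
    corr <- max(abs(cbind(h, n) - cbind(onb$h, onb$n)))
    pos <- matrix(fr[i, POSITION_COLS], nrow = 3) - C
    if (corr > 1e-3) {
      # stored basis was far from orthonormal: honour it literally with an
      # exact solve of A0 x = p - C on the raw (renormalised-rank) triad
      A0 <- cbind(h, n, onb$b)
      if (abs(det(A0)) < 1e-8) {
        stop(sprintf("frame %d: degenerate basis (rank < 3)", i))
      }
      out[i, POSITION_COLS] <- as.numeric(solve(A0, pos))
    } else {
      out[i, POSITION_COLS] <- as.numeric(crossprod(A, pos))
    }
    out[i, .point_cols$C] <- 0
    out[i, .point_cols$h] <- c(1, 0, 0)
    out[i, .point_cols$n] <- c(0, 1, 0)
    out[i, .point_cols$b] <- c(0, 0, 1)
  }
  trial$frames <- out
  trial$coordinate_frame <- "HCS"
  trial
}

#' Median-filter every channel of a trial
#'
#' Centered running median per channel with the window shrinking
#' symmetrically at the boundaries (no fabricated samples). Default window
#' of 5 frames corresponds to 1/6 s at 30 fps and removes impulsive
#' tracking spikes while preserving plateaus.
#'
#' @param trial A `trial_recording`.
#' @param window Odd positive integer window length, `<= n_frames`.
#' @return Filtered trial, same shape and metadata.
#' @export
median_filter_trial <- function(trial, window = 5L) {
  validate_trial(trial)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be a positive odd integer, got ", window)
  }
  if (window > n_frames(trial)) {
    stop("window (", window, ") exceeds number of frames (",
         n_frames(trial), ")")
  }
  n <- n_frames(trial)
  if (window > 1L && n >= 2L) {
    half <- (window - 1L) %/% 2L
    edge <- seq_len(min(half, n))
    trial$frames <- apply(trial$frames, 2, function(x) {
      # interior: running median (C code); edges: symmetric window shrink
      y <- as.numeric(runmed(x, window, endrule = "keep"))
      for (i in edge) {
        k <- min(half, i - 1L, n - i)
        y[i] <- median(x[(i - k):(i + k)])
        j <- n - i + 1L
        y[j] <- median(x[(j - k):(j + k)])
      }
      y
    })
  }
  trial
}

#' Standard preprocessing: hand-frame transform then median filter
#'
#' @param trial A `trial_recording` in GCS.
#' @param window Median filter window (default 5).
#' @return Filtered trial in HCS.
#' @export
preprocess_trial <- function(trial, window = 5L) {
  median_filter_trial(to_hcs(trial), window = window)
}
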