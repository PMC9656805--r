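# Geometric (per-frame) grasp features.
#
# All angle features are divided by pi so they live in [0, 1]; all distance
# features are divided by the per-subject hand length M so they are
# dimensionless and comparable across hand sizes. Single-frame functions
# below are the direct formula transcriptions; geometric_features() is the
# vectorised trial-level path used by the pipeline.

.ADJACENT_PAIRS <- cbind(FINGERS[1:4], FINGERS[2:5])

.angle_over_pi <- function(u, v, what = "vector") {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12) {
    stop("zero-length ", what, " in angle computation")
  }
  acos(min(1, max(-1, sum(u * v) / (nu * nv)))) / pi
}

#' Hand length M from a calibration trial
#'
#' Per frame, the accumulated Euclidean distance along the middle finger:
#' `|C->MCP| + |MCP->PIP| + |PIP->DIP| + |DIP->tip|`, averaged over the
#' first `n_frames` frames (default 30, i.e. the first second at 30 fps).
#' By convention M is taken from the first trial of the "cup" task of each
#' subject, where grasp variation across people is smallest.
#'
#' @param calibration_trial A `trial_recording` (any coordinate frame:
#'   the four summed lengths are rigid-motion invariant).
#' @param n_frames Number of leading frames to average (default 30).
#' @return Object of class `hand_length`: list with `M` (mm), `subject_id`,
#'   `source`, `n_frames_averaged`.
#' @export
hand_length <- function(calibration_trial, n_frames = 30L) {
  validate_trial(calibration_trial)
  n_frames <- as.integer(n_frames)
  if (n_frames(calibration_trial) < n_frames) {
    stop("calibration trial has ", n_frames(calibration_trial),
         " frames, need at least ", n_frames)
  }
  fr <- calibration_trial$frames[seq_len(n_frames), , drop = FALSE]
  r <- .role_cols$middle
  seglen <- function(a, b) {
    d <- fr[, a, drop = FALSE] - fr[, b, drop = FALSE]
    sqrt(rowSums(d^2))
  }
  per_frame <- seglen(.point_cols$C, r$mcp) + seglen(r$mcp, r$pip) +
    seglen(r$pip, r$dip) + seglen(r$dip, r$tip)
  M <- mean(per_frame)
  if (!is.finite(M) || M <= 0) stop("computed hand length is not positive")
  structure(list(M = M, subject_id = calibration_trial$subject_id,
                 source = sprintf("%s/%s#%d", calibration_trial$subject_id,
                                  calibration_trial$task_label,
                                  calibration_trial$trial_index),
                 n_frames_averaged = n_frames),
            class = "hand_length")
}

.as_M <- function(M) {
  m <- if (inherits(M, "hand_length")) M$M else as.numeric(M)
  if (!is.finite(m) || m <= 0) stop("hand length M must be positive")
  m
}

#' Adjacent fingertips angle (AFA)
#'
#' Angle between the palm-center-to-fingertip vectors of each adjacent
#' finger pair (thumb-index, ..., ring-pinky), divided by pi.
#'
#' @param frame A `hand_frame`.
#' @return Named 4-vector in \[0, 1\].
#' @export
afa <- function(frame) {
  tips <- vapply(FINGERS, function(f) finger_joints(frame, f)[, "tip"],
                 numeric(3))
  out <- vapply(seq_len(4), function(i) {
    .angle_over_pi(tips[, i] - frame$C, tips[, i + 1] - frame$C,
                   paste0("fingertip vector (", FINGERS[i], ")"))
  }, 0)
  names(out) <- paste0("AFA.", .ADJACENT_PAIRS[, 1], "_", .ADJACENT_PAIRS[, 2])
  out
}

#' Adjacent tips distance (ATD)
#'
#' Euclidean distance between adjacent fingertips, divided by M.
#'
#' @param frame A `hand_frame`.
#' @param M Hand length ([hand_length()] object or positive number, mm).
#' @return Named non-negative 4-vector.
#' @export
atd <- function(frame, M) {
  m <- .as_M(M)
  tips <- vapply(FINGERS, function(f) finger_joints(frame, f)[, "tip"],
                 numeric(3))
  out <- vapply(seq_len(4), function(i) {
    sqrt(sum((tips[, i] - tips[, i + 1])^2)) / m
  }, 0)
  names(out) <- paste0("ATD.", .ADJACENT_PAIRS[, 1], "_", .ADJACENT_PAIRS[, 2])
  out
}

#' Distal phalanx unit vectors (DPUV)
#'
#' Per finger, the unit vector from the distal interphalangeal joint to the
#' fingertip; 5 fingers x 3 components.
#'
#' @param frame A `hand_frame`.
#' @return Named 15-vector; each finger's 3-subvector has unit norm.
#' @export
dpuv <- function(frame) {
  out <- numeric(0)
  for (f in FINGERS) {
    j <- finger_joints(frame, f)
    v <- j[, "tip"] - j[, "dip"]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) stop("tip coincides with DIP for finger ", f)
    out <- c(out, v / nv)
  }
  names(out) <- paste0("DPUV.", rep(FINGERS, each = 3), ".",
                       rep(c("x", "y", "z"), 5))
  out
}

#' Normalized palm-tip distance (NPTD)
#'
#' Euclidean distance from the palm center to each fingertip, divided by M.
#'
#' @inheritParams atd
#' @return Named non-negative 5-vector.
#' @export
nptd <- function(frame, M) {
  m <- .as_M(M)
  out <- vapply(FINGERS, function(f) {
    sqrt(sum((finger_joints(frame, f)[, "tip"] - frame$C)^2)) / m
  }, 0)
  names(out) <- paste0("NPTD.", FINGERS)
  out
}

#' Joint angles (JA)
#'
#' Per finger, the angle between adjacent bones at the MCP, PIP and DIP
#' joints (the metacarpal bone at the MCP is proxied by the palm-center-to-
#' MCP vector), each divided by pi. A straight finger gives all zeros.
#'
#' @param frame A `hand_frame`.
#' @return Named 15-vector in \[0, 1\] (finger-major, joints mcp/pip/dip).
#' @export
ja <- function(frame) {
  out <- numeric(0)
  for (f in FINGERS) {
    j <- finger_joints(frame, f)
    bones <- list(mcp = list(j[, "mcp"] - frame$C, j[, "pip"] - j[, "mcp"]),
                  pip = list(j[, "pip"] - j[, "mcp"], j[, "dip"] - j[, "pip"]),
                  dip = list(j[, "dip"] - j[, "pip"], j[, "tip"] - j[, "dip"]))
    for (jn in names(bones)) {
      out <- c(out, .angle_over_pi(bones[[jn]][[1]], bones[[jn]][[2]],
                                   paste0("bone at ", f, ":", jn)))
    }
  }
  names(out) <- paste0("JA.", rep(FINGERS, each = 3), ".",
                       rep(c("mcp", "pip", "dip"), 5))
  out
}

#' Fingertip-h angle (FHA)
#'
#' Projects each fingertip onto the palm plane (through C, normal n) and
#' returns the angle between the palm-center-to-projection vector and the
#' finger-direction basis vector h, divided by pi.
#'
#' @param frame A `hand_frame`.
#' @return Named 5-vector in \[0, 1\].
#' @export
fha <- function(frame) {
  out <- vapply(FINGERS, function(f) {
    Fi <- finger_joints(frame, f)[, "tip"]
    Fip <- Fi - sum((Fi - frame$C) * frame$n) * frame$n
    .angle_over_pi(Fip - frame$C, frame$h,
                   paste0("palm-plane projection (", f, ")"))
  }, 0)
  names(out) <- paste0("FHA.", FINGERS)
  out
}

#' Fingertip elevation (FTE)
#'
#' Signed distance of each fingertip from the palm plane (positive on the
#' n side), divided by M.
#'
#' @inheritParams atd
#' @return Named 5-vector.
#' @export
fte <- function(frame, M) {
  m <- .as_M(M)
  out <- vapply(FINGERS, function(f) {
    Fi <- finger_joints(frame, f)[, "tip"]
    d <- sum((Fi - frame$C) * frame$n)
    Fip <- Fi - d * frame$n
    sign(d) * sqrt(sum((Fi - Fip)^2)) / m
  }, 0)
  names(out) <- paste0("FTE.", FINGERS)
  out
}

# --- vectorised trial-level blocks ----------------------------------------

.block <- function(values, name, rate) {
  structure(values, feature_name = name, rate = rate)
}

.row_angle_over_pi <- function(U, V) {
  nu <- sqrt(rowSums(U^2)); nv <- sqrt(rowSums(V^2))
  if (any(nu < 1e-12) || any(nv < 1e-12)) {
    stop("zero-length vector in angle computation at frame ",
         which(nu < 1e-12 | nv < 1e-12)[1])
  }
  acos(pmin(1, pmax(-1, rowSums(U * V) / (nu * nv)))) / pi
}

# role-resolved 3-column slices for all frames of a trial matrix
.pt <- function(fr, finger, role) fr[, .role_cols[[finger]][[role]],
                                     drop = FALSE]

#' Compute one geometric feature block for a whole trial
#'
#' Vectorised equivalent of applying the single-frame feature function to
#' every frame; one row per frame.
#'
#' @param trial A `trial_recording` (HCS expected for the pipeline, but any
#'   frame is accepted: geometric features only use stored points).
#' @param name One of `"AFA"`, `"ATD"`, `"DPUV"`, `"NPTD"`, `"JA"`,
#'   `"FHA"`, `"FTE"`.
#' @param M Hand length, required by ATD/NPTD/FTE.
#' @return Numeric matrix n_frames x m with feature column names, carrying
#'   attributes `feature_name` and `rate = "per_frame"`.
#' @export
geometric_block <- function(trial, name, M = NULL) {
  validate_trial(trial)
  fr <- trial$frames
  C <- fr[, .point_cols$C, drop = FALSE]
  h <- fr[, .point_cols$h, drop = FALSE]
  n <- fr[, .point_cols$n, drop = FALSE]
  tips <- lapply(FINGERS, function(f) .pt(fr, f, "tip"))
  names(tips) <- FINGERS
  name <- match.arg(name, c("AFA", "ATD", "DPUV", "NPTD", "JA", "FHA", "FTE"))
  vals <- switch(name,
    AFA = {
      out <- matrix(vapply(seq_len(4), function(i) {
        .row_angle_over_pi(tips[[i]] - C, tips[[i + 1]] - C)
      }, numeric(nrow(fr))), nrow = nrow(fr))
      colnames(out) <- paste0("AFA.", .ADJACENT_PAIRS[, 1], "_",
                              .ADJACENT_PAIRS[, 2])
      out
    },
    ATD = {
      m <- .as_M(M)
      out <- matrix(vapply(seq_len(4), function(i) {
        sqrt(rowSums((tips[[i]] - tips[[i + 1]])^2)) / m
      }, numeric(nrow(fr))), nrow = nrow(fr))
      colnames(out) <- paste0("ATD.", .ADJACENT_PAIRS[, 1], "_",
                              .ADJACENT_PAIRS[, 2])
      out
    },
    DPUV = {
      out <- do.call(cbind, lapply(FINGERS, function(f) {
        v <- tips[[f]] - .pt(fr, f, "dip")
        nv <- sqrt(rowSums(v^2))
        if (any(nv < 1e-12)) stop("tip coincides with DIP for finger ", f)
        v / nv
      }))
      colnames(out) <- paste0("DPUV.", rep(FINGERS, each = 3), ".",
                              rep(c("x", "y", "z"), 5))
      out
    },
    NPTD = {
      m <- .as_M(M)
      out <- matrix(vapply(FINGERS, function(f) {
        sqrt(rowSums((tips[[f]] - C)^2)) / m
      }, numeric(nrow(fr))), nrow = nrow(fr))
      colnames(out) <- paste0("NPTD.", FINGERS)
      out
    },
    JA = {
      out <- do.call(cbind, lapply(FINGERS, function(f) {
        mcp <- .pt(fr, f, "mcp"); pip <- .pt(fr, f, "pip")
        dip <- .pt(fr, f, "dip"); tip <- tips[[f]]
        cbind(.row_angle_over_pi(mcp - C, pip - mcp),
              .row_angle_over_pi(pip - mcp, dip - pip),
              .row_angle_over_pi(dip - pip, tip - dip))
      }))
      colnames(out) <- paste0("JA.", rep(FINGERS, each = 3), ".",
                              rep(c("mcp", "pip", "dip"), 5))
      out
    },
    FHA = {
      out <- matrix(vapply(FINGERS, function(f) {
        d <- rowSums((tips[[f]] - C) * n)
        Fip <- tips[[f]] - d * n
        .row_angle_over_pi(Fip - C, h)
      }, numeric(nrow(fr))), nrow = nrow(fr))
      colnames(out) <- paste0("FHA.", FINGERS)
      out
    },
    FTE = {
      m <- .as_M(M)
      out <- matrix(vapply(FINGERS, function(f) {
        d <- rowSums((tips[[f]] - C) * n)
        sign(d) * abs(d) / m
      }, numeric(nrow(fr))), nrow = nrow(fr))
      colnames(out) <- paste0("FTE.", FINGERS)
      out
    })
  vals <- matrix(vals, nrow = nrow(fr),
                 dimnames = list(NULL, colnames(vals)))
  .block(vals, name, "per_frame")
}
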