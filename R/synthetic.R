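# Synthetic grasp generator.
#
# A stand-in for motion-capture recordings: eight hand-authored grasp
# archetypes (per-finger flexion/abduction angles), a scalable hand
# geometry, and a motion profile with a ~10 s quasi-static hold followed
# by repeated gross rigid-body motion of the whole hand. Articulation
# jitter (Gaussian on joint angles) and sensor noise (Gaussian on emitted
# position coordinates) make the trials realistically non-constant while
# keeping the grasp itself quasi-static. The archetypes are conventions
# chosen for grasp-taxonomy diversity (power vs precision), not
# reconstructions of any participant's grasp.

FLEXION_MAX <- pi * 0.7
ABDUCTION_MAX <- pi / 6

#' Hand geometry (segment lengths)
#'
#' Baseline adult-hand segment lengths in mm, all multiplied by `scale`.
#' The middle-finger chain gives a hand length M of about 146 mm at
#' scale 1.
#'
#' @param scale Global hand-size multiplier (> 0).
#' @return List of class `hand_geometry`: per-finger palm-to-MCP distance
#'   `r`, segment lengths `L1`-`L3`, in-palm-plane root directions
#'   (degrees from h), and the metacarpal root offset.
#' @export
hand_geometry <- function(scale = 1) {
  stopifnot(scale > 0)
  structure(list(
    scale = scale,
    r  = scale * c(thumb = 25, index = 42, middle = 45, ring = 42,
                   pinky = 38),
    L1 = scale * c(thumb = 40, index = 45, middle = 48, ring = 44,
                   pinky = 35),
    L2 = scale * c(thumb = 32, index = 26, middle = 28, ring = 26,
                   pinky = 20),
    L3 = scale * c(thumb = 28, index = 24, middle = 25, ring = 24,
                   pinky = 20),
    root_angle_deg = c(thumb = 65, index = 12, middle = 0, ring = -12,
                       pinky = -26),
    cmc_back = scale * 60), class = "hand_geometry")
}

#' Grasp archetype: per-finger joint-angle configuration
#'
#' @param task_name One of the eight task names.
#' @param flexion 5 x 3 matrix (fingers x mcp/pip/dip) of flexion angles in
#'   radians, within \[0, 0.7 pi\].
#' @param abduction Length-5 vector of in-palm-plane abduction angles
#'   (radians, within +/- pi/6).
#' @param opposition Thumb opposition angle (radians): rotates the thumb's
#'   flexion plane out of the palm plane.
#' @return List of class `grasp_archetype`.
#' @export
grasp_archetype <- function(task_name, flexion, abduction,
                            opposition = 0) {
  task_index(task_name)
  flexion <- matrix(flexion, 5, 3,
                    dimnames = list(FINGERS, c("mcp", "pip", "dip")))
  if (any(flexion < 0) || any(flexion > FLEXION_MAX)) {
    stop("flexion angles must lie in [0, 0.7*pi]")
  }
  if (any(abs(abduction) > ABDUCTION_MAX)) {
    stop("abduction angles must lie in [-pi/6, pi/6]")
  }
  structure(list(task_name = task_name, flexion = flexion,
                 abduction = as.numeric(abduction),
                 opposition = as.numeric(opposition)),
            class = "grasp_archetype")
}

#' The eight default grasp archetypes
#'
#' Hand-authored configurations mirroring the grasp diversity of common
#' ADL objects: power grasps (cup, knife, doorknob, nail clipper) with
#' strong whole-hand flexion, precision grasps (pen, key, spoon, fork)
#' with differentiated thumb/index involvement.
#'
#' @return Named list of 8 `grasp_archetype`s, in task-vocabulary order.
#' @export
default_archetypes <- function() {
  a <- list(
    cup = grasp_archetype("cup",
      flexion = rbind(c(0.50, 0.45, 0.30), c(0.95, 0.85, 0.50),
                      c(1.00, 0.90, 0.55), c(1.00, 0.90, 0.55),
                      c(0.95, 0.85, 0.50)),
      abduction = c(0.20, 0.10, 0.00, -0.10, -0.20), opposition = 0.55),
    fork = grasp_archetype("fork",
      flexion = rbind(c(0.70, 0.55, 0.35), c(1.30, 0.70, 0.40),
                      c(1.35, 0.80, 0.45), c(1.60, 1.30, 0.80),
                      c(1.70, 1.40, 0.90)),
      abduction = c(0.15, 0.05, 0.00, -0.05, -0.10), opposition = 0.80),
    key = grasp_archetype("key",
      flexion = rbind(c(0.35, 0.30, 0.25), c(1.10, 1.30, 0.90),
                      c(1.80, 1.60, 1.00), c(1.85, 1.65, 1.05),
                      c(1.90, 1.70, 1.10)),
      abduction = c(0.05, 0.00, 0.00, -0.05, -0.10), opposition = 0.15),
    knife = grasp_archetype("knife",
      flexion = rbind(c(0.80, 0.70, 0.50), c(1.50, 1.40, 0.90),
                      c(1.55, 1.45, 0.95), c(1.55, 1.45, 0.95),
                      c(1.50, 1.40, 0.90)),
      abduction = c(0.10, 0.05, 0.00, -0.05, -0.10), opposition = 0.40),
    nail_clipper = grasp_archetype("nail_clipper",
      flexion = rbind(c(0.55, 0.40, 0.30), c(0.80, 0.50, 0.30),
                      c(1.20, 1.00, 0.60), c(1.75, 1.55, 1.00),
                      c(1.80, 1.60, 1.05)),
      abduction = c(0.30, 0.15, 0.05, -0.05, -0.15), opposition = 0.90),
    pen = grasp_archetype("pen",
      flexion = rbind(c(0.60, 0.50, 0.40), c(1.00, 0.95, 0.70),
                      c(0.85, 0.75, 0.55), c(1.50, 1.35, 0.85),
                      c(1.60, 1.45, 0.95)),
      abduction = c(0.40, 0.20, 0.05, -0.10, -0.20), opposition = 1.00),
    spherical_doorknob = grasp_archetype("spherical_doorknob",
      flexion = rbind(c(0.45, 0.40, 0.30), c(0.70, 0.60, 0.40),
                      c(0.75, 0.65, 0.45), c(0.75, 0.65, 0.45),
                      c(0.70, 0.60, 0.40)),
      abduction = c(0.50, 0.35, 0.10, -0.20, -0.45), opposition = 0.35),
    spoon = grasp_archetype("spoon",
      flexion = rbind(c(0.65, 0.50, 0.30), c(1.05, 0.55, 0.30),
                      c(1.10, 0.60, 0.35), c(1.25, 1.05, 0.60),
                      c(1.35, 1.15, 0.70)),
      abduction = c(0.25, 0.10, 0.00, -0.08, -0.18), opposition = 0.65))
  a[task_vocabulary()]
}

# Rodrigues rotation of vector v about unit axis a by angle th.
.rotate_about <- function(v, a, th) {
  cx <- c(a[2] * v[3] - a[3] * v[2], a[3] * v[1] - a[1] * v[3],
          a[1] * v[2] - a[2] * v[1])
  v * cos(th) + cx * sin(th) + a * sum(a * v) * (1 - cos(th))
}

#' Place all hand joints by forward kinematics
#'
#' Serial chain per finger in the canonical pose (palm center at the
#' origin, basis h = e1, n = e2, b = e3): the finger root direction lies
#' in the palm plane, abduction rotates it about the palm normal, flexion
#' rotates successive segments about the finger's lateral axis (cumulative
#' along the chain), and the thumb's opposition angle tilts its flexion
#' plane out of the palm. The whole hand is then moved by `pose`.
#'
#' @param archetype A `grasp_archetype` (angles within bounds).
#' @param geom A `hand_geometry`.
#' @param pose A `rigid_transform` applied to the whole hand.
#' @return A `hand_frame`.
#' @export
forward_kinematics <- function(archetype, geom,
                               pose = rigid_transform()) {
  stopifnot(inherits(archetype, "grasp_archetype"),
            inherits(geom, "hand_geometry"))
  h0 <- c(1, 0, 0); n0 <- c(0, 1, 0); b0 <- c(0, 0, 1)
  fingers <- list()
  for (fi in seq_along(FINGERS)) {
    f <- FINGERS[fi]
    phi <- geom$root_angle_deg[[f]] * pi / 180
    u0 <- cos(phi) * h0 + sin(phi) * b0            # root direction
    u <- .rotate_about(u0, n0, archetype$abduction[fi])
    w <- c(n0[2] * u[3] - n0[3] * u[2], n0[3] * u[1] - n0[1] * u[3],
           n0[1] * u[2] - n0[2] * u[1])            # n x u: flexion axis
    w <- w / sqrt(sum(w^2))
    if (f == "thumb" && archetype$opposition != 0) {
      w <- .rotate_about(w, u, archetype$opposition)
    }
    fl <- archetype$flexion[fi, ]
    d1 <- .rotate_about(u, w, fl[1])
    d2 <- .rotate_about(u, w, fl[1] + fl[2])
    d3 <- .rotate_about(u, w, fl[1] + fl[2] + fl[3])
    mcp <- geom$r[[f]] * u
    pip <- mcp + geom$L1[[f]] * d1
    dip <- pip + geom$L2[[f]] * d2
    tip <- dip + geom$L3[[f]] * d3
    pts <- if (f == "thumb") {
      # stored as cmc/mcp/dip/tip, filling the four chain roles
      cbind(cmc = mcp, mcp = pip, dip = dip, tip = tip)
    } else {
      cmc <- (geom$r[[f]] - geom$cmc_back) * u0    # metacarpal root
      cbind(cmc = cmc, mcp = mcp, pip = pip, dip = dip, tip = tip)
    }
    rownames(pts) <- c("x", "y", "z")
    fingers[[f]] <- pts
  }
  R <- pose$rotation; tv <- pose$translation
  for (f in FINGERS) fingers[[f]] <- R %*% fingers[[f]] + tv
  structure(list(C = as.numeric(tv), h = as.numeric(R %*% h0),
                 n = as.numeric(R %*% n0), b = as.numeric(R %*% b0),
                 fingers = fingers),
            class = "hand_frame")
}

#' Motion profile for synthetic trials
#'
#' @param fps Frames per second (default 30).
#' @param static_duration Quasi-static hold, seconds (default 10).
#' @param dynamic_duration Duration of one dynamic repetition, seconds
#'   (default 1.5).
#' @param repetitions Number of dynamic repetitions (default 5).
#' @param articulation_jitter_sd Gaussian sd on joint angles, radians
#'   (default 0.02).
#' @param sensor_noise_sd Gaussian sd on emitted position coordinates, mm
#'   (default 0.5).
#' @param trajectory Function of phase u in \[0, 1\] returning the
#'   `rigid_transform` of the whole hand at that point of one repetition;
#'   the default sweeps an arm-scale arc (~25 cm translation, ~35 deg
#'   rotation) returning to the start.
#' @return List of class `motion_profile`.
#' @export
motion_profile <- function(fps = 30, static_duration = 10,
                           dynamic_duration = 1.5, repetitions = 5L,
                           articulation_jitter_sd = 0.02,
                           sensor_noise_sd = 0.5,
                           trajectory = NULL) {
  stopifnot(fps > 0, static_duration >= 0, dynamic_duration >= 0,
            repetitions >= 0, articulation_jitter_sd >= 0,
            sensor_noise_sd >= 0)
  if (is.null(trajectory)) {
    axis <- c(0.3, 1, 0.2) / sqrt(sum(c(0.3, 1, 0.2)^2))
    trajectory <- function(u) {
      th <- 0.6 * sin(2 * pi * u)
      K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                    -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
      R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
      rigid_transform(R, c(250 * sin(pi * u), 120 * sin(2 * pi * u),
                           80 * (1 - cos(2 * pi * u))))
    }
  }
  structure(list(fps = fps, static_duration = static_duration,
                 dynamic_duration = dynamic_duration,
                 repetitions = as.integer(repetitions),
                 articulation_jitter_sd = articulation_jitter_sd,
                 sensor_noise_sd = sensor_noise_sd,
                 trajectory = trajectory),
            class = "motion_profile")
}

.jitter_archetype <- function(archetype, sd) {
  if (sd <= 0) return(archetype)
  fl <- archetype$flexion + matrix(rnorm(15, sd = sd), 5, 3)
  archetype$flexion[] <- pmin(pmax(fl, 0), FLEXION_MAX)
  ab <- archetype$abduction + rnorm(5, sd = sd)
  archetype$abduction <- pmin(pmax(ab, -ABDUCTION_MAX), ABDUCTION_MAX)
  archetype
}

#' Generate one synthetic trial
#'
#' Static phase: fixed identity pose plus per-frame articulation jitter
#' and sensor noise. Dynamic phase: the pose follows the profile's
#' trajectory, repeated `repetitions` times. Fully deterministic given
#' `seed`. Sensor noise perturbs position coordinates only; the stored
#' basis stays an exact unit triad (directions carry no mm noise).
#'
#' @param archetype A `grasp_archetype`.
#' @param geom A `hand_geometry`.
#' @param profile A `motion_profile`.
#' @param seed Integer seed.
#' @param subject_id,trial_index Metadata for the emitted trial.
#' @return A `trial_recording` in GCS.
#' @export
generate_trial <- function(archetype, geom, profile = motion_profile(),
                           seed = 1L, subject_id = "S1", trial_index = 1L) {
  n_static <- round(profile$static_duration * profile$fps)
  n_rep <- round(profile$dynamic_duration * profile$fps)
  n_dyn <- n_rep * profile$repetitions
  if (n_static + n_dyn < 1) {
    stop("profile produces zero frames (empty phases and no repetitions)")
  }
  set.seed(as.integer(seed))
  frames <- matrix(0, n_static + n_dyn, 84)
  for (i in seq_len(nrow(frames))) {
    pose <- if (i <= n_static) {
      rigid_transform()
    } else {
      u <- ((i - n_static - 1) %% n_rep) / max(1, n_rep)
      profile$trajectory(u)
    }
    jit <- .jitter_archetype(archetype, profile$articulation_jitter_sd)
    row <- flatten_frame(forward_kinematics(jit, geom, pose))
    if (profile$sensor_noise_sd > 0) {
      row[POSITION_COLS] <- row[POSITION_COLS] +
        rnorm(length(POSITION_COLS), sd = profile$sensor_noise_sd)
    }
    frames[i, ] <- row
  }
  trial_recording(frames, task_label = archetype$task_name,
                  subject_id = subject_id, trial_index = trial_index,
                  fps = profile$fps, coordinate_frame = "GCS")
}

.derive_seed <- function(master, subject, task, trial) {
  as.integer((as.numeric(master) * 2654435 + subject * 7919 +
                task * 131 + trial * 17) %% 2147483647)
}

#' Generate a full synthetic dataset
#'
#' Per subject: one sampled hand scale, then `trials_per_task` trials for
#' each of the eight tasks, with per-trial seeds derived deterministically
#' from the master seed. The first trial of the "cup" task of each subject
#' is flagged as the hand-length calibration trial in the manifest.
#'
#' @param archetypes Named list of 8 `grasp_archetype`s
#'   ([default_archetypes()]).
#' @param n_subjects Number of subjects.
#' @param trials_per_task Trials per subject and task.
#' @param profile A `motion_profile` template shared by all trials.
#' @param seed Master seed.
#' @param scale_range Range the per-subject hand scale is drawn from.
#' @return List with `trials` (list of `trial_recording`s) and `manifest`
#'   (data.frame with subject, task, trial index, hand scale, calibration
#'   flag and per-trial seed).
#' @export
generate_dataset <- function(archetypes = default_archetypes(),
                             n_subjects = 6L, trials_per_task = 2L,
                             profile = motion_profile(), seed = 1L,
                             scale_range = c(0.85, 1.15)) {
  if (length(archetypes) < 8) stop("need 8 archetypes, got ",
                                   length(archetypes))
  tasks <- vapply(archetypes, `[[`, "", "task_name")
  set.seed(as.integer(seed))
  scales <- runif(n_subjects, scale_range[1], scale_range[2])
  trials <- list()
  rows <- list()
  for (s in seq_len(n_subjects)) {
    geom <- hand_geometry(scales[s])
    sid <- sprintf("S%02d", s)
    for (a in seq_along(archetypes)) {
      for (tr in seq_len(trials_per_task)) {
        ts <- .derive_seed(seed, s, a, tr)
        trial <- generate_trial(archetypes[[a]], geom, profile, seed = ts,
                                subject_id = sid, trial_index = tr)
        trials[[length(trials) + 1]] <- trial
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = sid, task_label = tasks[a], trial_index = tr,
          hand_scale = scales[s],
          is_calibration = (tasks[a] == "cup" && tr == 1L),
          seed_used = ts, stringsAsFactors = FALSE)
      }
    }
  }
  list(trials = trials, manifest = do.call(rbind, rows))
}

#' Per-subject hand lengths from a dataset's calibration trials
#'
#' @param dataset Result of [generate_dataset()] (or a compatible
#'   trials+manifest list with an `is_calibration` column).
#' @param n_frames Leading frames to average (default 30).
#' @return Named list of [hand_length()] objects keyed by subject_id.
#' @export
calibration_hand_lengths <- function(dataset, n_frames = 30L) {
  m <- dataset$manifest
  idx <- which(m$is_calibration)
  out <- lapply(idx, function(i) hand_length(dataset$trials[[i]], n_frames))
  names(out) <- m$subject_id[idx]
  out
}
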