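# Trial container and on-disk format.
#
# A trial is one task performance: an n x 84 frame matrix plus metadata.
# On disk it is plain text: a '#'-prefixed key=value header block followed
# by comma-separated rows of 84 values. A bundle is a directory of trial
# files plus a manifest.csv.

#' Construct a trial recording
#'
#' @param frames Numeric matrix, n_frames x 84, coordinates in mm.
#' @param task_label One of the eight task names ([task_vocabulary()]).
#' @param subject_id Subject identifier string.
#' @param trial_index Integer trial counter within subject/task.
#' @param fps Sampling rate in frames per second (default 30).
#' @param coordinate_frame `"GCS"` (global) or `"HCS"` (hand-anchored).
#' @return Object of class `trial_recording`.
#' @export
trial_recording <- function(frames, task_label, subject_id,
                            trial_index = 1L, fps = 30,
                            coordinate_frame = c("GCS", "HCS")) {
  coordinate_frame <- match.arg(coordinate_frame)
  frames <- as.matrix(frames)
  storage.mode(frames) <- "double"
  trial <- structure(
    list(frames = frames, task_label = as.character(task_label),
         subject_id = as.character(subject_id),
         trial_index = as.integer(trial_index), fps = as.numeric(fps),
         coordinate_frame = coordinate_frame),
    class = "trial_recording")
  validate_trial(trial)
  trial
}

#' Validate a trial recording's invariants
#'
#' Checks the 84-column shape, finiteness, positive fps and a known task
#' label. Called by every constructor and by [write_trial()].
#'
#' @param trial A `trial_recording`.
#' @return The trial, invisibly.
#' @export
validate_trial <- function(trial) {
  stopifnot(inherits(trial, "trial_recording"))
  fr <- trial$frames
  if (!is.matrix(fr) || ncol(fr) != 84) {
    stop("trial frames must be a matrix with 84 columns, got ",
         if (is.matrix(fr)) ncol(fr) else "a non-matrix")
  }
  if (nrow(fr) < 1) stop("trial must contain at least one frame")
  if (!all(is.finite(fr))) {
    bad <- which(!is.finite(fr), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at frame %d, column %d", bad[1], bad[2]))
  }
  if (!is.finite(trial$fps) || trial$fps <= 0) stop("fps must be > 0")
  task_index(trial$task_label)  # errors on unknown label
  if (!trial$coordinate_frame %in% c("GCS", "HCS")) {
    stop("coordinate_frame must be GCS or HCS")
  }
  invisible(trial)
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf(
    "<trial_recording> %s / %s #%d: %d frames @ %g fps [%s]\n",
    x$subject_id, x$task_label, x$trial_index, nrow(x$frames), x$fps,
    x$coordinate_frame))
  invisible(x)
}

#' Number of frames in a trial
#' @param trial A `trial_recording`.
#' @return Integer frame count.
#' @export
n_frames <- function(trial) nrow(trial$frames)

#' Write a trial to a delimited text file
#'
#' Format: header lines `# key=value` (subject_id, task_label, trial_index,
#' fps, coordinate_frame, layout_version) then one comma-separated row of
#' 84 full-precision values per frame.
#'
#' @param trial A valid `trial_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  validate_trial(trial)
  header <- sprintf("# %s=%s",
                    c("subject_id", "task_label", "trial_index", "fps",
                      "coordinate_frame", "layout_version"),
                    c(trial$subject_id, trial$task_label,
                      format(trial$trial_index),
                      format(trial$fps, digits = 17),
                      trial$coordinate_frame, LAYOUT_VERSION))
  body <- apply(trial$frames, 1, function(r) {
    paste(format(r, digits = 17, scientific = TRUE, trim = TRUE),
          collapse = ",")
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a trial from a delimited text file
#'
#' @param path File written by [write_trial()].
#' @return A `trial_recording`; errors name the offending row/column when
#'   the file is malformed.
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop("no such trial file: ", path)
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  kv <- sub("^#\\s*", "", lines[hdr])
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  names(vals) <- keys
  req <- c("subject_id", "task_label", "trial_index", "fps",
           "coordinate_frame")
  missing_keys <- setdiff(req, keys)
  if (length(missing_keys)) {
    stop("malformed trial header, missing: ",
         paste(missing_keys, collapse = ", "))
  }
  body <- lines[!hdr & nzchar(lines)]
  if (!length(body)) stop("trial file contains no frames")
  rows <- strsplit(body, ",", fixed = TRUE)
  nc <- lengths(rows)
  if (any(nc != 84)) {
    i <- which(nc != 84)[1]
    stop(sprintf("frame row %d has %d columns, expected 84", i, nc[i]))
  }
  frames <- matrix(NA_real_, length(rows), 84)
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]]))
    if (anyNA(v)) {
      stop(sprintf("non-numeric cell at frame row %d, column %d",
                   i, which(is.na(v))[1]))
    }
    frames[i, ] <- v
  }
  trial_recording(frames, task_label = vals[["task_label"]],
                  subject_id = vals[["subject_id"]],
                  trial_index = as.integer(vals[["trial_index"]]),
                  fps = as.numeric(vals[["fps"]]),
                  coordinate_frame = vals[["coordinate_frame"]])
}

#' Write a list of trials as a directory bundle with a manifest
#'
#' @param trials List of `trial_recording`s.
#' @param dir Output directory (created if needed).
#' @param extra Optional data.frame of per-trial manifest columns (e.g.
#'   hand scale, calibration flag), one row per trial.
#' @return Path of the manifest file, invisibly.
#' @export
write_trial_bundle <- function(trials, dir, extra = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(
    file = sprintf("trial_%04d.csv", seq_along(trials)),
    subject_id = vapply(trials, `[[`, "", "subject_id"),
    task_label = vapply(trials, `[[`, "", "task_label"),
    trial_index = vapply(trials, function(t) t$trial_index, 1L),
    n_frames = vapply(trials, n_frames, 1L),
    fps = vapply(trials, `[[`, 1, "fps"),
    coordinate_frame = vapply(trials, `[[`, "", "coordinate_frame"),
    stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    stopifnot(nrow(extra) == length(trials))
    manifest <- cbind(manifest, extra)
  }
  for (i in seq_along(trials)) {
    write_trial(trials[[i]], file.path(dir, manifest$file[i]))
  }
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a trial bundle written by [write_trial_bundle()]
#'
#' @param dir Bundle directory.
#' @return List with `trials` (list of `trial_recording`) and `manifest`
#'   (data.frame).
#' @export
read_trial_bundle <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv in ", dir)
  manifest <- read.csv(mpath, stringsAsFactors = FALSE)
  trials <- lapply(manifest$file, function(f) read_trial(file.path(dir, f)))
  list(trials = trials, manifest = manifest)
}
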