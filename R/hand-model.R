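#' @useDynLib graspADL, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runmed median rnorm runif sd var fft predict
#' @importFrom utils read.csv write.csv head
"_PACKAGE"

# ---------------------------------------------------------------------------
# Frame layout
#
# One tracking frame is a flat vector of 84 values = 28 points x 3 (mm):
#   cols  1:3   palm center C
#   cols  4:12  hand basis: h (finger direction), n (palm normal), b = h x n
#   cols 13:24  thumb:  CMC, MCP, DIP, tip          (no intermediate phalanx)
#   cols 25:84  index/middle/ring/pinky, 15 cols each:
#               CMC (metacarpal root), MCP, PIP, DIP, tip
# For feature equations every finger exposes the four roles mcp/pip/dip/tip;
# the thumb's CMC/MCP/DIP/tip fill those roles, the other fingers drop their
# CMC root. This ordering is a documented convention of this package: the
# upstream device documentation never enumerates the 28 points.
# ---------------------------------------------------------------------------

FINGERS <- c("thumb", "index", "middle", "ring", "pinky")
ROLES <- c("mcp", "pip", "dip", "tip")
LAYOUT_VERSION <- "graspADL-84-v1"

.point_cols <- local({
  pts <- list(
    C = 1:3, h = 4:6, n = 7:9, b = 10:12,
    thumb = list(cmc = 13:15, mcp = 16:18, dip = 19:21, tip = 22:24)
  )
  start <- 25L
  for (f in c("index", "middle", "ring", "pinky")) {
    pts[[f]] <- list(
      cmc = start + 0:2, mcp = start + 3:5, pip = start + 6:8,
      dip = start + 9:11, tip = start + 12:14
    )
    start <- start + 15L
  }
  pts
})

# Columns of the point filling a given role for a given finger.
.role_cols <- local({
  out <- list()
  for (f in FINGERS) {
    p <- .point_cols[[f]]
    out[[f]] <- if (f == "thumb") {
      list(mcp = p$cmc, pip = p$mcp, dip = p$dip, tip = p$tip)
    } else {
      list(mcp = p$mcp, pip = p$pip, dip = p$dip, tip = p$tip)
    }
  }
  out
})

POSITION_COLS <- c(1:3, 13:84)   # translate under rigid motion
DIRECTION_COLS <- 4:12           # rotate only
HCS_FEATURE_COLS <- 13:84        # non-constant channels once in HCS

#' Frame layout used for the flat 84-value representation
#'
#' @return A named list with the column indices of every stored point
#'   (palm center `C`, basis `h`, `n`, `b`, and per-finger joints), the
#'   role-resolved columns used by the feature equations, and the layout
#'   version string written to trial files.
#' @export
hand_layout <- function() {
  list(points = .point_cols, roles = .role_cols,
       position_cols = POSITION_COLS, direction_cols = DIRECTION_COLS,
       version = LAYOUT_VERSION)
}

#' The eight ADL task names
#'
#' Ordered task vocabulary (cup, fork, key, knife, nail clipper, pen,
#' spherical doorknob, spoon) with contiguous class indices 0-7.
#'
#' @return Character vector of length 8; names are the class indices.
#' @export
task_vocabulary <- function() {
  tasks <- c("cup", "fork", "key", "knife", "nail_clipper", "pen",
             "spherical_doorknob", "spoon")
  names(tasks) <- as.character(0:7)
  tasks
}

#' Class index (0-7) of a task label
#' @param task_label Character vector of task names.
#' @return Integer vector of 0-based class indices.
#' @export
task_index <- function(task_label) {
  idx <- match(task_label, task_vocabulary())
  if (anyNA(idx)) {
    stop("unknown task label(s): ",
         paste(unique(task_label[is.na(idx)]), collapse = ", "))
  }
  idx - 1L
}

# Re-orthonormalise a stored (h, n, b) triad: keep the direction of h,
# project n against it, rebuild b = h x n. Returns the triad plus the size
# of the correction that was applied.
.orthonormalize_basis <- function(h, n) {
  nh <- sqrt(sum(h^2))
  nn <- sqrt(sum(n^2))
  if (nh < 1e-12 || nn < 1e-12) {
    stop("degenerate hand basis: zero-length basis vector")
  }
  h1 <- h / nh
  n1 <- n - sum(n * h1) * h1
  nn1 <- sqrt(sum(n1^2))
  if (nn1 < 1e-12) stop("degenerate hand basis: h and n are collinear")
  n1 <- n1 / nn1
  b1 <- c(h1[2] * n1[3] - h1[3] * n1[2],
          h1[3] * n1[1] - h1[1] * n1[3],
          h1[1] * n1[2] - h1[2] * n1[1])
  list(h = h1, n = n1, b = b1)
}

#' Structure a flat 84-value frame row into a hand frame
#'
#' Splits one tracking frame into palm center, basis triad and per-finger
#' joint matrices. A slightly non-orthonormal stored basis is repaired by
#' projection (keeping `h`); a warning is emitted when the correction
#' exceeds 1e-3, which indicates corrupted rather than merely noisy data.
#'
#' @param row Numeric vector of 84 finite values (mm / unit vectors).
#' @return An object of class `hand_frame`: list with `C`, `h`, `n`, `b`
#'   (3-vectors), and `fingers`, a list of 3 x k joint matrices in stored
#'   order (thumb: cmc/mcp/dip/tip; other fingers: cmc/mcp/pip/dip/tip).
#' @seealso [flatten_frame()], its exact inverse.
#' @export
structure_frame <- function(row) {
  row <- as.numeric(row)
  if (length(row) != 84) {
    stop("frame row must have 84 values, got ", length(row))
  }
  if (!all(is.finite(row))) {
    stop("frame row contains non-finite values at position(s) ",
         paste(head(which(!is.finite(row)), 5), collapse = ", "))
  }
  h <- row[.point_cols$h]; n <- row[.point_cols$n]; b <- row[.point_cols$b]
  onb <- .orthonormalize_basis(h, n)
  corr <- max(sqrt(sum((onb$h - h)^2)), sqrt(sum((onb$n - n)^2)),
              sqrt(sum((onb$b - b)^2)))
  if (corr > 1e-3) {
    warning(sprintf(
      "stored hand basis deviates from orthonormality by %.2e; renormalized",
      corr))
  }
  fingers <- lapply(FINGERS, function(f) {
    p <- .point_cols[[f]]
    m <- vapply(p, function(cols) row[cols], numeric(3))
    rownames(m) <- c("x", "y", "z")
    m
  })
  names(fingers) <- FINGERS
  structure(
    list(C = row[.point_cols$C], h = row[.point_cols$h],
         n = row[.point_cols$n], b = row[.point_cols$b], fingers = fingers),
    class = "hand_frame")
}

#' Flatten a hand frame back to its 84-value row
#'
#' Exact inverse of [structure_frame()]: round-trips bit-exactly, including
#' a stored basis that needed renormalisation (the raw values are kept).
#'
#' @param frame A `hand_frame`.
#' @return Numeric vector of length 84.
#' @export
flatten_frame <- function(frame) {
  stopifnot(inherits(frame, "hand_frame"))
  row <- numeric(84)
  row[.point_cols$C] <- frame$C
  row[.point_cols$h] <- frame$h
  row[.point_cols$n] <- frame$n
  row[.point_cols$b] <- frame$b
  for (f in FINGERS) {
    p <- .point_cols[[f]]
    m <- frame$fingers[[f]]
    for (pt in names(p)) row[p[[pt]]] <- m[, pt]
  }
  row
}

#' Joint positions of one finger in feature roles
#'
#' Resolves the role mapping used by every feature equation: the thumb's
#' CMC/MCP/DIP/tip stand in for the MCP/PIP/DIP/tip roles, the other
#' fingers use their anatomical joints and drop the metacarpal root.
#'
#' @param frame A `hand_frame`.
#' @param finger One of `"thumb"`, `"index"`, `"middle"`, `"ring"`,
#'   `"pinky"`.
#' @return 3 x 4 matrix with columns `mcp`, `pip`, `dip`, `tip`.
#' @export
finger_joints <- function(frame, finger) {
  finger <- match.arg(finger, FINGERS)
  m <- frame$fingers[[finger]]
  cols <- if (finger == "thumb") c("cmc", "mcp", "dip", "tip") else ROLES
  out <- m[, cols, drop = FALSE]
  colnames(out) <- ROLES
  out
}
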