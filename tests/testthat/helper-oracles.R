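# Shared fixtures and independent brute-force oracles. Everything here is
# deliberately naive (loops, double sums, direct formulas) so it stays
# independent of the vectorised implementation paths it checks.

# A random valid 84-value frame row: random orthonormal basis, random palm
# center, random joint positions in a plausible mm range.
random_frame_row <- function() {
  R <- random_rotation()
  row <- numeric(84)
  row[1:3] <- rnorm(3, sd = 100)
  row[4:6] <- R[, 1]; row[7:9] <- R[, 2]; row[10:12] <- R[, 3]
  row[13:84] <- row[rep(1:3, 24)] + rnorm(72, sd = 60)
  row
}

random_trial <- function(n = 20, task = "cup", subject = "S1",
                         frame_fun = random_frame_row) {
  frames <- t(vapply(seq_len(n), function(i) frame_fun(), numeric(84)))
  trial_recording(frames, task, subject)
}

# layout helpers mirrored from the documented convention
lay <- hand_layout()
tipcols <- function(f) lay$roles[[f]]$tip

# sort-based running median with symmetric window shrink at the edges
oracle_running_median <- function(x, window) {
  n <- length(x)
  half <- (window - 1) %/% 2
  vapply(seq_len(n), function(i) {
    k <- min(half, i - 1, n - i)
    median(sort(x[(i - k):(i + k)]))
  }, 0)
}

# direct-formula geometric oracles on one raw frame row
oracle_angle <- function(u, v) acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
frame_pt <- function(row, f, role) row[lay$roles[[f]][[role]]]

oracle_afa <- function(row) {
  C <- row[1:3]
  fingers <- names(lay$roles)
  vapply(1:4, function(i) {
    oracle_angle(row[tipcols(fingers[i])] - C,
                 row[tipcols(fingers[i + 1])] - C) / pi
  }, 0)
}

oracle_atd <- function(row, M) {
  fingers <- names(lay$roles)
  vapply(1:4, function(i) {
    sqrt(sum((row[tipcols(fingers[i])] - row[tipcols(fingers[i + 1])])^2)) / M
  }, 0)
}

oracle_nptd <- function(row, M) {
  C <- row[1:3]
  vapply(names(lay$roles), function(f) {
    sqrt(sum((row[tipcols(f)] - C)^2)) / M
  }, 0, USE.NAMES = FALSE)
}

oracle_dpuv <- function(row) {
  unlist(lapply(names(lay$roles), function(f) {
    v <- row[tipcols(f)] - frame_pt(row, f, "dip")
    v / sqrt(sum(v^2))
  }))
}

oracle_ja <- function(row) {
  C <- row[1:3]
  unlist(lapply(names(lay$roles), function(f) {
    m <- frame_pt(row, f, "mcp"); p <- frame_pt(row, f, "pip")
    d <- frame_pt(row, f, "dip"); t <- frame_pt(row, f, "tip")
    c(oracle_angle(m - C, p - m), oracle_angle(p - m, d - p),
      oracle_angle(d - p, t - d)) / pi
  }))
}

oracle_fha <- function(row) {
  C <- row[1:3]; h <- row[4:6]; nv <- row[7:9]
  vapply(names(lay$roles), function(f) {
    Fi <- row[tipcols(f)]
    Fip <- Fi - sum((Fi - C) * nv) * nv
    oracle_angle(Fip - C, h) / pi
  }, 0, USE.NAMES = FALSE)
}

oracle_fte <- function(row, M) {
  C <- row[1:3]; nv <- row[7:9]
  vapply(names(lay$roles), function(f) {
    Fi <- row[tipcols(f)]
    d <- sum((Fi - C) * nv)
    Fip <- Fi - d * nv
    sign(d) * sqrt(sum((Fi - Fip)^2)) / M
  }, 0, USE.NAMES = FALSE)
}

# loop implementations of the windowed time-domain features (Eqs. as sums)
oracle_td_window <- function(seg) {
  N <- length(seg)
  xbar <- sum(seg) / N
  list(mav = sum(abs(seg)) / N,
       rms = sqrt(sum(seg^2) / N),
       var = sum((seg - xbar)^2) / (N - 1),
       wl = sum(abs(diff(seg))))
}

# naive O(N^2) double-sum DFT magnitudes
oracle_dft_mag <- function(x, kept) {
  N <- length(x)
  vapply(seq_len(kept) - 1, function(k) {
    s <- 0 + 0i
    for (n in 0:(N - 1)) s <- s + x[n + 1] * exp(-2i * pi * n * k / N)
    Mod(s)
  }, 0)
}

# independent per-class metric computation on a confusion matrix
oracle_metrics <- function(cm) {
  k <- nrow(cm)
  prec <- rec <- f1 <- numeric(k)
  for (c in seq_len(k)) {
    tp <- cm[c, c]
    prec[c] <- if (sum(cm[, c]) > 0) tp / sum(cm[, c]) else 0
    rec[c] <- if (sum(cm[c, ]) > 0) tp / sum(cm[c, ]) else 0
    f1[c] <- if (prec[c] + rec[c] > 0) {
      2 * prec[c] * rec[c] / (prec[c] + rec[c])
    } else 0
  }
  list(accuracy = sum(diag(cm)) / sum(cm), macro_precision = mean(prec),
       macro_recall = mean(rec), macro_f1 = mean(f1))
}

# short motion profile used throughout the tests (compute budget; the
# generator's noise/jitter defaults are untouched)
short_profile <- function(...) {
  motion_profile(static_duration = 1.5, dynamic_duration = 1,
                 repetitions = 2, ...)
}

# scale a trial's coordinates by s: positions are mm and scale; the stored
# basis is a dimensionless unit triad and does not
scale_trial <- function(trial, s) {
  trial$frames[, lay$position_cols] <- trial$frames[, lay$position_cols] * s
  trial
}

# time-varying rigid motion: one random rigid transform per frame
random_motion <- function(n) {
  lapply(seq_len(n), function(i) {
    rigid_transform(random_rotation(), rnorm(3, sd = 200))
  })
}

all_feature_names <- c("AFA", "ATD", "DPUV", "NPTD", "JA", "FHA", "FTE",
                       "MAV", "RMS", "VAR", "WL", "DFT")
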