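test_that("rigid transforms move positions and rotate directions", {
  set.seed(21)
  tr <- random_trial(6)
  # identity leaves the trial untouched
  expect_equal(apply_rigid_transform(tr, rigid_transform())$frames,
               tr$frames)
  # pure translation: palm shifts, basis unchanged
  t3 <- c(10, -20, 5)
  shifted <- apply_rigid_transform(tr, rigid_transform(translation = t3))
  expect_equal(shifted$frames[, 1:3], tr$frames[, 1:3] + rep(t3, each = 6))
  expect_equal(shifted$frames[, 4:12], tr$frames[, 4:12])
  # any rigid transform preserves pairwise joint distances
  T1 <- rigid_transform(random_rotation(), rnorm(3, sd = 100))
  moved <- apply_rigid_transform(tr, T1)
  for (i in 1:6) {
    pts0 <- matrix(tr$frames[i, lay$position_cols], nrow = 3)
    pts1 <- matrix(moved$frames[i, lay$position_cols], nrow = 3)
    expect_equal(as.numeric(dist(t(pts1))), as.numeric(dist(t(pts0))),
                 tolerance = 1e-9)
  }
  expect_error(rigid_transform(matrix(rnorm(9), 3, 3)), "orthonormal")
  # reflections (det -1) are not rigid hand motions
  expect_error(rigid_transform(diag(c(1, 1, -1))), "determinant")
})

test_that("to_hcs matches a per-point linear solve and zeroes the palm", {
  set.seed(22)
  tr <- random_trial(5)
  hcs <- to_hcs(tr)
  expect_identical(hcs$coordinate_frame, "HCS")
  for (i in 1:5) {
    row <- tr$frames[i, ]
    A <- cbind(row[4:6], row[7:9], row[10:12])
    for (p in seq(13, 82, by = 3)) {
      x <- solve(A, row[p + 0:2] - row[1:3])
      expect_equal(as.numeric(hcs$frames[i, p + 0:2]), as.numeric(x),
                   tolerance = 1e-9)
    }
  }
  expect_true(all(hcs$frames[, 1:3] == 0))
  expect_equal(hcs$frames[, 4:12],
               matrix(rep(as.numeric(diag(3)), each = 5), 5, 9))
  # identity basis, palm at origin: positions pass through unchanged
  row0 <- numeric(84)
  row0[4:12] <- as.numeric(diag(3))
  row0[13:84] <- rnorm(72)
  t0 <- trial_recording(rbind(row0), "cup", "S1")
  expect_equal(to_hcs(t0)$frames[1, 13:84], row0[13:84])
})

test_that("HCS output is invariant to time-varying rigid motion", {
  set.seed(23)
  for (rep in 1:3) {
    tr <- random_trial(8)
    moved <- apply_rigid_transform(tr, random_motion(8))
    h0 <- to_hcs(tr)$frames
    h1 <- to_hcs(moved)$frames
    expect_equal(h1, h0, tolerance = 1e-9)
  }
})

test_that("median filter matches the sort-based oracle", {
  set.seed(24)
  tr <- random_trial(30)
  filt <- median_filter_trial(tr, 5)
  for (ch in sample(1:84, 10)) {
    expect_equal(filt$frames[, ch], oracle_running_median(tr$frames[, ch], 5))
  }
  # spike removal and constant channels
  x <- c(0, 0, 9, 0, 0)
  expect_equal(oracle_running_median(x, 5)[3], 0)
  const <- trial_recording(matrix(3, 7, 84), "cup", "S1")
  expect_equal(median_filter_trial(const, 5)$frames, const$frames)
  # window bounded by per-window min/max
  w7 <- median_filter_trial(tr, 7)$frames
  expect_true(all(w7 >= min(tr$frames) & w7 <= max(tr$frames)))
  expect_error(median_filter_trial(tr, 4), "odd")
  expect_error(median_filter_trial(tr, -3), "odd|positive")
  expect_error(median_filter_trial(random_trial(3), 5), "exceeds")
})

test_that("apply_rigid_transform guards its preconditions", {
  tr <- random_trial(3)
  hcs <- to_hcs(tr)
  expect_error(apply_rigid_transform(hcs, rigid_transform()), "GCS")
  expect_error(apply_rigid_transform(tr, list(rigid_transform())),
               "length|must")
})
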