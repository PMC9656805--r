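test_that("hand length M: unit chain, homogeneity, loop oracle", {
  # middle-finger chain with four unit segments along x
  row <- numeric(84)
  row[4:12] <- as.numeric(diag(3))
  r <- lay$roles$middle
  row[r$mcp] <- c(1, 0, 0); row[r$pip] <- c(2, 0, 0)
  row[r$dip] <- c(3, 0, 0); row[r$tip] <- c(4, 0, 0)
  tr <- trial_recording(matrix(row, 30, 84, byrow = TRUE), "cup", "S1")
  expect_equal(hand_length(tr)$M, 4)

  set.seed(31)
  tr2 <- random_trial(35)
  M <- hand_length(tr2)$M
  # homogeneity under coordinate scaling
  expect_equal(hand_length(scale_trial(tr2, 2.5))$M, 2.5 * M)
  # brute-force per-frame loop oracle
  acc <- 0
  for (i in 1:30) {
    rw <- tr2$frames[i, ]
    pts <- rbind(rw[1:3], rw[lay$roles$middle$mcp], rw[lay$roles$middle$pip],
                 rw[lay$roles$middle$dip], rw[lay$roles$middle$tip])
    acc <- acc + sum(sqrt(rowSums(diff(pts)^2)))
  }
  expect_equal(M, acc / 30)
  expect_error(hand_length(random_trial(10)), "need at least 30")
})

test_that("single-frame features reproduce their closed-form cases", {
  # hand with identity basis; fingertips placed explicitly
  row <- numeric(84)
  row[4:12] <- as.numeric(diag(3))
  for (f in names(lay$roles)) {
    row[lay$roles[[f]]$mcp] <- c(1, 0, 0)
    row[lay$roles[[f]]$pip] <- c(2, 0, 0)
    row[lay$roles[[f]]$dip] <- c(3, 0, 0)
    row[lay$roles[[f]]$tip] <- c(4, 0, 0)
  }
  # thumb/index tips orthogonal as seen from C; index/middle parallel
  row[lay$roles$thumb$tip] <- c(0, 0, 2)
  fr <- structure_frame(row)
  a <- afa(fr)
  expect_equal(unname(a[1]), 0.5)   # orthogonal
  expect_equal(unname(a[2]), 0)     # parallel
  # straight collinear bones: JA zero; right angle at DIP: 0.5
  expect_equal(max(abs(ja(fr)[-(1:3)])), 0, tolerance = 1e-9)
  row2 <- row
  row2[lay$roles$index$tip] <- row2[lay$roles$index$dip] + c(0, 0, 1)
  expect_equal(unname(ja(structure_frame(row2))["JA.index.dip"]), 0.5)
  # ATD: coincident tips 0; 10 mm apart with M=20 gives 0.5
  expect_equal(unname(atd(fr, 20)[2]), 0)
  row3 <- row
  row3[lay$roles$middle$tip] <- row3[lay$roles$ring$tip] + c(0, 10, 0)
  expect_equal(unname(atd(structure_frame(row3), 20)[3]), 0.5)
  # DPUV: unit vector along the distal phalanx
  row4 <- row
  row4[lay$roles$pinky$dip] <- c(0, 0, 0)
  row4[lay$roles$pinky$tip] <- c(0, 0, 2)
  expect_equal(unname(dpuv(structure_frame(row4))[13:15]), c(0, 0, 1))
  # NPTD: tip at distance M from C gives exactly 1
  row5 <- row
  row5[lay$roles$index$tip] <- c(0, 20, 0)
  expect_equal(unname(nptd(structure_frame(row5), 20)["NPTD.index"]), 1)
  # FHA: projection along +h gives 0; along -h gives 1
  expect_equal(unname(fha(fr)["FHA.middle"]), 0)
  row6 <- row
  row6[lay$roles$ring$tip] <- c(-3, 1, 0)
  expect_equal(unname(fha(structure_frame(row6))["FHA.ring"]), 1)
  # FTE: on-plane 0; at C + M*n exactly +1; at C - M*n exactly -1
  expect_equal(unname(fte(fr, 20)["FTE.middle"]), 0)
  row7 <- row
  row7[lay$roles$index$tip] <- c(0, 20, 0)
  row7[lay$roles$ring$tip] <- c(0, -20, 0)
  v <- fte(structure_frame(row7), 20)
  expect_equal(unname(v[c("FTE.index", "FTE.ring")]), c(1, -1))
})

test_that("vectorised blocks agree with direct-formula oracles", {
  set.seed(32)
  tr <- random_trial(50)
  M <- 137.5
  checks <- list(
    AFA = function(rw) oracle_afa(rw),
    ATD = function(rw) oracle_atd(rw, M),
    DPUV = function(rw) oracle_dpuv(rw),
    NPTD = function(rw) oracle_nptd(rw, M),
    JA = function(rw) oracle_ja(rw),
    FHA = function(rw) oracle_fha(rw),
    FTE = function(rw) oracle_fte(rw, M))
  for (nm in names(checks)) {
    blk <- geometric_block(tr, nm, M)
    orc <- t(apply(tr$frames, 1, checks[[nm]]))
    expect_equal(unname(unclass(blk)), unname(orc), tolerance = 1e-9,
                 label = nm, ignore_attr = TRUE)
    # and the single-frame functions agree with the block path
    f1 <- structure_frame(tr$frames[7, ])
    single <- switch(nm, AFA = afa(f1), ATD = atd(f1, M), DPUV = dpuv(f1),
                     NPTD = nptd(f1, M), JA = ja(f1), FHA = fha(f1),
                     FTE = fte(f1, M))
    expect_equal(unname(single), unname(blk[7, ]), tolerance = 1e-12,
                 label = nm)
  }
})

test_that("feature ranges and normalisation invariants hold", {
  set.seed(33)
  tr <- random_trial(40)
  M <- hand_length(random_trial(30))$M
  for (nm in c("AFA", "JA", "FHA")) {
    v <- geometric_block(tr, nm, M)
    expect_true(all(v >= 0 & v <= 1), label = nm)
  }
  expect_true(all(geometric_block(tr, "ATD", M) >= 0))
  expect_true(all(geometric_block(tr, "NPTD", M) >= 0))
  d <- geometric_block(tr, "DPUV")
  for (k in 0:4) {
    norms <- sqrt(rowSums(d[, 3 * k + 1:3]^2))
    expect_equal(norms, rep(1, 40), tolerance = 1e-12)
  }
  # FTE flips sign when the palm normal is negated (b rebuilt by repair)
  fr <- structure_frame(tr$frames[1, ])
  neg <- tr$frames[1, ]
  neg[7:9] <- -neg[7:9]; neg[10:12] <- -neg[10:12]
  expect_equal(unname(fte(structure_frame(neg), M)),
               -unname(fte(fr, M)), tolerance = 1e-12)
})
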