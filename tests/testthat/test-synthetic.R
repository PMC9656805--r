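straight_archetype <- function(task = "cup") {
  grasp_archetype(task, flexion = matrix(0, 5, 3), abduction = rep(0, 5),
                  opposition = 0)
}

test_that("forward kinematics honors the straight-finger limit", {
  fr <- forward_kinematics(straight_archetype(), hand_geometry())
  expect_equal(max(abs(ja(fr))), 0, tolerance = 1e-6)
  expect_equal(max(abs(fte(fr, 146))), 0, tolerance = 1e-9)
  # a right-angle DIP flexion shows up as a 0.5 joint-angle feature
  a <- straight_archetype()
  a$flexion["index", "dip"] <- pi / 2
  fr2 <- forward_kinematics(a, hand_geometry())
  expect_equal(unname(ja(fr2)["JA.index.dip"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(ja(fr2)["JA.index.mcp"]), 0, tolerance = 1e-6)
})

test_that("segment lengths equal the hand geometry for random angles", {
  set.seed(91)
  geom <- hand_geometry(1.07)
  for (i in 1:5) {
    arch <- grasp_archetype("pen",
      flexion = matrix(runif(15, 0, pi * 0.7), 5, 3),
      abduction = runif(5, -pi / 6, pi / 6),
      opposition = runif(1, 0, 1.2))
    pose <- rigid_transform(random_rotation(), rnorm(3, sd = 100))
    fr <- forward_kinematics(arch, geom, pose)
    for (f in c("thumb", "index", "middle", "ring", "pinky")) {
      j <- finger_joints(fr, f)
      lens <- sqrt(colSums((j[, -1] - j[, -4])^2))
      expect_equal(unname(lens),
                   unname(c(geom$L1[[f]], geom$L2[[f]], geom$L3[[f]])),
                   tolerance = 1e-9)
      expect_equal(sqrt(sum((j[, "mcp"] - fr$C)^2)), unname(geom$r[[f]]),
                   tolerance = 1e-9)
    }
  }
  expect_error(grasp_archetype("pen", matrix(3, 5, 3), rep(0, 5)),
               "flexion")
  expect_error(grasp_archetype("pen", matrix(0, 5, 3), rep(1, 5)),
               "abduction")
})

test_that("generate_trial: determinism, phases, HCS constancy", {
  arch <- default_archetypes()$knife
  geom <- hand_geometry()
  # zero jitter/noise, no dynamic phase: all frames identical
  p0 <- motion_profile(static_duration = 0.5, dynamic_duration = 0,
                       repetitions = 0, articulation_jitter_sd = 0,
                       sensor_noise_sd = 0)
  t0 <- generate_trial(arch, geom, p0, seed = 1)
  expect_equal(nrow(t0$frames), 15)
  expect_equal(t0$frames, t0$frames[rep(1, 15), ])
  # with gross motion but no noise, the HCS view is constant
  p1 <- motion_profile(static_duration = 0.5, dynamic_duration = 1,
                       repetitions = 2, articulation_jitter_sd = 0,
                       sensor_noise_sd = 0)
  t1 <- generate_trial(arch, geom, p1, seed = 2)
  h <- to_hcs(t1)$frames
  expect_equal(max(abs(sweep(h, 2, h[1, ]))), 0, tolerance = 1e-9)
  # and the GCS view is genuinely moving during the dynamic phase
  expect_gt(max(abs(t1$frames[20, 1:3] - t1$frames[16, 1:3])), 1)
  # determinism
  t2 <- generate_trial(arch, geom, short_profile(), seed = 77)
  t3 <- generate_trial(arch, geom, short_profile(), seed = 77)
  expect_identical(t2$frames, t3$frames)
  expect_error(generate_trial(arch, geom,
                              motion_profile(static_duration = 0,
                                             dynamic_duration = 0,
                                             repetitions = 0)),
               "zero frames")
})

test_that("dataset generation: counts, manifest, reproducibility", {
  ds <- generate_dataset(n_subjects = 2, trials_per_task = 1,
                         profile = motion_profile(static_duration = 1.2,
                                                  dynamic_duration = 0,
                                                  repetitions = 0),
                         seed = 5)
  expect_length(ds$trials, 16)
  expect_equal(sum(ds$manifest$is_calibration), 2)
  expect_length(unique(ds$manifest$hand_scale), 2)
  ds2 <- generate_dataset(n_subjects = 2, trials_per_task = 1,
                          profile = motion_profile(static_duration = 1.2,
                                                   dynamic_duration = 0,
                                                   repetitions = 0),
                          seed = 5)
  expect_identical(ds$trials[[7]]$frames, ds2$trials[[7]]$frames)
  expect_error(generate_dataset(default_archetypes()[1:5]), "8 archetypes")
})

test_that("hand length scales linearly with hand-size scale", {
  p <- motion_profile(static_duration = 1.2, dynamic_duration = 0,
                      repetitions = 0, articulation_jitter_sd = 0,
                      sensor_noise_sd = 0)
  arch <- default_archetypes()$cup
  t1 <- generate_trial(arch, hand_geometry(1), p, seed = 3)
  t2 <- generate_trial(arch, hand_geometry(1.3), p, seed = 3)
  M1 <- hand_length(to_hcs(t1), 30)$M
  M2 <- hand_length(to_hcs(t2), 30)$M
  expect_equal(M2 / M1, 1.3, tolerance = 1e-9)
  # M-normalised features are invariant across pure size change
  f1 <- geometric_block(to_hcs(t1), "NPTD", M1)
  f2 <- geometric_block(to_hcs(t2), "NPTD", M2)
  expect_equal(unclass(f2), unclass(f1), tolerance = 1e-9)
})

test_that("variance features are bounded by the articulation-noise level", {
  sigma <- 0.02
  p <- motion_profile(static_duration = 1, dynamic_duration = 1,
                      repetitions = 1, articulation_jitter_sd = sigma)
  for (tk in c("cup", "key", "pen")) {
    tr <- preprocess_trial(generate_trial(default_archetypes()[[tk]],
                                          hand_geometry(), p, seed = 13))
    M <- hand_length(to_hcs(generate_trial(default_archetypes()$cup,
                                           hand_geometry(), p, seed = 13)))
    td <- windowed_td_features(tr, M, 15)
    # per-channel coordinate sd from angle jitter is at most ~2*sigma in
    # M-normalised units (chain length ~ M); generous a-priori factors
    expect_lt(max(td$VAR), (4 * sigma)^2)
    expect_lt(max(td$WL), 14 * 8 * sigma)
  }
})

test_that("without angular jitter, variance features carry no class signal", {
  # control for the known acceptance-6b failure: when articulation noise is
  # zero and only coordinate (sensor) noise remains, VAR is class-blind and
  # classification collapses to near chance (1/8)
  p0 <- motion_profile(static_duration = 1.5, dynamic_duration = 1,
                       repetitions = 1, articulation_jitter_sd = 0)
  ds <- generate_dataset(n_subjects = 3, trials_per_task = 1,
                         profile = p0, seed = 29)
  pp <- lapply(ds$trials, preprocess_trial)
  Ms <- calibration_hand_lengths(ds)
  fm <- build_feature_matrix(pp, Ms, "VAR")
  res <- suppressWarnings(
    train_eval_svm(fm, make_folds(fm, 5, seed = 29)))
  expect_lt(res$mean$accuracy, 0.40)
})
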