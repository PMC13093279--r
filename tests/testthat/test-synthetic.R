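test_that("marker layouts carry the documented roles and spacing", {
  for (setup in c("abdominal", "hn")) {
    lay <- make_layout(setup)
    expect_equal(nrow(lay), 26)
    expect_equal(anyDuplicated(lay$marker), 0)
    # no two markers closer than the 20 mm nearest-neighbour safety margin
    P <- as.matrix(lay[, c("x", "y", "z")])
    D <- as.matrix(stats::dist(P))
    diag(D) <- Inf
    expect_gt(min(D), 20)
  }
  ab <- make_layout("abdominal")
  expect_equal(sum(ab$role == "body_respiratory"), 9)
  expect_equal(sum(ab$role == "thigh"), 2)
  expect_setequal(ab$marker[ab$role == "thigh"], c("A10", "A11"))
  expect_setequal(ab$marker[ab$role == "body_respiratory"], paste0("A", 1:9))
  hn <- make_layout("hn")
  expect_gt(sum(hn$role == "body_rigid"), 2)
  expect_equal(sum(hn$role %in% c("body_rigid", "mask")), 26)
})

test_that("default rig frames every marker with well-conditioned ray pairs", {
  for (setup in c("abdominal", "hn")) {
    cfg <- scene_config(setup, seed = 2)
    rig <- make_rig(cfg)
    lay <- make_layout(setup)
    P <- as.matrix(lay[, c("x", "y", "z")])
    for (cam in rig) {
      uv <- project(cam$intr, cam$pose, P)
      expect_true(all(uv[, 1] > 0 & uv[, 1] < cam$intr$width))
      expect_true(all(uv[, 2] > 0 & uv[, 2] < cam$intr$height))
    }
    # every marker's assigned pair triangulates with a healthy ray angle
    for (i in seq_len(nrow(lay))) {
      pair <- select_camera_pair(lay$side[i])
      tri <- triangulate_pair(rig[[pair[1]]], rig[[pair[2]]],
                              project(rig[[pair[1]]]$intr, rig[[pair[1]]]$pose, P[i, ]),
                              project(rig[[pair[2]]]$intr, rig[[pair[2]]]$pose, P[i, ]))
      expect_gt(tri$ray_angle_deg, 20)
    }
  }
})

test_that("saturating drift follows its closed form", {
  cfg <- quiet_cfg(duration_s = 300, seed = 13,
                   drift = list(amp = c(lr = 0, ap = 0, si = 2, pitch = 0,
                                        roll = 0, yaw = 0), tau_s = 150))
  sim <- simulate_intrafraction(cfg)
  truth <- dplyr::filter(sim$truth$displacement, .data$object == "body",
                         .data$time_s == 150)
  expect_equal(truth$si, 2 * (1 - exp(-1)), tolerance = 1e-9)
  # monotone in t
  body <- dplyr::filter(sim$truth$displacement, .data$object == "body")
  expect_true(all(diff(body$si) >= 0))
})

test_that("the same seed reproduces the full sample path bit-exactly", {
  cfg <- scene_config(seed = 77, duration_s = 30)
  s1 <- simulate_intrafraction(cfg)
  s2 <- simulate_intrafraction(cfg)
  expect_identical(s1$detections, s2$detections)
  expect_identical(s1$clouds, s2$clouds)
  s3 <- simulate_intrafraction(scene_config(seed = 78, duration_s = 30))
  expect_false(identical(s1$detections$u, s3$detections$u))
})

test_that("dropout frequency is binomially consistent with its rate", {
  cfg <- scene_config(seed = 14, duration_s = 1200, dropout = 0.04)
  sim <- simulate_intrafraction(cfg)
  flags <- !sim$clouds$valid[sim$clouds$frame > 0]
  n <- length(flags)
  expect_equal(n, 240 * 26)
  phat <- mean(flags)
  half <- stats::qnorm(0.995) * sqrt(0.04 * 0.96 / n)
  expect_gt(phat, 0.04 - half)
  expect_lt(phat, 0.04 + half)
  # reference frame never drops
  expect_true(all(sim$clouds$valid[sim$clouds$frame == 0]))
})

test_that("inter-fractional generator honours its degenerate cases", {
  cfg <- scene_config(seed = 15,
                      interfraction = list(sigma_sys = rep(0, 6),
                                           sigma_rand = rep(0, 6)))
  inter <- simulate_interfraction(cfg, n_subjects = 3, n_reps = 4,
                                  emit = "clouds")
  expect_true(all(abs(as.matrix(inter$truth[, c("lr", "ap", "si", "pitch",
                                                "roll", "yaw")])) < 1e-12))
  ref <- dplyr::filter(inter$clouds, .data$subject == 1, .data$frame == 0)
  rep3 <- dplyr::filter(inter$clouds, .data$subject == 1, .data$frame == 3)
  expect_equal(rep3$x, ref$x, tolerance = 1e-12)

  # a single repetition leaves the random component undefined downstream
  cfg2 <- scene_config(seed = 16)
  one <- simulate_interfraction(cfg2, n_subjects = 3, n_reps = 1)
  expect_message(s <- interfraction_summary(one$truth), "single repetition")
  expect_true(all(is.na(s$by_axis$sigma_random)))
})

test_that("grid fixture emits complete, reproducible detections", {
  cfg <- scene_config(seed = 17)
  fx <- grid_fixture(cfg, n_poses = 2, noise_px = 0.3)
  expect_equal(nrow(fx$plate), 2378)
  per <- dplyr::count(fx$calibration, .data$pose_id, .data$camera)
  expect_true(all(per$n == 2378))
  fx2 <- grid_fixture(cfg, n_poses = 2, noise_px = 0.3)
  expect_identical(fx$calibration, fx2$calibration)
})

test_that("rig serialization round-trips bit-exactly", {
  cfg <- scene_config(seed = 18)
  rig <- make_rig(cfg)
  for (cam in rig) {
    back <- rt_from_json(rt_to_json(cam$pose$pose))
    expect_identical(back$transform$R, cam$pose$pose$R)
    expect_identical(back$transform$t, cam$pose$pose$t)
  }
})

test_that("respiratory leakage into the tracked body stays within the gain bound", {
  amp <- c(lr = 0.5, ap = 2, si = 0.8)
  cfg <- scene_config(seed = 19, duration_s = 400, pixel_noise_px = 0,
                      dropout = 0, thigh_amp_mm = 0,
                      respiration = list(amp = amp, period_s = 4))
  sim <- simulate_intrafraction(cfg)
  tr <- track_sequence(sim$clouds, "abdominal", smooth = TRUE)
  ser <- displacement_series(tr, sim$origin, objects = "body")
  truth <- dplyr::filter(sim$truth$displacement, .data$object == "body")
  m <- dplyr::inner_join(ser, truth, by = "frame")
  gain <- ma_gain(0.25, 5)
  core <- dplyr::filter(m, .data$frame >= 2, .data$frame <= max(.data$frame) - 2)
  for (ax in c("lr", "ap", "si")) {
    resid <- core[[paste0(ax, ".x")]] - core[[paste0(ax, ".y")]]
    expect_lt(max(abs(resid)), gain * max(amp) * 1.05 + 1e-9)
  }
})
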