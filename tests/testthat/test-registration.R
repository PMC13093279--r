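cloud_from_layout <- function(layout, transform = NULL, frame = 0,
                              time_s = frame * 5) {
  out <- layout
  if (!is.null(transform)) {
    xyz <- rt_apply(transform, as.matrix(layout[, c("x", "y", "z")]))
    out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
  }
  out$frame <- frame
  out$time_s <- time_s
  out
}

test_that("kabsch recovers exact transforms and honest residuals", {
  lay <- make_layout("abdominal")
  P <- as.matrix(lay[, c("x", "y", "z")])
  fit <- kabsch(P, P)
  expect_lt(max_transform_diff(fit$transform, rt_identity()), 1e-12)
  expect_equal(fit$rms_mm, 0, tolerance = 1e-12)

  Tr <- from_displacement(c(lr = 1, ap = 2, si = 3, pitch = 0, roll = 0,
                            yaw = 10))
  fit <- kabsch(P, rt_apply(Tr, P))
  expect_lt(max_transform_diff(fit$transform, Tr), 1e-9)

  # noisy correspondences: reported RMS equals brute-force RMSD of the fit
  set.seed(121)
  Q <- rt_apply(Tr, P) + matrix(stats::rnorm(length(P), 0, 0.3), ncol = 3)
  fit <- kabsch(P, Q)
  res <- rt_apply(fit$transform, P) - Q
  expect_equal(fit$rms_mm, sqrt(mean(rowSums(res^2))), tolerance = 1e-12)

  expect_error(kabsch(P[1:2, ], P[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch(line, line), "collinear")
})

test_that("nearest-neighbour ICP equals the labeled-Kabsch oracle", {
  lay <- make_layout("abdominal")
  ref <- cloud_from_layout(lay)
  set.seed(131)
  for (i in 1:25) {
    Tr <- random_small_transform(max_angle_deg = 1, max_trans_mm = 5)
    cur <- cloud_from_layout(lay, Tr, frame = 1)
    near <- icp(ref, cur, mode = "nearest")
    lab <- icp(ref, cur, mode = "labeled")
    expect_lt(max_transform_diff(near$transform, lab$transform), 1e-9)
    expect_lt(max_transform_diff(near$transform, Tr), 1e-9)
    expect_true(all(diff(near$rms_trace) <= 1e-12))
  }
  same <- icp(ref, ref, mode = "nearest")
  expect_lt(max_transform_diff(same$transform, rt_identity()), 1e-12)
})

test_that("ICP tolerates 4% random marker dropout", {
  lay <- make_layout("abdominal")
  ref <- cloud_from_layout(lay)
  set.seed(141)
  for (i in 1:20) {
    Tr <- random_small_transform(max_angle_deg = 1, max_trans_mm = 5)
    cur <- cloud_from_layout(lay, Tr, frame = 1)
    cur$valid <- stats::runif(nrow(cur)) > 0.04
    fit <- icp(ref, cur, mode = "nearest")
    expect_lt(max(abs(fit$transform$t - Tr$t)), 0.1)
  }
})

test_that("fewer than 3 usable markers flags the frame unregistered", {
  lay <- make_layout("abdominal")
  ref <- cloud_from_layout(lay)
  cur <- cloud_from_layout(lay, frame = 1)
  cur$valid <- c(TRUE, TRUE, rep(FALSE, nrow(cur) - 2))
  fit <- icp(ref, cur)
  expect_null(fit$transform)
  expect_false(fit$converged)
})

test_that("leave-one-out marker stability for small motions", {
  lay <- make_layout("abdominal")
  body <- dplyr::filter(lay, .data$role == "body_respiratory")
  ref <- cloud_from_layout(body)
  set.seed(151)
  Tr <- random_small_transform(max_angle_deg = 1, max_trans_mm = 5)
  cur <- cloud_from_layout(body, Tr, frame = 1)
  full <- icp(ref, cur, mode = "nearest")$transform
  for (drop in body$marker) {
    fit <- icp(ref[ref$marker != drop, ], cur[cur$marker != drop, ],
               mode = "nearest")
    expect_lt(max(abs(fit$transform$t - full$t)), 0.2)
    ang <- to_displacement(rt_compose(fit$transform, rt_invert(full)))
    expect_lt(max(abs(ang[c("pitch", "roll", "yaw")])), 0.1)
  }
})

test_that("moving-average smoothing matches closed forms", {
  expect_equal(smooth_ma(rep(4, 10)), rep(4, 10))
  expect_equal(smooth_ma(1:5)[3], 3)
  # symmetric edge shrinkage: frame 1 keeps its raw value, frame 2
  # averages frames 1..3
  expect_equal(smooth_ma(1:5)[1], 1)
  expect_equal(smooth_ma(1:5)[2], 2)
  expect_equal(smooth_ma(1:5, mode = "trailing")[5], 3)
  expect_error(smooth_ma(numeric(0)), "at least one")

  # sinusoid of 4 s period sampled at 5 s: the aliased tone at 0.25
  # cycles/frame is attenuated by the closed-form Dirichlet gain
  n <- 2000
  t <- (0:(n - 1)) * 5
  x <- sin(2 * pi * t / 4)
  sm <- smooth_ma(x, window = 5)
  core <- 50:(n - 50)
  gain <- ma_gain(f = 1.25 %% 1, w = 5)
  expect_equal(max(abs(sm[core])), gain, tolerance = 0.01)
})

test_that("origin sits on the rotation axis at the anchor SI height", {
  lay <- make_layout("abdominal")
  lay$z[lay$marker == "A2"] <- 1100
  expect_equal(set_origin(lay, "abdominal", axis_lr = 0, axis_ap = 150),
               c(0, 150, 1100))
  # anchor on the axis: origin equals the anchor
  lay2 <- lay
  lay2$x[lay2$marker == "A2"] <- 0
  lay2$y[lay2$marker == "A2"] <- 150
  anchor <- unlist(lay2[lay2$marker == "A2", c("x", "y", "z")])
  expect_equal(unname(set_origin(lay2, "abdominal", 0, 150)), unname(anchor))
  # rule is SI-only: anchors differing only in SI shift the origin in SI only
  lay3 <- lay
  lay3$z[lay3$marker == "A2"] <- 900
  o1 <- set_origin(lay, "abdominal", 0, 150)
  o3 <- set_origin(lay3, "abdominal", 0, 150)
  expect_equal(o1[1:2], o3[1:2])
  expect_equal(o1[3] - o3[3], 200)

  lay$valid[lay$marker == "A2"] <- FALSE
  expect_error(set_origin(lay, "abdominal"), "missing or invalid")
})

test_that("track_sequence recovers a rigid drift trajectory exactly", {
  cfg <- quiet_cfg(duration_s = 60, seed = 8)
  sim <- simulate_intrafraction(cfg)
  tr <- track_sequence(sim$clouds, "abdominal", smooth = FALSE)
  expect_true(all(tr$frames$registered))
  expect_lt(max_transform_diff(tr$body[[1]], rt_identity()), 1e-12)
  for (k in seq_along(tr$body)) {
    expect_lt(max_transform_diff(tr$body[[k]], sim$truth$body[[k]]), 1e-6)
    expect_lt(max_transform_diff(tr$mask[[k]], sim$truth$mask[[k]]), 1e-6)
  }
  # identical frames -> identity transforms
  ref <- sim$clouds[sim$clouds$frame == 0, ]
  still <- dplyr::bind_rows(ref, dplyr::mutate(ref, frame = 1, time_s = 5))
  tr0 <- track_sequence(still, "abdominal", smooth = FALSE)
  expect_lt(max_transform_diff(tr0$body[[2]], rt_identity()), 1e-9)
})

test_that("respiration-only motion is suppressed to within the filter gain", {
  amp <- c(lr = 0, ap = 2, si = 0.5)
  cfg <- scene_config(seed = 9, duration_s = 300, pixel_noise_px = 0,
                      dropout = 0, respiration = list(amp = amp, period_s = 4),
                      thigh_amp_mm = 0,
                      drift = list(amp = c(lr = 0, ap = 0, si = 0, pitch = 0,
                                           roll = 0, yaw = 0)),
                      mask_drift = list(amp = c(lr = 0, ap = 0, si = 0,
                                                pitch = 0, roll = 0, yaw = 0)))
  sim <- simulate_intrafraction(cfg)
  tr <- track_sequence(sim$clouds, "abdominal", smooth = TRUE)
  ser <- displacement_series(tr, sim$origin, objects = "body")
  # residual translational amplitude bounded by the moving-average gain
  # (edges see a shorter window: use the interior frames, gain of window 3
  # bounds the worst interior truncation)
  core <- dplyr::filter(ser, .data$frame >= 2,
                        .data$frame <= max(.data$frame) - 2)
  bound <- ma_gain(0.25, 5) * max(abs(amp)) * 1.05
  expect_lt(max(abs(core$ap)), bound)
  expect_lt(max(abs(core$si)), bound)
})
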