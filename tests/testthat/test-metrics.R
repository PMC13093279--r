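test_that("displacement series reproduces tracked and relative motion", {
  cfg <- quiet_cfg(duration_s = 100, seed = 12)
  sim <- simulate_intrafraction(cfg)
  tr <- track_sequence(sim$clouds, "abdominal", smooth = FALSE)
  ser <- displacement_series(tr, sim$origin)
  truth <- sim$truth$displacement
  for (obj in c("body", "mask")) {
    got <- dplyr::filter(ser, .data$object == obj)
    want <- dplyr::filter(truth, .data$object == obj)
    m <- dplyr::inner_join(got, want, by = "frame")
    for (ax in c("lr", "ap", "si", "pitch", "roll", "yaw")) {
      expect_lt(max(abs(m[[paste0(ax, ".x")]] - m[[paste0(ax, ".y")]])), 1e-6)
    }
  }
  # frame 0 is all zeros; the drift curve itself is reproduced
  f0 <- dplyr::filter(ser, .data$frame == 0, .data$object == "body")
  expect_equal(unlist(f0[, c("lr", "ap", "si", "pitch", "roll", "yaw")]),
               c(lr = 0, ap = 0, si = 0, pitch = 0, roll = 0, yaw = 0))
  body <- dplyr::filter(ser, .data$object == "body")
  curve <- cfg$drift$amp[["ap"]] * (1 - exp(-body$time_s / cfg$drift$tau_s))
  expect_lt(max(abs(body$ap - curve)), 1e-6)

  # equal body and mask transforms give an all-zero relative series
  trk <- tr
  trk$mask <- trk$body
  rel <- displacement_series(trk, sim$origin, objects = "relative")
  expect_lt(max(abs(as.matrix(rel[, c("lr", "ap", "si", "pitch", "roll",
                                      "yaw")]))), 1e-12)
})

test_that("euclidean_3d is the translational L2 norm", {
  expect_equal(euclidean_3d(c(lr = 3, ap = 4, si = 0)), 5)
  expect_equal(euclidean_3d(c(lr = 0, ap = 0, si = 0)), 0)
  expect_equal(euclidean_3d(c(lr = 1, ap = 1, si = 1)), sqrt(3))
  df <- tibble::tibble(lr = c(3, 1), ap = c(4, 1), si = c(0, 1))
  expect_equal(euclidean_3d(df), c(5, sqrt(3)))
})

test_that("setup-error summary matches the worked definitions", {
  # subject 1 LR errors (1,2,3); subject 2 LR errors (0,0,0):
  # mu = 1.0, Sigma = sd(c(2,0)) = sqrt(2), sigma = mean(c(1,0)) = 0.5
  errs <- tibble::tibble(
    subject = rep(1:2, each = 3), rep = rep(1:3, 2),
    lr = c(1, 2, 3, 0, 0, 0), ap = 0, si = 0,
    pitch = 0, roll = 0, yaw = 0)
  s <- interfraction_summary(errs)
  lr <- dplyr::filter(s$by_axis, .data$axis == "lr")
  expect_equal(lr$mu, 1)
  expect_equal(lr$sigma_systematic, sqrt(2))
  expect_equal(lr$sigma_random, 0.5)

  zeros <- dplyr::mutate(errs, lr = 0)
  s0 <- interfraction_summary(zeros)
  expect_true(all(abs(s0$by_axis$mu) < 1e-12))
  expect_true(all(s0$by_axis$sigma_systematic < 1e-12))
  expect_true(all(s0$by_axis$sigma_random < 1e-12))
})

test_that("summary equals a brute-force two-pass recomputation", {
  set.seed(161)
  for (trial in 1:100) {
    ns <- sample(3:8, 1); nr <- sample(2:6, 1)
    errs <- tibble::tibble(
      subject = rep(seq_len(ns), each = nr),
      rep = rep(seq_len(nr), ns),
      lr = stats::rnorm(ns * nr, 0, 2), ap = stats::rnorm(ns * nr, 1, 1),
      si = stats::rnorm(ns * nr), pitch = stats::rnorm(ns * nr, 0, 0.5),
      roll = stats::rnorm(ns * nr, 0, 0.5), yaw = stats::rnorm(ns * nr, 0, 0.5))
    s <- interfraction_summary(errs)
    # oracle: plain two-pass loops
    for (ax in c("lr", "pitch")) {
      means <- sds <- numeric(ns)
      for (subj in seq_len(ns)) {
        v <- errs[[ax]][errs$subject == subj]
        means[subj] <- sum(v) / length(v)
        sds[subj] <- sqrt(sum((v - means[subj])^2) / (length(v) - 1))
      }
      row <- dplyr::filter(s$by_axis, .data$axis == ax)
      expect_equal(row$mu, mean(means), tolerance = 1e-12)
      expect_equal(row$sigma_systematic,
                   sqrt(sum((means - mean(means))^2) / (ns - 1)),
                   tolerance = 1e-12)
      expect_equal(row$sigma_random, mean(sds), tolerance = 1e-12)
    }
    # 3D statistics built on per-repetition norms
    e3 <- sqrt(errs$lr^2 + errs$ap^2 + errs$si^2)
    expect_equal(unname(s$overall_3d["mean"]), mean(e3), tolerance = 1e-12)
  }
})

test_that("single-repetition subjects leave sigma undefined", {
  errs <- tibble::tibble(subject = 1:3, rep = 1, lr = c(1, 2, 3), ap = 0,
                         si = 0, pitch = 0, roll = 0, yaw = 0)
  expect_message(s <- interfraction_summary(errs), "single repetition")
  expect_true(all(is.na(s$by_axis$sigma_random)))
  expect_false(anyNA(s$by_axis$sigma_systematic))
})

make_series <- function(values_by_axis, n = 241, cadence = 5) {
  out <- tibble::tibble(object = "body", frame = 0:(n - 1),
                        time_s = (0:(n - 1)) * cadence,
                        lr = 0, ap = 0, si = 0, pitch = 0, roll = 0, yaw = 0,
                        registered = TRUE)
  for (ax in names(values_by_axis)) out[[ax]] <- values_by_axis[[ax]]
  class(out) <- c("displacement_series", class(out))
  out
}

test_that("BDT equals hand-counted values on constructed trajectories", {
  tol <- default_tolerance("abdominal")
  # always within tolerance: the full 20 min
  b <- bdt(make_series(list()), tol)
  expect_equal(b$total_min, 20)
  expect_true(all(b$per_axis_min == 20))

  # within for exactly the first half then permanently outside: 10 min
  # under both conventions (frames 0..120 in, 121..240 out)
  half <- make_series(list(ap = c(rep(0, 121), rep(5, 120))))
  expect_equal(bdt(half, tol)$total_min, 10)
  expect_equal(bdt(half, tol, convention = "until_first_violation")$total_min,
               10)

  # violating only yaw: total equals the yaw per-axis time, others 20 min
  yawbad <- make_series(list(yaw = c(rep(0, 200), rep(2, 41))))
  b <- bdt(yawbad, tol)
  expect_equal(b$total_min, unname(b$per_axis_min["yaw"]))
  expect_equal(unname(b$per_axis_min[c("lr", "ap", "si", "pitch", "roll")]),
               rep(20, 5))
  # hand count: 200 within-tolerance frames after the reference -> 199
  # intervals of 5 s
  expect_equal(b$total_min, 199 * 5 / 60)
})

test_that("BDT respects its bound and threshold monotonicity", {
  set.seed(171)
  for (i in 1:20) {
    drift <- cumsum(stats::rnorm(241, 0, 0.3))
    ser <- make_series(list(ap = drift, si = cumsum(stats::rnorm(241, 0, 0.2)),
                            yaw = cumsum(stats::rnorm(241, 0, 0.05))))
    prev <- -1
    for (thr in c(0.5, 1, 2, 4, 8)) {
      b <- bdt(ser, tolerance_spec(thr, thr / 2))
      expect_lte(b$total_min, min(b$per_axis_min))
      expect_gte(b$total_min, prev)
      prev <- b$total_min
    }
  }
})

test_that("degenerate BDT inputs are rejected", {
  tol <- default_tolerance("hn")
  expect_error(bdt(make_series(list())[0, ], tol), "empty")
  two <- dplyr::bind_rows(make_series(list()),
                          dplyr::mutate(make_series(list()), object = "mask"))
  expect_error(bdt(two, tol), "single-object")
})
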