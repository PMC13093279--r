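#' Scene and motion simulator configuration
#'
#' One config object fixes the whole stated world of a simulated session:
#' the three-camera rig, the marker layout, the motion model and the
#' observation noise. All randomness flows from `seed` through per-stage
#' substreams so stages can be re-run independently and reproducibly.
#'
#' Motion defaults emulate the phenomenology of upright immobilization
#' sessions: a saturating drift `A * (1 - exp(-t / tau))` largest over the
#' first ~5 min, directed anterior (+AP) and inferior (-SI); quasi-periodic
#' respiratory displacement of the abdominal skin markers (period ~4 s,
#' deliberately aliased by the 5-s acquisition cadence); small independent
#' mask-relative-to-body drift; near-static thigh markers; 4% marker
#' dropout; 0.5 px detection noise. Inter-fractional systematic/random
#' spreads default to the masked abdominal setup of the source platform
#' (per-axis values of a few mm / well under 1 deg).
#'
#' @param setup `"abdominal"` or `"hn"` marker layout.
#' @param seed Integer master seed.
#' @param duration_s,cadence_s Session length and frame interval (s).
#' @param pixel_noise_px Gaussian detection noise SD (px).
#' @param dropout Per marker-frame dropout probability (non-reference
#'   frames).
#' @param camera_distance_mm,camera_azimuth_deg Rig geometry: camera
#'   distance from the chair rotation axis and lateral camera azimuth.
#' @param focal_mm,pixel_pitch_mm Lens focal length and sensor pixel pitch
#'   defining the default intrinsics for the 5496 x 3672 px sensor.
#' @param axis_lr,axis_ap Chair rotation-axis LR/AP position (mm); the
#'   axis is 150 mm anterior to the backrest plane at y = 0.
#' @param drift,mask_drift Lists with `amp` (named lr/ap/si mm,
#'   pitch/roll/yaw deg) and `tau_s` for the saturating drifts of the body
#'   and of the mask relative to the body.
#' @param respiration List with `amp` (named lr/ap/si mm), `period_s`,
#'   `phase`.
#' @param thigh_amp_mm Amplitude of the independent thigh-marker drift.
#' @param interfraction List with `sigma_sys` and `sigma_rand`: per-axis
#'   systematic (per-subject) and random (per-repetition) SDs, named
#'   lr/ap/si (mm) and pitch/roll/yaw (deg).
#' @return A `scene_config` list.
#' @export
scene_config <- function(setup = c("abdominal", "hn"), seed = 1,
                         duration_s = 1200, cadence_s = 5,
                         pixel_noise_px = 0.5, dropout = 0.04,
                         camera_distance_mm = 2000, camera_azimuth_deg = 55,
                         focal_mm = 25, pixel_pitch_mm = 0.0024,
                         axis_lr = 0, axis_ap = 150,
                         drift = NULL, mask_drift = NULL,
                         respiration = NULL, thigh_amp_mm = 0.3,
                         interfraction = NULL) {
  setup <- match.arg(setup)
  stopifnot(dropout >= 0, dropout <= 1, pixel_noise_px >= 0)
  axes <- c("lr", "ap", "si", "pitch", "roll", "yaw")
  amp6 <- function(x, default) {
    if (is.null(x)) return(default)
    out <- default
    if (is.null(names(x))) {
      stopifnot(length(x) == length(default))
      out[] <- x
    } else {
      stopifnot(all(names(x) %in% names(default)))
      out[names(x)] <- x
    }
    out
  }
  drift_default <- stats::setNames(c(0.3, 1.5, -2.0, 0.3, 0.1, 0.2), axes)
  maskd_default <- stats::setNames(c(0.1, 0.4, -0.3, 0.1, 0.05, 0.05), axes)
  sys_default <- stats::setNames(c(1.4, 1.7, 2.2, 0.8, 0.8, 0.5), axes)
  rand_default <- stats::setNames(c(1.3, 1.6, 1.4, 0.4, 0.5, 0.5), axes)
  structure(list(
    setup = setup, seed = as.integer(seed),
    duration_s = duration_s, cadence_s = cadence_s,
    pixel_noise_px = pixel_noise_px, dropout = dropout,
    camera_distance_mm = camera_distance_mm,
    camera_azimuth_deg = camera_azimuth_deg,
    focal_mm = focal_mm, pixel_pitch_mm = pixel_pitch_mm,
    axis_lr = axis_lr, axis_ap = axis_ap,
    drift = list(amp = amp6(drift$amp, drift_default),
                 tau_s = drift$tau_s %||% 150),
    mask_drift = list(amp = amp6(mask_drift$amp, maskd_default),
                      tau_s = mask_drift$tau_s %||% 300),
    respiration = list(
      amp = amp6(respiration$amp,
                 stats::setNames(c(0, 2, 0.5), axes[1:3])),
      period_s = respiration$period_s %||% 4,
      phase = respiration$phase %||% 0),
    thigh_amp_mm = thigh_amp_mm,
    interfraction = list(
      sigma_sys = amp6(interfraction$sigma_sys, sys_default),
      sigma_rand = amp6(interfraction$sigma_rand, rand_default))),
    class = "scene_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Counter-based substream seeding: one master seed, independent stage
# streams. Kept below 2^31.
substream_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 16807) %% 2147483647
}

#' Build the three-camera rig of a scene
#'
#' Front, left and right cameras at `camera_distance_mm` from the chair
#' rotation axis, at azimuths 0 and +/- `camera_azimuth_deg`, all aimed at
#' the centroid of the marker layout. Intrinsics follow the configured lens
#' and pixel pitch; distortion defaults to zero.
#'
#' @param cfg A `scene_config`.
#' @return Named list of cameras (`front`, `left`, `right`), each a list
#'   with `intr` and `pose`.
#' @export
make_rig <- function(cfg) {
  layout <- make_layout(cfg$setup, cfg)
  # aim at the mid-range of the marker extents so the vertical span
  # (thigh to abdomen in the abdominal setup) is framed symmetrically
  target <- c(mean(range(layout$x)), mean(range(layout$y)),
              mean(range(layout$z)))
  f_px <- cfg$focal_mm / cfg$pixel_pitch_mm
  intr <- camera_intrinsics(fx = f_px)
  az <- cfg$camera_azimuth_deg * pi / 180
  axis <- c(cfg$axis_lr, cfg$axis_ap)
  centers <- list(
    front = c(axis[1], axis[2] + cfg$camera_distance_mm, target[3]),
    left  = c(axis[1] + cfg$camera_distance_mm * sin(az),
              axis[2] + cfg$camera_distance_mm * cos(az), target[3]),
    right = c(axis[1] - cfg$camera_distance_mm * sin(az),
              axis[2] + cfg$camera_distance_mm * cos(az), target[3]))
  if (max(abs(centers$left - centers$right)) < 1e-9) {
    stop("coincident camera centers", call. = FALSE)
  }
  purrr::imap(centers, function(ctr, id) {
    list(intr = intr, pose = look_at_pose(ctr, target, id = id))
  })
}

#' Reference marker layout for a setup
#'
#' Invented but geometrically plausible coordinates for the 26 labeled
#' markers of each setup (the clinical layouts are not published). The
#' abdominal layout places nine respiratory skin markers A1-A9 on an
#' elliptic-cylinder torso, two thigh markers A10-A11, and 15 mask markers
#' on an anterior thermoplastic shell; the head-and-neck layout places ten
#' rigid head markers H1-H10 visible through mask openings and 16 mask
#' markers on a head-shaped shell. Markers are tagged with their lateral
#' side for camera-pair selection and are spaced at least 20 mm apart
#' (nearest-neighbour ICP safety margin).
#'
#' @param setup `"abdominal"` or `"hn"`.
#' @param cfg Optional `scene_config` (unused by the default geometry but
#'   kept for signature stability).
#' @return A labeled-cloud tibble: `marker`, `x`, `y`, `z` (mm), `role`
#'   (`mask`, `body_rigid`, `body_respiratory`, `thigh`), `side` (`left`,
#'   `right`, `central`), `valid`.
#' @export
make_layout <- function(setup = c("abdominal", "hn"), cfg = NULL) {
  setup <- match.arg(setup)
  ellipse_y <- function(x, a, b, y0) y0 + b * sqrt(pmax(0, 1 - (x / a)^2))
  if (setup == "abdominal") {
    # torso: elliptic cylinder, semi-axes 150 (LR) x 110 (AP), back at y=0
    gx <- c(-80, 0, 80)
    gz <- c(1000, 1070, 1140)
    body <- expand.grid(x = gx, z = gz)
    body$y <- ellipse_y(body$x, 150, 110, 110)
    # A1..A9 column-major: A2 is the central-column mid marker (anchor)
    body$marker <- paste0("A", seq_len(9))
    body$role <- "body_respiratory"
    thigh <- data.frame(marker = c("A10", "A11"),
                        x = c(-100, 100), y = 280, z = 600,
                        role = "thigh")
    mx <- c(-100, -50, 0, 50, 100)
    mz <- c(950, 1050, 1150)
    mask <- expand.grid(x = mx, z = mz)
    # shell standoff > 20 mm from the skin markers (ICP safety margin)
    mask$y <- ellipse_y(mask$x, 170, 135, 110)
    mask$marker <- paste0("M", seq_len(15))
    mask$role <- "mask"
    out <- rbind(body[, c("marker", "x", "y", "z", "role")],
                 thigh[, c("marker", "x", "y", "z", "role")],
                 mask[, c("marker", "x", "y", "z", "role")])
  } else {
    # head: sphere-ish shell centred on the rotation axis at eye height
    hc <- c(0, 150, 1530)
    hx <- c(-60, -30, 0, 30, 60)
    hz <- hc[3] + c(-40, 0, 40)
    head <- expand.grid(x = hx, z = hz)[seq_len(10), ]
    head$y <- ellipse_y(head$x, 95, 95, hc[2] - 10)
    head$marker <- paste0("H", seq_len(10))
    head$role <- "body_rigid"
    mx <- c(-90, -45, 0, 45, 90)
    mz <- hc[3] + c(-90, -35, 35, 90)
    mask <- expand.grid(x = mx, z = mz)[seq_len(16), ]
    mask$y <- ellipse_y(mask$x, 125, 122, hc[2] - 10)
    mask$marker <- paste0("M", seq_len(16))
    mask$role <- "mask"
    out <- rbind(head[, c("marker", "x", "y", "z", "role")],
                 mask[, c("marker", "x", "y", "z", "role")])
  }
  out$side <- ifelse(out$x > 20, "left", ifelse(out$x < -20, "right",
                                                "central"))
  tibble::tibble(marker = out$marker, x = out$x, y = out$y, z = out$z,
                 role = out$role, side = out$side, valid = TRUE)
}

# 6-axis displacement (lr, ap, si, pitch, roll, yaw) of the saturating
# drift model at time t.
drift_displacement <- function(t, amp, tau) amp * (1 - exp(-t / tau))

#' Simulate an intra-fractional tracking session
#'
#' Generates the full 20-minute session: ground-truth body and mask
#' transforms from the saturating-drift motion model, additive respiratory
#' displacement on the abdominal skin markers, independent thigh-marker
#' drift, per marker-frame dropout, projection into the three cameras and
#' sub-pixel detection noise. Ground truth is emitted alongside every
#' observation so downstream recovery tests never recompute it.
#'
#' @param cfg A `scene_config`.
#' @return A list: `config`, `cameras`, `layout`, `origin` (reporting
#'   origin on the rotation axis), `truth` (list with `displacement` tibble
#'   of per-frame true body/mask 6-DoF displacements about `origin`, and
#'   `body`, `mask` transform lists), `clouds` (true 3D marker positions
#'   per frame, dropout applied to `valid`), `detections` (per camera x
#'   frame x marker pixel observations), `boxes` (per-camera static patch
#'   boxes from the reference projections).
#' @export
simulate_intrafraction <- function(cfg) {
  cameras <- make_rig(cfg)
  layout <- make_layout(cfg$setup, cfg)
  anchor <- if (cfg$setup == "abdominal") "A2" else "H1"
  origin <- c(cfg$axis_lr, cfg$axis_ap, layout$z[layout$marker == anchor])
  times <- seq(0, cfg$duration_s, by = cfg$cadence_s)
  n <- length(times)
  axes <- c("lr", "ap", "si", "pitch", "roll", "yaw")

  # thigh drift directions: one fixed random unit vector per thigh marker
  set.seed(substream_seed(cfg$seed, 1))
  thigh_markers <- layout$marker[layout$role == "thigh"]
  thigh_dir <- stats::setNames(
    lapply(thigh_markers, function(m) {
      v <- stats::rnorm(3); v / sqrt(sum(v^2))
    }), thigh_markers)

  body_tr <- mask_tr <- vector("list", n)
  disp_rows <- vector("list", n)
  cloud_rows <- vector("list", n)
  P <- as.matrix(layout[, c("x", "y", "z")])
  resp_idx <- layout$role == "body_respiratory"
  mask_idx <- layout$role == "mask"
  thigh_idx <- layout$role == "thigh"
  for (k in seq_len(n)) {
    t <- times[k]
    db <- drift_displacement(t, cfg$drift$amp, cfg$drift$tau_s)
    dm <- drift_displacement(t, cfg$mask_drift$amp, cfg$mask_drift$tau_s)
    Tb <- from_displacement(stats::setNames(db, axes), origin)
    Trel <- from_displacement(stats::setNames(dm, axes), origin)
    Tm <- rt_compose(Trel, Tb)
    body_tr[[k]] <- Tb
    mask_tr[[k]] <- Tm
    pts <- P
    pts[resp_idx | thigh_idx, ] <- rt_apply(Tb, P[resp_idx | thigh_idx, ,
                                                  drop = FALSE])
    pts[mask_idx, ] <- rt_apply(Tm, P[mask_idx, , drop = FALSE])
    if (any(cfg$respiration$amp != 0)) {
      r <- cfg$respiration$amp *
        sin(2 * pi * t / cfg$respiration$period_s + cfg$respiration$phase)
      pts[resp_idx, ] <- sweep(pts[resp_idx, , drop = FALSE], 2, r, "+")
    }
    if (cfg$thigh_amp_mm != 0) {
      sat <- 1 - exp(-t / cfg$drift$tau_s)
      for (m in thigh_markers) {
        i <- which(layout$marker == m)
        pts[i, ] <- pts[i, ] + cfg$thigh_amp_mm * sat * thigh_dir[[m]]
      }
    }
    dbm <- to_displacement(Tb, origin)
    dmm <- to_displacement(Tm, origin)
    disp_rows[[k]] <- tibble::tibble(
      object = rep(c("body", "mask"), each = 6),
      frame = k - 1L, time_s = t,
      axis = rep(axes, 2), value = unname(c(dbm, dmm)))
    cloud_rows[[k]] <- tibble::tibble(
      frame = k - 1L, time_s = t, marker = layout$marker,
      x = pts[, 1], y = pts[, 2], z = pts[, 3],
      role = layout$role, side = layout$side, valid = TRUE)
  }
  clouds <- dplyr::bind_rows(cloud_rows)

  # dropout: per marker-frame (all cameras lose the marker), reference kept
  set.seed(substream_seed(cfg$seed, 2))
  if (cfg$dropout > 0) {
    key <- clouds$frame > 0
    drop <- stats::runif(sum(key)) < cfg$dropout
    clouds$valid[key][drop] <- FALSE
  }

  detections <- project_clouds(clouds, cameras, cfg, noise_stream = 3)
  boxes <- reference_boxes(clouds[clouds$frame == 0, ], cameras,
                           halfwidth = 40)
  disp <- dplyr::bind_rows(disp_rows) |>
    tidyr::pivot_wider(names_from = "axis", values_from = "value")
  list(config = cfg, cameras = cameras, layout = layout, origin = origin,
       truth = list(displacement = disp, body = body_tr, mask = mask_tr),
       clouds = clouds, detections = detections, boxes = boxes)
}

# Project true clouds into every camera, adding pixel noise; dropout is
# inherited from the cloud validity flags.
project_clouds <- function(clouds, cameras, cfg, noise_stream = 3) {
  set.seed(substream_seed(cfg$seed, noise_stream))
  P <- as.matrix(clouds[, c("x", "y", "z")])
  purrr::imap_dfr(cameras, function(cam, id) {
    uv <- project(cam$intr, cam$pose, P)
    if (cfg$pixel_noise_px > 0) {
      uv <- uv + matrix(stats::rnorm(length(uv), 0, cfg$pixel_noise_px),
                        ncol = 2)
    }
    tibble::tibble(frame = clouds$frame, time_s = clouds$time_s,
                   camera = id, marker = clouds$marker,
                   u = uv[, 1], v = uv[, 2], valid = clouds$valid)
  })
}

# Static per-camera patch boxes centred on the reference-frame projections.
reference_boxes <- function(ref_cloud, cameras, halfwidth = 40) {
  P <- as.matrix(ref_cloud[, c("x", "y", "z")])
  purrr::imap_dfr(cameras, function(cam, id) {
    uv <- project(cam$intr, cam$pose, P)
    tibble::tibble(camera = id, marker = ref_cloud$marker,
                   u0 = round(uv[, 1]) - halfwidth,
                   v0 = round(uv[, 2]) - halfwidth,
                   width = 2 * halfwidth, height = 2 * halfwidth)
  })
}

#' Render the marker patches of one simulated frame
#'
#' Draws each visible marker of one frame and camera as an anti-aliased
#' dark disc in its static patch, for exercising the image-based detection
#' stage. Markers invalid in the frame render as background-only patches.
#'
#' @param sim Result of [simulate_intrafraction()].
#' @param frame Frame index.
#' @param camera Camera id.
#' @param marker_diameter_mm Physical marker diameter (mm).
#' @return Named list of 8-bit patch matrices (names = marker labels).
#' @export
render_frame_patches <- function(sim, frame, camera,
                                 marker_diameter_mm = 5) {
  cam <- sim$cameras[[camera]]
  cl <- sim$clouds[sim$clouds$frame == frame, ]
  boxes <- sim$boxes[sim$boxes$camera == camera, ]
  det <- sim$detections[sim$detections$frame == frame &
                          sim$detections$camera == camera, ]
  out <- list()
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    row <- cl[cl$marker == b$marker, ]
    d <- det[det$marker == b$marker, ]
    if (!row$valid) {
      out[[b$marker]] <- matrix(200L, b$height, b$width)
      next
    }
    # radius in px from the camera range of the true point
    depth <- rt_apply(cam$pose$pose, c(row$x, row$y, row$z))[3]
    radius_px <- (marker_diameter_mm / 2) * cam$intr$fx / depth
    out[[b$marker]] <- render_marker_patch(c(d$u, d$v), b, radius_px)
  }
  out
}

#' Simulate inter-fractional setup repetitions
#'
#' Per subject, one systematic 6-axis offset is drawn from
#' `Normal(0, sigma_sys)`; each repetition adds an independent random
#' offset from `Normal(0, sigma_rand)`. The true per-repetition setup
#' errors are always emitted; marker clouds (and optionally camera
#' detections) are emitted on request for end-to-end runs.
#'
#' @param cfg A `scene_config`.
#' @param n_subjects Number of subjects.
#' @param n_reps Repetitions per subject (default 5; a single repetition
#'   leaves the random component undefined downstream).
#' @param emit `"offsets"` (truth table only), `"clouds"` or
#'   `"detections"`.
#' @return A list: `truth` (tibble `subject`, `rep`, lr/ap/si/pitch/roll/
#'   yaw true setup errors about the reporting origin), `origin`, and when
#'   requested `clouds` / `detections` stacked with columns `subject`,
#'   `frame` (0 = reference, 1..n_reps = repetitions).
#' @export
simulate_interfraction <- function(cfg, n_subjects, n_reps = 5,
                                   emit = c("offsets", "clouds",
                                            "detections")) {
  emit <- match.arg(emit)
  stopifnot(n_subjects >= 1, n_reps >= 1)
  layout <- make_layout(cfg$setup, cfg)
  anchor <- if (cfg$setup == "abdominal") "A2" else "H1"
  origin <- c(cfg$axis_lr, cfg$axis_ap, layout$z[layout$marker == anchor])
  axes <- c("lr", "ap", "si", "pitch", "roll", "yaw")
  set.seed(substream_seed(cfg$seed, 4))
  rows <- list()
  clouds <- list()
  for (s in seq_len(n_subjects)) {
    sys <- stats::rnorm(6, 0, cfg$interfraction$sigma_sys)
    for (r in seq_len(n_reps)) {
      d <- sys + stats::rnorm(6, 0, cfg$interfraction$sigma_rand)
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject = s, rep = r,
        lr = d[1], ap = d[2], si = d[3],
        pitch = d[4], roll = d[5], yaw = d[6])
      if (emit != "offsets") {
        tr <- from_displacement(stats::setNames(d, axes), origin)
        pts <- rt_apply(tr, as.matrix(layout[, c("x", "y", "z")]))
        clouds[[length(clouds) + 1]] <- tibble::tibble(
          subject = s, frame = r, time_s = r * cfg$cadence_s,
          marker = layout$marker, x = pts[, 1], y = pts[, 2], z = pts[, 3],
          role = layout$role, side = layout$side, valid = TRUE)
      }
    }
    if (emit != "offsets") {
      clouds[[length(clouds) + 1]] <- tibble::tibble(
        subject = s, frame = 0L, time_s = 0,
        marker = layout$marker, x = layout$x, y = layout$y, z = layout$z,
        role = layout$role, side = layout$side, valid = TRUE)
    }
  }
  out <- list(truth = dplyr::bind_rows(rows), origin = origin,
              layout = layout, config = cfg)
  if (emit != "offsets") {
    out$clouds <- dplyr::bind_rows(clouds) |>
      dplyr::arrange(.data$subject, .data$frame, .data$marker)
  }
  if (emit == "detections") {
    cameras <- make_rig(cfg)
    out$cameras <- cameras
    out$detections <- out$clouds |>
      dplyr::group_by(.data$subject) |>
      dplyr::group_modify(function(g, key) {
        project_clouds(g, cameras, cfg,
                       noise_stream = 100 + key$subject)
      }) |>
      dplyr::ungroup()
  }
  out
}

#' Grid-plate calibration and verification fixture
#'
#' Places the 41 x 58 grid plate at `n_poses` calibration poses plus one
#' held-out verification pose (distinct tilts and offsets around the scene
#' target), and emits noiseless or noisy per-camera detections of every
#' grid point together with the ground-truth camera poses.
#'
#' @param cfg A `scene_config`.
#' @param n_poses Number of calibration poses.
#' @param noise_px Gaussian pixel noise SD added to the detections.
#' @return A list: `cameras` (truth), `poses` (list of plate
#'   `rigid_transform`s, the last one held out), `calibration` (tibble
#'   `pose_id`, `camera`, `row`, `col`, `x`, `y`, `z`, `u`, `v`, `valid`),
#'   `verification` (same shape, the held-out pose), `plate`
#'   (held-out-pose grid truth).
#' @export
grid_fixture <- function(cfg, n_poses = 6, noise_px = 0) {
  cameras <- make_rig(cfg)
  layout <- make_layout(cfg$setup, cfg)
  target <- c(mean(range(layout$x)), mean(range(layout$y)),
              mean(range(layout$z)))
  # base orientation: plate x -> LR, plate y -> SI, normal -> anterior
  R0 <- matrix(c(1, 0, 0,
                 0, 0, -1,
                 0, 1, 0), 3, 3, byrow = TRUE)
  tilts <- data.frame(
    yaw = c(0, 12, -12, 8, -8, 15, 5),
    pitch = c(0, 8, -8, -12, 12, 5, -10),
    dx = c(0, 60, -60, 30, -30, 80, -45),
    dy = c(0, 40, -40, -60, 60, 20, 50),
    dz = c(0, 50, -50, 70, -70, -40, 30))
  stopifnot(n_poses + 1 <= nrow(tilts))
  poses <- lapply(seq_len(n_poses + 1), function(i) {
    R <- rotation_from_angles(pitch = tilts$pitch[i], yaw = tilts$yaw[i]) %*% R0
    center <- target + c(tilts$dx[i], tilts$dy[i], tilts$dz[i])
    rigid_transform(R, center)
  })
  set.seed(substream_seed(cfg$seed, 5))
  detect_pose <- function(pose, pose_id) {
    g <- grid_plate(pose)
    P <- as.matrix(g[, c("x", "y", "z")])
    purrr::imap_dfr(cameras, function(cam, id) {
      uv <- project(cam$intr, cam$pose, P)
      if (noise_px > 0) {
        uv <- uv + matrix(stats::rnorm(length(uv), 0, noise_px), ncol = 2)
      }
      tibble::tibble(pose_id = pose_id, camera = id,
                     row = g$row, col = g$col,
                     x = g$x, y = g$y, z = g$z,
                     u = uv[, 1], v = uv[, 2], valid = TRUE)
    })
  }
  calib <- purrr::map_dfr(seq_len(n_poses),
                          function(i) detect_pose(poses[[i]], i))
  verif <- detect_pose(poses[[n_poses + 1]], n_poses + 1)
  list(cameras = cameras, poses = poses, calibration = calib,
       verification = verif, plate = grid_plate(poses[[n_poses + 1]]))
}
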