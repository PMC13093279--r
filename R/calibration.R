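#' Calibration grid plate
#'
#' A planar 41 x 58 grid of points at 5.0 mm spacing (2378 points), placed
#' in the world by a rigid plate pose. Grid local coordinates are centred on
#' the plate with x along columns, y along rows and z = 0.
#'
#' @param pose A `rigid_transform` placing plate coordinates in the world.
#' @param rows,cols Grid dimensions.
#' @param spacing Grid spacing in mm.
#' @return A tibble with columns `row`, `col`, `x`, `y`, `z` (world mm).
#' @export
grid_plate <- function(pose = rt_identity(), rows = 41, cols = 58,
                       spacing = 5.0) {
  g <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  local <- cbind((g$col - (cols + 1) / 2) * spacing,
                 (g$row - (rows + 1) / 2) * spacing,
                 0)
  world <- rt_apply(pose, local)
  tibble::tibble(row = g$row, col = g$col,
                 x = world[, 1], y = world[, 2], z = world[, 3])
}

# Rodrigues rotation-vector <-> matrix conversions used to parameterise the
# pose search space with exactly 3 rotational degrees of freedom.
rotvec_to_matrix <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3) + skew3(w))
  k <- w / th
  K <- skew3(k)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

matrix_to_rotvec <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- max(-1, min(1, ct))
  th <- acos(ct)
  if (th < 1e-12) {
    return(c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2)
  }
  if (abs(pi - th) < 1e-6) {
    # near 180 deg: extract axis from R + I
    B <- (R + diag(3)) / 2
    k <- sqrt(pmax(diag(B), 0))
    k[2] <- k[2] * sign(B[1, 2] + 1e-300)
    k[3] <- k[3] * sign(B[1, 3] + 1e-300)
    return(th * k / sqrt(sum(k^2)))
  }
  th / (2 * sin(th)) *
    c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
}

skew3 <- function(w) {
  matrix(c(0, -w[3], w[2],
           w[3], 0, -w[1],
           -w[2], w[1], 0), 3, 3, byrow = TRUE)
}

#' Calibrate camera extrinsics from grid observations
#'
#' Nonlinear least squares over the 6 pose parameters (Rodrigues rotation
#' vector + translation), minimising the summed squared pixel distance
#' between detected grid-point positions and the projections of their known
#' 3D world positions. Levenberg-Marquardt with a numerically differenced
#' Jacobian; intrinsics are fixed inputs.
#'
#' @param intr A `camera_intrinsics`.
#' @param observations Data frame with columns `x`, `y`, `z` (known world
#'   point, mm) and `u`, `v` (detected pixel). At least 6 non-collinear
#'   points are required.
#' @param init Initial `camera_pose`; must place all points in front of the
#'   camera.
#' @param max_iter,tol Levenberg-Marquardt iteration cap and relative
#'   cost-decrease convergence tolerance.
#' @return A list with `pose` (`camera_pose`), `rms_px` (RMS reprojection
#'   error at the optimum), `n_obs` and `converged`.
#' @export
calibrate_extrinsics <- function(intr, observations, init,
                                 max_iter = 100, tol = 1e-14) {
  obs <- as.data.frame(observations)
  need <- c("x", "y", "z", "u", "v")
  if (!all(need %in% names(obs))) {
    stop("observations must have columns x, y, z, u, v", call. = FALSE)
  }
  obs <- obs[stats::complete.cases(obs[, need]), need]
  if (nrow(obs) < 6) {
    stop("at least 6 observations are required for extrinsic calibration",
         call. = FALSE)
  }
  P <- as.matrix(obs[, c("x", "y", "z")])
  if (point_rank(P) < 2) {
    stop("degenerate observations: grid points are collinear", call. = FALSE)
  }
  target <- as.numeric(t(as.matrix(obs[, c("u", "v")])))

  resid <- function(par) {
    R <- rotvec_to_matrix(par[1:3])
    pose <- camera_pose(rigid_transform(R, par[4:6]), id = init$id)
    as.numeric(t(project(intr, pose, P))) - target
  }

  par <- c(matrix_to_rotvec(init$pose$R), init$pose$t)
  r <- resid(par)
  cost <- sum(r^2)
  lambda <- 1e-6
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    J <- numeric_jacobian(resid, par, r)
    JtJ <- crossprod(J)
    g <- crossprod(J, r)
    repeat {
      H <- JtJ + lambda * diag(diag(JtJ) + 1e-12)
      step <- tryCatch(as.numeric(solve(H, -g)), error = function(e) NULL)
      if (is.null(step)) {
        lambda <- lambda * 10
        if (lambda > 1e12) stop("extrinsic calibration failed to converge: singular normal equations", call. = FALSE)
        next
      }
      par_new <- par + step
      r_new <- tryCatch(resid(par_new), error = function(e) NULL)
      cost_new <- if (is.null(r_new)) Inf else sum(r_new^2)
      if (cost_new < cost) {
        lambda <- max(lambda / 10, 1e-12)
        break
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (!is.finite(cost_new) || cost_new >= cost) {
      converged <- TRUE  # no achievable decrease: at a (local) optimum
      break
    }
    dc <- cost - cost_new
    par <- par_new; r <- r_new; cost <- cost_new
    if (dc < tol * max(cost, 1e-300) || cost < 1e-24) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("extrinsic calibration stopped at iteration cap (cost %.3e)", cost),
            call. = FALSE)
  }
  pose <- camera_pose(rigid_transform(rotvec_to_matrix(par[1:3]), par[4:6]),
                      id = init$id)
  # per-coordinate RMS: with iid pixel noise of SD s this approaches s
  list(pose = pose, rms_px = sqrt(cost / length(r)), n_obs = nrow(obs),
       converged = converged)
}

point_rank <- function(P, tol = 1e-8) {
  Pc <- sweep(P, 2, colMeans(P))
  sv <- svd(Pc)$d
  sum(sv > tol * max(sv, 1e-300))
}

#' Verify 3D reconstruction accuracy on a held-out grid plate
#'
#' Triangulates detections of a grid plate placed at a pose not used for
#' calibration, for each camera pair, and reports per-axis absolute-error
#' and 3D-error statistics against the known grid positions.
#'
#' @param cameras Named list of cameras (each `list(intr, pose)`), with
#'   names `front`, `left`, `right`.
#' @param plate Tibble from [grid_plate()] at the held-out pose (truth).
#' @param detections Tibble with columns `camera`, `row`, `col`, `u`, `v`,
#'   `valid` of per-camera grid detections.
#' @param pairs List of camera-id pairs to evaluate.
#' @return A `grid_accuracy` tibble: one row per pair x axis (LR, AP, SI,
#'   `3D`) with `mean_abs_mm`, `sd_mm`, `p95_mm` and `n_points`. Percentiles
#'   use linear interpolation between order statistics (type 7).
#' @export
verify_grid <- function(cameras, plate, detections,
                        pairs = list(c("front", "left"), c("front", "right"),
                                     c("left", "right"))) {
  det <- dplyr::filter(detections, .data$valid)
  out <- purrr::map_dfr(pairs, function(pr) {
    a <- dplyr::inner_join(
      dplyr::filter(det, .data$camera == pr[1]),
      dplyr::filter(det, .data$camera == pr[2]),
      by = c("row", "col"), suffix = c("_a", "_b"))
    a <- dplyr::inner_join(a, plate, by = c("row", "col"))
    n_excluded <- nrow(plate) - nrow(a)
    if (n_excluded > 0) {
      message(sprintf("verify_grid: pair %s-%s: %d grid points excluded (missing/invalid detections)",
                      pr[1], pr[2], n_excluded))
    }
    uva <- as.matrix(a[, c("u_a", "v_a")])
    uvb <- as.matrix(a[, c("u_b", "v_b")])
    truth <- as.matrix(a[, c("x", "y", "z")])
    err <- t(vapply(seq_len(nrow(a)), function(i) {
      tri <- triangulate_pair(cameras[[pr[1]]], cameras[[pr[2]]],
                              uva[i, ], uvb[i, ])
      tri$point - truth[i, ]
    }, numeric(3)))
    abs_err <- abs(err)
    e3 <- sqrt(rowSums(err^2))
    axes <- list(LR = abs_err[, 1], AP = abs_err[, 2], SI = abs_err[, 3],
                 `3D` = e3)
    purrr::imap_dfr(axes, function(e, ax) {
      tibble::tibble(pair = paste(pr, collapse = "-"), axis = ax,
                     mean_abs_mm = mean(e), sd_mm = stats::sd(e),
                     p95_mm = stats::quantile(e, 0.95, names = FALSE, type = 7),
                     n_points = length(e))
    })
  })
  class(out) <- c("grid_accuracy", class(out))
  out
}
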