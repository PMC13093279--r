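#' Pinhole camera intrinsics
#'
#' Standard pinhole model with optional Brown-Conrady distortion. The
#' default image size matches the 5496 x 3672 px sensors of the tracking
#' rig; focal lengths are in pixels.
#'
#' @param fx,fy Focal lengths in pixels (> 0).
#' @param cx,cy Principal point in pixels; must lie inside the image.
#' @param skew Skew term in pixels (default 0).
#' @param k1,k2,k3 Radial distortion coefficients (dimensionless).
#' @param p1,p2 Tangential distortion coefficients (dimensionless).
#' @param width,height Image size in pixels.
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy = fx, cx = width / 2, cy = height / 2,
                              skew = 0, k1 = 0, k2 = 0, k3 = 0,
                              p1 = 0, p2 = 0,
                              width = 5496, height = 3672) {
  stopifnot(fx > 0, fy > 0)
  if (cx < 0 || cx > width || cy < 0 || cy > height) {
    stop("principal point must lie inside the image bounds", call. = FALSE)
  }
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy, skew = skew,
                 dist = c(k1 = k1, k2 = k2, k3 = k3, p1 = p1, p2 = p2),
                 width = width, height = height),
            class = "camera_intrinsics")
}

#' Camera pose (world -> camera rigid transform)
#'
#' Camera frame convention: z forward along the optical axis, x along image
#' u, y along image v. `pose` maps world coordinates (mm) into that frame.
#'
#' @param pose A `rigid_transform` mapping world to camera coordinates.
#' @param id Camera identifier, one of `"front"`, `"left"`, `"right"` (other
#'   labels are accepted for synthetic rigs).
#' @return An object of class `camera_pose`.
#' @export
camera_pose <- function(pose, id = "front") {
  stopifnot(inherits(pose, "rigid_transform"))
  structure(list(pose = pose, id = id), class = "camera_pose")
}

#' Build a camera pose looking at a target point
#'
#' @param center Camera center in world mm.
#' @param target World point the optical axis passes through.
#' @param up World up direction (default +SI).
#' @param id Camera identifier.
#' @return A `camera_pose`.
#' @export
look_at_pose <- function(center, target, up = c(0, 0, 1), id = "front") {
  f <- target - center
  f <- f / sqrt(sum(f^2))
  x <- cross3(up, f)
  nx <- sqrt(sum(x^2))
  if (nx < 1e-12) stop("camera up direction parallel to view axis", call. = FALSE)
  x <- x / nx
  y <- cross3(f, x)
  R <- rbind(x, y, f)          # rows: camera axes in world coords
  dimnames(R) <- NULL
  camera_pose(rigid_transform(R, as.numeric(-R %*% center)), id = id)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Apply Brown-Conrady distortion to normalized coordinates (n x 2).
distort_normalized <- function(xy, dist) {
  x <- xy[, 1]; y <- xy[, 2]
  r2 <- x^2 + y^2
  radial <- 1 + dist[["k1"]] * r2 + dist[["k2"]] * r2^2 + dist[["k3"]] * r2^3
  xd <- x * radial + 2 * dist[["p1"]] * x * y + dist[["p2"]] * (r2 + 2 * x^2)
  yd <- y * radial + dist[["p1"]] * (r2 + 2 * y^2) + 2 * dist[["p2"]] * x * y
  cbind(xd, yd)
}

# Invert the distortion by fixed-point iteration (exact for zero distortion).
undistort_normalized <- function(xy, dist, iters = 20) {
  if (all(dist == 0)) return(xy)
  und <- xy
  for (i in seq_len(iters)) {
    d <- distort_normalized(und, dist)
    und <- und + (xy - d)
  }
  und
}

#' Project world points into a camera image
#'
#' Applies the world-to-camera pose, perspective division, Brown-Conrady
#' distortion and the pixel mapping, returning sub-pixel coordinates.
#'
#' @param intr A `camera_intrinsics`.
#' @param pose A `camera_pose`.
#' @param p Length-3 vector or n x 3 matrix of world points (mm).
#' @return An n x 2 matrix (or length-2 vector) of pixel coordinates (u, v).
#'   Points at or behind the camera plane raise an error.
#' @export
project <- function(intr, pose, p) {
  vec <- !is.matrix(p)
  if (vec) p <- matrix(p, 1, 3)
  pc <- rt_apply(pose$pose, p)
  if (any(pc[, 3] <= 1e-9)) {
    stop("point at or behind the camera plane cannot be projected",
         call. = FALSE)
  }
  xy <- cbind(pc[, 1] / pc[, 3], pc[, 2] / pc[, 3])
  xy <- distort_normalized(xy, intr$dist)
  uv <- cbind(intr$fx * xy[, 1] + intr$skew * xy[, 2] + intr$cx,
              intr$fy * xy[, 2] + intr$cy)
  colnames(uv) <- c("u", "v")
  if (vec) uv[1, ] else uv
}

# Pixel -> undistorted normalized camera ray direction (world frame) + center.
pixel_ray <- function(intr, pose, uv) {
  y <- (uv[2] - intr$cy) / intr$fy
  x <- (uv[1] - intr$cx - intr$skew * y) / intr$fx
  nrm <- undistort_normalized(matrix(c(x, y), 1, 2), intr$dist)
  Rcw <- t(pose$pose$R)
  center <- as.numeric(-Rcw %*% pose$pose$t)
  dir <- as.numeric(Rcw %*% c(nrm[1, 1], nrm[1, 2], 1))
  list(center = center, dir = dir / sqrt(sum(dir^2)))
}

# 3x4 projection matrix on undistorted normalized geometry: K [R | t].
projection_matrix <- function(intr, pose) {
  K <- matrix(c(intr$fx, intr$skew, intr$cx,
                0, intr$fy, intr$cy,
                0, 0, 1), 3, 3, byrow = TRUE)
  K %*% cbind(pose$pose$R, pose$pose$t)
}

#' Triangulate a 3D point from a camera pair
#'
#' Direct linear transformation (DLT) estimate from the two undistorted
#' pixel observations, refined by Gauss-Newton minimisation of the summed
#' squared reprojection error. With noiseless observations the result is
#' exact to numerical precision.
#'
#' @param camA,camB Lists with elements `intr` (`camera_intrinsics`) and
#'   `pose` (`camera_pose`).
#' @param pxA,pxB Length-2 pixel observations (u, v) in each camera.
#' @param min_angle_deg Minimum ray separation angle; closer-to-parallel
#'   geometry raises an error.
#' @return A list with `point` (length-3 mm), `residual_px` (RMS
#'   reprojection residual over the 4 coordinates) and `ray_angle_deg`.
#' @export
triangulate_pair <- function(camA, camB, pxA, pxB, min_angle_deg = 0.5) {
  rayA <- pixel_ray(camA$intr, camA$pose, pxA)
  rayB <- pixel_ray(camB$intr, camB$pose, pxB)
  if (max(abs(rayA$center - rayB$center)) < 1e-9) {
    stop("degenerate geometry: identical camera centers", call. = FALSE)
  }
  cosang <- abs(sum(rayA$dir * rayB$dir))
  angle <- acos(min(1, cosang)) * 180 / pi
  if (angle < min_angle_deg) {
    stop(sprintf("near-parallel rays (%.3f deg < %.3f deg): triangulation ill-conditioned",
                 angle, min_angle_deg), call. = FALSE)
  }
  # Undistort observations, then DLT on the distortion-free model.
  uvA <- undistort_px(camA$intr, pxA)
  uvB <- undistort_px(camB$intr, pxB)
  PA <- projection_matrix(strip_distortion(camA$intr), camA$pose)
  PB <- projection_matrix(strip_distortion(camB$intr), camB$pose)
  A <- rbind(uvA[1] * PA[3, ] - PA[1, ],
             uvA[2] * PA[3, ] - PA[2, ],
             uvB[1] * PB[3, ] - PB[1, ],
             uvB[2] * PB[3, ] - PB[2, ])
  v <- svd(A)$v[, 4]
  X <- v[1:3] / v[4]
  X <- refine_triangulation(X, camA, camB, pxA, pxB)
  res <- triang_residuals(X, camA, camB, pxA, pxB)
  list(point = X, residual_px = sqrt(mean(res^2)), ray_angle_deg = angle)
}

strip_distortion <- function(intr) {
  intr$dist[] <- 0
  intr
}

undistort_px <- function(intr, uv) {
  y <- (uv[2] - intr$cy) / intr$fy
  x <- (uv[1] - intr$cx - intr$skew * y) / intr$fx
  n <- undistort_normalized(matrix(c(x, y), 1, 2), intr$dist)
  c(intr$fx * n[1, 1] + intr$skew * n[1, 2] + intr$cx,
    intr$fy * n[1, 2] + intr$cy)
}

triang_residuals <- function(X, camA, camB, pxA, pxB) {
  c(project(camA$intr, camA$pose, X) - pxA,
    project(camB$intr, camB$pose, X) - pxB)
}

refine_triangulation <- function(X, camA, camB, pxA, pxB,
                                 max_iter = 15, tol = 1e-12) {
  f <- function(x) triang_residuals(x, camA, camB, pxA, pxB)
  r <- f(X)
  for (i in seq_len(max_iter)) {
    J <- numeric_jacobian(f, X, r)
    step <- tryCatch(solve(crossprod(J), crossprod(J, -r)),
                     error = function(e) NULL)
    if (is.null(step)) break
    Xn <- X + as.numeric(step)
    rn <- f(Xn)
    if (sum(rn^2) > sum(r^2)) break
    improved <- sum(r^2) - sum(rn^2)
    X <- Xn; r <- rn
    if (improved < tol) break
  }
  X
}

numeric_jacobian <- function(f, x, fx = f(x), h = 1e-6) {
  J <- matrix(0, length(fx), length(x))
  for (j in seq_along(x)) {
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' Select the camera pair for a marker
#'
#' Left-side markers are triangulated from the (front, left) pair and
#' right-side (and central) markers from (front, right); the lateral
#' (left, right) pair is used only when the front camera view of the marker
#' is unavailable.
#'
#' @param marker_side `"left"`, `"right"` or `"central"`.
#' @param availability Named logical vector of per-camera validity with
#'   names `front`, `left`, `right`.
#' @return Character vector of two camera ids, or `NULL` when fewer than two
#'   valid views remain (the marker is then flagged invalid upstream).
#' @export
select_camera_pair <- function(marker_side,
                               availability = c(front = TRUE, left = TRUE,
                                                right = TRUE)) {
  marker_side <- match.arg(marker_side, c("left", "right", "central"))
  av <- availability
  if (sum(av) < 2) return(NULL)
  lateral <- if (marker_side == "left") "left" else "right"
  if (av[["front"]] && av[[lateral]]) return(c("front", lateral))
  other <- setdiff(c("left", "right"), lateral)
  if (av[["front"]] && av[[other]]) return(c("front", other))
  if (av[["left"]] && av[["right"]]) return(c("left", "right"))
  NULL
}
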