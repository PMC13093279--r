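#' Rigid transforms and 6-DoF displacement decomposition
#'
#' The world frame used throughout the package is the patient frame of
#' upright positioning: x = LR (+left), y = AP (+anterior), z = SI
#' (+superior), a right-handed basis with all lengths in millimetres.
#' A `rigid_transform` maps reference-frame coordinates to current-frame
#' coordinates: `p_current = R %*% p_reference + t`.
#'
#' @param rotation 3x3 orthonormal rotation matrix with determinant +1.
#' @param translation length-3 numeric translation in mm.
#' @return An object of class `rigid_transform` with elements `R` and `t`.
#' @examples
#' rt <- rigid_transform(diag(3), c(1, 2, 3))
#' rt_apply(rt, c(0, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3)
  check_rotation(rotation)
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

check_rotation <- function(R, tol = 1e-9) {
  if (max(abs(crossprod(R) - diag(3))) > tol) {
    stop("rotation matrix is not orthonormal within tolerance", call. = FALSE)
  }
  if (abs(det(R) - 1) > tol) {
    stop("rotation matrix must have determinant +1 (no reflections)",
         call. = FALSE)
  }
  invisible(R)
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rt_angles(x)
  cat("<rigid_transform>\n")
  cat(sprintf("  translation [mm]: %.4f %.4f %.4f\n",
              x$t[1], x$t[2], x$t[3]))
  cat(sprintf("  yaw/pitch/roll [deg]: %.4f %.4f %.4f\n",
              ang["yaw"], ang["pitch"], ang["roll"]))
  invisible(x)
}

#' @rdname rigid_transform
#' @export
rt_identity <- function() rigid_transform()

#' Apply a rigid transform to points
#'
#' @param t A `rigid_transform`.
#' @param p A length-3 vector or an n x 3 matrix of points (mm).
#' @return Transformed points with the shape of the input.
#' @export
rt_apply <- function(t, p) {
  if (is.matrix(p)) {
    sweep(p %*% t(t$R), 2, t$t, "+")
  } else {
    as.numeric(t$R %*% p + t$t)
  }
}

#' Compose two rigid transforms
#'
#' `rt_compose(outer, inner)` returns the transform equivalent to applying
#' `inner` first and `outer` second.
#'
#' @param outer,inner `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
rt_compose <- function(outer, inner) {
  rigid_transform(outer$R %*% inner$R,
                  as.numeric(outer$R %*% inner$t + outer$t))
}

#' Invert a rigid transform
#'
#' @param t A `rigid_transform`.
#' @return The inverse transform.
#' @export
rt_invert <- function(t) {
  Rinv <- t(t$R)
  rigid_transform(Rinv, as.numeric(-Rinv %*% t$t))
}

#' Relative body-to-mask transform
#'
#' Body motion expressed relative to the (possibly also moving)
#' thermoplastic mask: the body transform composed with the inverse of the
#' mask transform. When body and mask move identically the result is the
#' identity transform.
#'
#' @param m_body,m_mask `rigid_transform` objects from the same frame,
#'   mapping reference coordinates to current coordinates.
#' @return A `rigid_transform` `m_body %*% m_mask^-1`.
#' @export
rt_relative <- function(m_body, m_mask) {
  rt_compose(m_body, rt_invert(m_mask))
}

# Axis rotation generators about the world LR (x), AP (y) and SI (z) axes,
# right-hand rule, angle in degrees.
rot_lr <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(a), -sin(a),
           0, sin(a), cos(a)), 3, 3, byrow = TRUE)
}
rot_ap <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, sin(a),
           0, 1, 0,
           -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
}
rot_si <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0,
           sin(a), cos(a), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Build a rotation from yaw, pitch and roll angles
#'
#' Intrinsic yaw-pitch-roll sequence: yaw about SI (z), then pitch about the
#' rotated LR (x), then roll about the twice-rotated AP (y). Equivalently
#' `R = Rz(yaw) %*% Rx(pitch) %*% Ry(roll)`. All observed clinical rotations
#' are below ~1.5 degrees, where the sequence choice is numerically
#' immaterial (a tested property), but one must be fixed.
#'
#' @param pitch,roll,yaw angles in degrees about the LR, AP and SI axes.
#' @return A 3x3 rotation matrix.
#' @export
rotation_from_angles <- function(pitch = 0, roll = 0, yaw = 0) {
  rot_si(yaw) %*% rot_lr(pitch) %*% rot_ap(roll)
}

# Euler decomposition of the intrinsic yaw (SI) - pitch (LR) - roll (AP)
# sequence. With R = Rz(yaw) Rx(pitch) Ry(roll):
#   R[3,2] = sin(pitch)
#   R[1,2] = -sin(yaw) cos(pitch),  R[2,2] = cos(yaw) cos(pitch)
#   R[3,1] = -cos(pitch) sin(roll), R[3,3] = cos(pitch) cos(roll)
rt_angles <- function(t, gimbal_tol = 1 - 1e-9) {
  R <- if (inherits(t, "rigid_transform")) t$R else t
  s <- max(-1, min(1, R[3, 2]))
  if (abs(s) > gimbal_tol) {
    warning("pitch within 1e-9 of +/-90 degrees: yaw/roll are degenerate",
            call. = FALSE)
  }
  c(pitch = asin(s) * 180 / pi,
    roll  = atan2(-R[3, 1], R[3, 3]) * 180 / pi,
    yaw   = atan2(-R[1, 2], R[2, 2]) * 180 / pi)
}

#' Decompose a rigid transform into a 6-DoF displacement
#'
#' Translations are reported as the motion of the chosen reporting origin:
#' `t(origin) - origin`, in mm along LR/AP/SI. Rotations are the intrinsic
#' yaw-pitch-roll Euler angles of the rotation part, in degrees about the
#' SI/LR/AP axes (right-hand rule). The rotation part is independent of the
#' origin; the translation part obeys `t_o = t_0 + (R - I) %*% o`.
#'
#' @param t A `rigid_transform` (reference -> current).
#' @param origin Length-3 reporting origin in mm (see [set_origin()]).
#' @return A named numeric vector with components `lr`, `ap`, `si` (mm) and
#'   `pitch`, `roll`, `yaw` (degrees).
#' @seealso [from_displacement()] for the inverse operation.
#' @export
to_displacement <- function(t, origin = c(0, 0, 0)) {
  d <- rt_apply(t, origin) - origin
  ang <- rt_angles(t)
  c(lr = d[1], ap = d[2], si = d[3],
    pitch = unname(ang["pitch"]), roll = unname(ang["roll"]),
    yaw = unname(ang["yaw"]))
}

#' Rebuild a rigid transform from a 6-DoF displacement
#'
#' Inverse of [to_displacement()] about the same reporting origin.
#'
#' @param d Named vector with `lr`, `ap`, `si` (mm), `pitch`, `roll`, `yaw`
#'   (degrees), or a one-row data frame with those columns.
#' @param origin Length-3 reporting origin in mm.
#' @return A `rigid_transform`.
#' @export
from_displacement <- function(d, origin = c(0, 0, 0)) {
  if (is.data.frame(d)) d <- unlist(d[1, c("lr", "ap", "si", "pitch", "roll", "yaw")])
  R <- rotation_from_angles(pitch = d[["pitch"]], roll = d[["roll"]],
                            yaw = d[["yaw"]])
  trans <- c(d[["lr"]], d[["ap"]], d[["si"]]) + origin - as.numeric(R %*% origin)
  rigid_transform(R, trans)
}

#' Serialize / deserialize a rigid transform as JSON
#'
#' Row-major rotation entries, translation in mm and the reporting origin
#' in mm, as a JSON object. Round-trips at full double precision.
#'
#' @param t A `rigid_transform`.
#' @param origin Reporting origin stored alongside (mm).
#' @return `rt_to_json()`: a JSON string; `rt_from_json()`: a list with
#'   elements `transform` (a `rigid_transform`) and `origin`.
#' @export
rt_to_json <- function(t, origin = c(0, 0, 0)) {
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::toJSON(list(rotation = as.numeric(t(t$R)),
                        translation_mm = t$t,
                        origin_mm = as.numeric(origin)),
                   digits = I(17))
}

#' @rdname rt_to_json
#' @param json JSON string produced by `rt_to_json()`.
#' @export
rt_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  list(transform = rigid_transform(
         matrix(as.numeric(x$rotation), 3, 3, byrow = TRUE),
         as.numeric(x$translation_mm)),
       origin = as.numeric(x$origin_mm))
}
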