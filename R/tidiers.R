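#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a tracking result
#'
#' One row per frame and tracked object with the 6-DoF displacement about
#' the supplied origin plus registration diagnostics.
#'
#' @param x A `track_result`.
#' @param origin Reporting origin (mm); defaults to the world origin.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.track_result <- function(x, origin = c(0, 0, 0), ...) {
  series <- displacement_series(x, origin, objects = c("body", "mask"))
  dplyr::left_join(series,
                   x$frames[, c("frame", "rms_body_mm", "rms_mask_mm",
                                "n_body", "n_mask")],
                   by = "frame")
}

#' @rdname tidy.track_result
#' @export
glance.track_result <- function(x, ...) {
  tibble::tibble(
    setup_type = x$setup_type,
    n_frames = nrow(x$frames),
    n_registered = sum(x$frames$registered),
    mean_rms_body_mm = mean(x$frames$rms_body_mm, na.rm = TRUE),
    mean_rms_mask_mm = mean(x$frames$rms_mask_mm, na.rm = TRUE))
}

#' Tidy an inter-fractional setup-error summary
#'
#' @param x An `interfraction_summary`.
#' @param ... Unused.
#' @return The per-axis mu / Sigma / sigma tibble.
#' @export
tidy.interfraction_summary <- function(x, ...) x$by_axis

#' @rdname tidy.interfraction_summary
#' @export
glance.interfraction_summary <- function(x, ...) {
  tibble::tibble(n_subjects = unname(x$n["subjects"]),
                 n_repetitions = unname(x$n["repetitions"]),
                 mean_3d_mm = unname(x$overall_3d["mean"]),
                 sd_3d_mm = unname(x$overall_3d["sd"]))
}

#' Tidy a beam-delivery-time result
#'
#' @param x A `bdt_result`.
#' @param ... Unused.
#' @return A tibble with the total and per-axis tolerable times (min).
#' @export
tidy.bdt_result <- function(x, ...) {
  tibble::tibble(axis = c("all", names(x$per_axis_min)),
                 tolerable_min = c(x$total_min, unname(x$per_axis_min)),
                 convention = x$convention)
}
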