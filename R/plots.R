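#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a displacement time series
#'
#' Six-panel time course (LR/AP/SI translations, pitch/roll/yaw rotations)
#' of the tracked objects, matching the sign convention: positive toward
#' left, anterior and superior relative to the reference frame.
#'
#' @param object A `displacement_series` tibble.
#' @param objects Objects to show (default body, mask and relative).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.displacement_series <- function(object,
                                         objects = c("body", "mask",
                                                     "relative"), ...) {
  long <- object |>
    dplyr::filter(.data$object %in% objects) |>
    tidyr::pivot_longer(dplyr::all_of(c("lr", "ap", "si",
                                        "pitch", "roll", "yaw")),
                        names_to = "axis", values_to = "value") |>
    dplyr::mutate(axis = factor(.data$axis,
                                levels = c("lr", "ap", "si",
                                           "pitch", "roll", "yaw"),
                                labels = c("LR [mm]", "AP [mm]", "SI [mm]",
                                           "pitch [deg]", "roll [deg]",
                                           "yaw [deg]")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s / 60,
                                     y = .data$value,
                                     colour = .data$object)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2,
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~axis, scales = "free_y") +
    ggplot2::labs(x = "Time [min]", y = "Displacement", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-axis tolerable times and total beam delivery time
#'
#' @param object A `bdt_result`.
#' @param ... Unused.
#' @return A ggplot bar chart.
#' @export
autoplot.bdt_result <- function(object, ...) {
  d <- tidy.bdt_result(object)
  d$axis <- factor(d$axis, levels = d$axis)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$axis,
                                  y = .data$tolerable_min)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Time within tolerance [min]",
                  subtitle = sprintf("%s counting", object$convention)) +
    ggplot2::theme_minimal()
}

#' Plot grid-plate reconstruction accuracy
#'
#' Per camera pair and axis, the mean absolute triangulation error with an
#' SD error bar and the 95th percentile marked.
#'
#' @param object A `grid_accuracy` tibble from [verify_grid()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.grid_accuracy <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$axis,
                                       y = .data$mean_abs_mm,
                                       fill = .data$pair)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_abs_mm,
                                        ymax = .data$mean_abs_mm + .data$sd_mm),
                           position = ggplot2::position_dodge(width = 0.9),
                           width = 0.25) +
    ggplot2::geom_point(ggplot2::aes(y = .data$p95_mm),
                        position = ggplot2::position_dodge(width = 0.9),
                        shape = 4) +
    ggplot2::labs(x = NULL, y = "Grid position error [mm]", fill = NULL,
                  subtitle = "bars: mean |error| + SD; crosses: 95th percentile") +
    ggplot2::theme_minimal()
}
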