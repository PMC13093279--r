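#' Displacement time series from tracked transforms
#'
#' Converts the per-frame body and mask transforms of a [track_sequence()]
#' result into 6-DoF displacement series about the reporting origin, plus
#' the relative body-to-mask series (body transform composed with the
#' inverse mask transform) and the raw per-thigh-marker translation series.
#' Unregistered frames appear with NA displacements and `registered =
#' FALSE`; downstream metrics exclude them and log the count.
#'
#' @param track A `track_result`.
#' @param origin Reporting origin from [set_origin()] (mm).
#' @param objects Which series to emit: subset of `"body"`, `"mask"`,
#'   `"relative"`, `"marker"`.
#' @return A `displacement_series` tibble: columns `object`, `frame`,
#'   `time_s`, `lr`, `ap`, `si` (mm), `pitch`, `roll`, `yaw` (deg),
#'   `registered`. Thigh-marker objects are named `marker:<label>` and carry
#'   NA rotations (individual markers have no orientation).
#' @export
displacement_series <- function(track, origin,
                                objects = c("body", "mask", "relative",
                                            "marker")) {
  frames <- track$frames
  rows <- list()
  series_of <- function(transforms, object) {
    purrr::map2_dfr(seq_len(nrow(frames)), transforms, function(k, tr) {
      if (is.null(tr)) {
        d <- stats::setNames(rep(NA_real_, 6),
                             c("lr", "ap", "si", "pitch", "roll", "yaw"))
        ok <- FALSE
      } else {
        d <- to_displacement(tr, origin)
        ok <- TRUE
      }
      tibble::tibble(object = object, frame = frames$frame[k],
                     time_s = frames$time_s[k],
                     lr = d[["lr"]], ap = d[["ap"]], si = d[["si"]],
                     pitch = d[["pitch"]], roll = d[["roll"]],
                     yaw = d[["yaw"]], registered = ok)
    })
  }
  if ("body" %in% objects) rows$body <- series_of(track$body, "body")
  if ("mask" %in% objects) rows$mask <- series_of(track$mask, "mask")
  if ("relative" %in% objects) {
    rel <- purrr::map2(track$body, track$mask, function(b, m) {
      if (is.null(b) || is.null(m)) NULL else rt_relative(b, m)
    })
    rows$relative <- series_of(rel, "relative")
  }
  if ("marker" %in% objects && nrow(track$thigh) > 0) {
    rows$marker <- track$thigh |>
      dplyr::transmute(object = paste0("marker:", .data$marker),
                       frame = .data$frame, time_s = .data$time_s,
                       lr = .data$lr, ap = .data$ap, si = .data$si,
                       pitch = NA_real_, roll = NA_real_, yaw = NA_real_,
                       registered = .data$valid)
  }
  out <- dplyr::bind_rows(rows)
  n_bad <- sum(!out$registered)
  if (n_bad > 0) {
    message(sprintf("displacement_series: %d unregistered/invalid records excluded from metrics",
                    n_bad))
  }
  class(out) <- c("displacement_series", class(out))
  out
}

#' 3D (Euclidean) displacement magnitude
#'
#' L2 norm of the translational triplet; rotations are reported separately.
#'
#' @param d A displacement: named vector or data frame with `lr`, `ap`,
#'   `si` columns (mm).
#' @return Numeric 3D displacement(s) in mm.
#' @export
euclidean_3d <- function(d) {
  if (is.data.frame(d)) sqrt(d$lr^2 + d$ap^2 + d$si^2)
  else sqrt(d[["lr"]]^2 + d[["ap"]]^2 + d[["si"]]^2)
}

#' Inter-fractional setup-error summary
#'
#' Per-axis overall mean mu, systematic component Sigma and random
#' component sigma of setup errors over subjects x repetitions:
#' mu is the mean of the per-subject mean errors, Sigma the standard
#' deviation (n-1) of the per-subject means over subjects, and sigma the
#' mean over subjects of the per-subject standard deviations (n-1). The 3D
#' row applies the same definitions to the per-repetition Euclidean norms
#' of the translations.
#'
#' @param errors Tibble with columns `subject`, `rep`, `lr`, `ap`, `si`
#'   (mm), `pitch`, `roll`, `yaw` (deg): one row per subject x repetition.
#' @return An `interfraction_summary` object: list with `by_axis` (tibble
#'   axis x mu/Sigma/sigma/n_subjects), `overall_3d` (mean and SD of all
#'   per-repetition 3D errors) and `n`. Subjects with a single repetition
#'   leave sigma undefined (NA) and are flagged.
#' @export
interfraction_summary <- function(errors) {
  stopifnot(all(c("subject", "rep", "lr", "ap", "si",
                  "pitch", "roll", "yaw") %in% names(errors)))
  if (dplyr::n_distinct(errors$subject) < 2) {
    stop("at least 2 subjects are required for Sigma", call. = FALSE)
  }
  long <- errors |>
    dplyr::mutate(`3D` = euclidean_3d(errors)) |>
    tidyr::pivot_longer(dplyr::all_of(c("lr", "ap", "si", "3D",
                                        "pitch", "roll", "yaw")),
                        names_to = "axis", values_to = "value") |>
    dplyr::filter(is.finite(.data$value))
  per_subject <- long |>
    dplyr::group_by(.data$axis, .data$subject) |>
    dplyr::summarise(m = mean(.data$value),
                     s = stats::sd(.data$value),
                     n_rep = dplyr::n(), .groups = "drop")
  single_rep <- per_subject |> dplyr::filter(.data$n_rep < 2)
  if (nrow(single_rep) > 0) {
    message(sprintf("interfraction_summary: %d subject-axis cells have a single repetition; sigma undefined there",
                    nrow(single_rep)))
  }
  axis_order <- c("lr", "ap", "si", "3D", "pitch", "roll", "yaw")
  by_axis <- per_subject |>
    dplyr::group_by(.data$axis) |>
    dplyr::summarise(
      mu = mean(.data$m),
      sigma_systematic = stats::sd(.data$m),
      sigma_random = mean(.data$s),
      n_subjects = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(match(.data$axis, axis_order))
  e3 <- euclidean_3d(errors)
  structure(list(by_axis = by_axis,
                 overall_3d = c(mean = mean(e3, na.rm = TRUE),
                                sd = stats::sd(e3, na.rm = TRUE)),
                 n = c(subjects = dplyr::n_distinct(errors$subject),
                       repetitions = nrow(errors))),
            class = "interfraction_summary")
}

#' @export
print.interfraction_summary <- function(x, ...) {
  cat(sprintf("<interfraction_summary> %d subjects, %d repetitions\n",
              x$n["subjects"], x$n["repetitions"]))
  cat(sprintf("  3D setup error: %.2f +/- %.2f mm\n",
              x$overall_3d["mean"], x$overall_3d["sd"]))
  print(x$by_axis)
  invisible(x)
}

#' Tolerance thresholds for beam-delivery-time analysis
#'
#' Defaults per treatment region: +/- 2 mm / +/- 1 deg for abdominal
#' setups and +/- 1.5 mm / +/- 1 deg for head-and-neck setups.
#'
#' @param translation_mm,rotation_deg Positive tolerance half-widths.
#' @return A `tolerance_spec` list.
#' @export
tolerance_spec <- function(translation_mm, rotation_deg = 1) {
  stopifnot(translation_mm > 0, rotation_deg > 0)
  structure(list(translation_mm = translation_mm,
                 rotation_deg = rotation_deg), class = "tolerance_spec")
}

#' @rdname tolerance_spec
#' @param setup_type `"abdominal"` or `"hn"`.
#' @export
default_tolerance <- function(setup_type = c("abdominal", "hn")) {
  setup_type <- match.arg(setup_type)
  tolerance_spec(if (setup_type == "abdominal") 2 else 1.5, 1)
}

#' Beam delivery time under motion tolerances
#'
#' Time during the session in which all six displacement components stay
#' within the tolerance thresholds, plus the six per-axis tolerable times.
#' Under the default `"cumulative"` convention every within-tolerance frame
#' after the reference contributes one full cadence interval (a fully
#' within-tolerance 20-min session of 241 frames yields 240 x 5 s =
#' 20 min); frame 0 is within tolerance by construction. The
#' `"until_first_violation"` convention counts only the interval up to the
#' first out-of-tolerance frame.
#'
#' @param series A `displacement_series` tibble (one object, e.g. the body
#'   series) with uniform cadence.
#' @param tol A `tolerance_spec`.
#' @param convention `"cumulative"` or `"until_first_violation"`.
#' @return A `bdt_result`: list with `total_min`, `per_axis_min` (named,
#'   six axes), `convention`, `cadence_s`, `n_frames`.
#' @export
bdt <- function(series, tol, convention = c("cumulative",
                                            "until_first_violation")) {
  convention <- match.arg(convention)
  if (nrow(series) == 0) stop("empty displacement series", call. = FALSE)
  if (length(unique(series$object)) > 1) {
    stop("bdt expects a single-object series; filter first", call. = FALSE)
  }
  series <- dplyr::arrange(series, .data$time_s)
  dt <- unique(round(diff(series$time_s), 9))
  if (length(dt) != 1) stop("bdt requires a uniform cadence", call. = FALSE)
  cadence <- dt
  within_tr <- function(x) !is.na(x) & abs(x) <= tol$translation_mm
  within_rot <- function(x) !is.na(x) & abs(x) <= tol$rotation_deg
  w <- cbind(lr = within_tr(series$lr), ap = within_tr(series$ap),
             si = within_tr(series$si), pitch = within_rot(series$pitch),
             roll = within_rot(series$roll), yaw = within_rot(series$yaw))
  count_time <- function(ok) {
    if (convention == "cumulative") {
      n <- sum(ok) - 1          # frame 0 anchors; each later in-frame adds one interval
    } else {
      first_bad <- which(!ok)[1]
      n <- if (is.na(first_bad)) length(ok) - 1 else first_bad - 2
    }
    max(0, n) * cadence / 60
  }
  per_axis <- apply(w, 2, count_time)
  total <- count_time(rowSums(w) == 6)
  structure(list(total_min = total, per_axis_min = per_axis,
                 convention = convention, cadence_s = cadence,
                 n_frames = nrow(series)),
            class = "bdt_result")
}

#' @export
print.bdt_result <- function(x, ...) {
  cat(sprintf("<bdt_result> total %.2f min (%s convention, %d frames @ %.0f s)\n",
              x$total_min, x$convention, x$n_frames, x$cadence_s))
  print(round(x$per_axis_min, 2))
  invisible(x)
}
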