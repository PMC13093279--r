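#' Closed-form rigid fit between corresponded point sets (Kabsch)
#'
#' Least-squares rigid transform mapping `source` onto `target` via
#' singular value decomposition of the cross-covariance, with the
#' determinant correction that excludes reflections.
#'
#' @param source,target n x 3 matrices of corresponded points (n >= 3,
#'   non-collinear).
#' @return A list with `transform` (a `rigid_transform` such that
#'   `rt_apply(transform, source) ~ target`) and `rms_mm` (root-mean-square
#'   residual distance).
#' @export
kabsch <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  stopifnot(ncol(source) == 3, ncol(target) == 3,
            nrow(source) == nrow(target))
  if (nrow(source) < 3) {
    stop("at least 3 point pairs are required for a rigid fit", call. = FALSE)
  }
  if (point_rank(source) < 2) {
    stop("degenerate configuration: source points are collinear", call. = FALSE)
  }
  cs <- colMeans(source); ct <- colMeans(target)
  H <- crossprod(sweep(source, 2, cs), sweep(target, 2, ct))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- ct - as.numeric(R %*% cs)
  tr <- rigid_transform(R, t)
  res <- rt_apply(tr, source) - target
  list(transform = tr, rms_mm = sqrt(mean(rowSums(res^2))))
}

#' Iterative closest point rigid registration
#'
#' Alternates correspondence assignment and the closed-form Kabsch update
#' until the RMS change falls below tolerance. In `"nearest"` mode each
#' transformed source point is matched to its nearest target point (the
#' classic ICP used per frame on the marker clouds); `"labeled"` mode uses
#' the marker labels as fixed correspondences and serves as the oracle path.
#' Only markers valid in both clouds participate.
#'
#' @param source,target Labeled clouds: tibbles with columns `marker`, `x`,
#'   `y`, `z`, `valid` (see [make_layout()]). Matrices are accepted in
#'   labeled-free form.
#' @param mode `"nearest"` or `"labeled"`.
#' @param init Initial `rigid_transform` (identity default; millimetric
#'   clinical motions keep identity inside the convergence basin).
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the change in RMS (mm).
#' @return A list: `transform`, `rms_mm`, `iterations`, `rms_trace`
#'   (per-iteration RMS, non-increasing), `n_points`, `converged`.
#' @export
icp <- function(source, target, mode = c("nearest", "labeled"),
                init = rt_identity(), max_iter = 50, tol = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(tol > 0, max_iter >= 1)
  if (is.data.frame(source)) {
    # only markers valid in BOTH clouds participate
    keep_s <- source[source$valid, , drop = FALSE]
    keep_t <- target[target$valid, , drop = FALSE]
    common <- intersect(keep_s$marker, keep_t$marker)
    keep_s <- keep_s[keep_s$marker %in% common, , drop = FALSE]
    keep_t <- keep_t[keep_t$marker %in% common, , drop = FALSE]
    if (mode == "labeled") {
      keep_s <- keep_s[match(common, keep_s$marker), , drop = FALSE]
      keep_t <- keep_t[match(common, keep_t$marker), , drop = FALSE]
    }
    S <- as.matrix(keep_s[, c("x", "y", "z")])
    Tm <- as.matrix(keep_t[, c("x", "y", "z")])
  } else {
    S <- as.matrix(source); Tm <- as.matrix(target)
  }
  if (nrow(S) < 3 || nrow(Tm) < 3) {
    return(list(transform = NULL, rms_mm = NA_real_, iterations = 0L,
                rms_trace = numeric(), n_points = min(nrow(S), nrow(Tm)),
                converged = FALSE))
  }
  tr <- init
  rms_trace <- numeric()
  prev_rms <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Sm <- rt_apply(tr, S)
    idx <- if (mode == "labeled") {
      seq_len(nrow(Tm))
    } else {
      nearest_index(Sm, Tm)
    }
    fit <- kabsch(S, Tm[idx, , drop = FALSE])
    tr <- fit$transform
    rms <- fit$rms_mm
    rms_trace <- c(rms_trace, rms)
    if (mode == "labeled" || abs(prev_rms - rms) < tol) {
      converged <- TRUE
      if (mode == "labeled") break
      break
    }
    prev_rms <- rms
  }
  if (!converged) {
    warning(sprintf("ICP stopped at iteration cap (last RMS %.3e mm, change %.3e mm)",
                    rms, abs(prev_rms - rms)), call. = FALSE)
  }
  list(transform = tr, rms_mm = rms, iterations = length(rms_trace),
       rms_trace = rms_trace, n_points = nrow(S), converged = converged)
}

nearest_index <- function(A, B) {
  # index into B of the nearest neighbour of each row of A
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  max.col(-d2, ties.method = "first")
}

#' Moving-average smoothing of a time series
#'
#' Centred (default) or trailing moving average. Near the series edges the
#' centred window shrinks symmetrically (5 -> 3 -> 1 frames) so the filter
#' stays phase-neutral and unbiased everywhere: in particular the reference
#' frame (frame 0) passes through unchanged. The trailing mode truncates
#' causally to the available past frames. Used to suppress quasi-periodic
#' respiratory displacement of the abdominal skin markers before rigid
#' registration.
#'
#' @param x Numeric vector sampled at a uniform cadence.
#' @param window Window length in frames (default 5).
#' @param mode `"centered"` (phase-neutral) or `"trailing"` (causal).
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_ma <- function(x, window = 5, mode = c("centered", "trailing")) {
  mode <- match.arg(mode)
  n <- length(x)
  if (n < 1) stop("series must contain at least one frame", call. = FALSE)
  half <- (window - 1) %/% 2
  vapply(seq_len(n), function(i) {
    if (mode == "centered") {
      h <- min(half, i - 1, n - i)
      lo <- i - h; hi <- i + h
    } else {
      lo <- max(1, i - window + 1); hi <- i
    }
    mean(x[lo:hi])
  }, numeric(1))
}

#' Smooth the respiratory markers of a cloud sequence
#'
#' Applies [smooth_ma()] per marker and axis to the 3D positions of
#' `body_respiratory` markers across frames; all other roles pass through
#' unchanged. Frames where a marker is invalid are excluded from its
#' averages and stay invalid.
#'
#' @param clouds Tibble of stacked per-frame clouds: columns `frame`,
#'   `time_s`, `marker`, `x`, `y`, `z`, `role`, `valid`.
#' @param window,mode See [smooth_ma()].
#' @param roles Roles to smooth.
#' @return The clouds tibble with smoothed coordinates.
#' @export
smooth_cloud_series <- function(clouds, window = 5,
                                mode = c("centered", "trailing"),
                                roles = "body_respiratory") {
  mode <- match.arg(mode)
  smooth_col <- function(col, role, valid) {
    if (!(role[1] %in% roles) || !any(valid)) return(col)
    col[valid] <- smooth_ma(col[valid], window = window, mode = mode)
    col
  }
  clouds |>
    dplyr::group_by(.data$marker) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(x = smooth_col(.data$x, .data$role, .data$valid),
                  y = smooth_col(.data$y, .data$role, .data$valid),
                  z = smooth_col(.data$z, .data$role, .data$valid)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$frame, .data$marker)
}

#' Reporting origin on the chair rotation axis
#'
#' The origin of all reported transforms sits on the vertical rotation axis
#' of the treatment chair (a vertical line 15 cm anterior to the backrest),
#' at the SI height of the anatomy anchor marker in the reference cloud:
#' A2 for abdominal setups, H1 for head-and-neck setups.
#'
#' @param reference Reference labeled cloud (tibble with `marker`, `x`,
#'   `y`, `z`, `valid`).
#' @param setup_type `"abdominal"` or `"hn"`; selects the anchor marker
#'   unless `anchor` is given.
#' @param axis_lr,axis_ap LR and AP coordinates (mm) of the vertical
#'   rotation axis.
#' @param anchor Anchor marker label override.
#' @return Length-3 origin in world mm.
#' @export
set_origin <- function(reference, setup_type = c("abdominal", "hn"),
                       axis_lr = 0, axis_ap = 150, anchor = NULL) {
  setup_type <- match.arg(setup_type)
  if (is.null(anchor)) anchor <- if (setup_type == "abdominal") "A2" else "H1"
  row <- reference[reference$marker == anchor, , drop = FALSE]
  if (nrow(row) != 1 || !row$valid) {
    stop(sprintf("anchor marker %s is missing or invalid in the reference cloud",
                 anchor), call. = FALSE)
  }
  c(axis_lr, axis_ap, row$z)
}

#' Track body and mask transforms across a session
#'
#' Runs the per-frame rigid registration of the tracking pipeline: the mask
#' transform from mask-role markers and the body transform from body-role
#' markers, each registered from the reference cloud (frame 0) to the
#' current frame. For abdominal sessions the respiratory markers (A1-A9)
#' are first smoothed over `smooth_window` frames ([smooth_cloud_series()]);
#' thigh markers (A10, A11) are excluded from registration and reported as
#' raw per-marker displacement vectors.
#'
#' @param clouds Stacked per-frame clouds (columns `frame`, `time_s`,
#'   `marker`, `x`, `y`, `z`, `role`, `valid`); frame 0 is the reference.
#' @param setup_type `"abdominal"` or `"hn"`.
#' @param smooth Smooth respiratory markers first (TRUE for intra-fractional
#'   sessions; inter-fractional single images are never smoothed).
#' @param smooth_window,smooth_mode See [smooth_ma()].
#' @param mode,max_iter,tol ICP settings, see [icp()].
#' @return A `track_result` object: list with `frames` (tibble of per-frame
#'   `time_s`, `rms_body_mm`, `rms_mask_mm`, `n_body`, `n_mask`,
#'   `registered`), `body`, `mask` (lists of `rigid_transform` per frame),
#'   `thigh` (tibble of per-frame thigh-marker displacement vectors) and
#'   `setup_type`.
#' @export
track_sequence <- function(clouds, setup_type = c("abdominal", "hn"),
                           smooth = TRUE, smooth_window = 5,
                           smooth_mode = "centered",
                           mode = "nearest", max_iter = 50, tol = 1e-6) {
  setup_type <- match.arg(setup_type)
  body_roles <- if (setup_type == "abdominal") "body_respiratory" else "body_rigid"
  if (smooth && setup_type == "abdominal") {
    clouds <- smooth_cloud_series(clouds, window = smooth_window,
                                  mode = smooth_mode)
  }
  frames <- sort(unique(clouds$frame))
  stopifnot(frames[1] == 0)
  ref <- clouds[clouds$frame == 0, , drop = FALSE]
  ref_body <- ref[ref$role %in% body_roles, , drop = FALSE]
  ref_mask <- ref[ref$role == "mask", , drop = FALSE]
  ref_thigh <- ref[ref$role == "thigh", , drop = FALSE]

  body <- mask <- vector("list", length(frames))
  rows <- vector("list", length(frames))
  thigh <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    f <- frames[k]
    cur <- clouds[clouds$frame == f, , drop = FALSE]
    if (f == 0) {
      body[[k]] <- rt_identity(); mask[[k]] <- rt_identity()
      fb <- list(rms_mm = 0, n_points = sum(ref_body$valid), converged = TRUE)
      fm <- list(rms_mm = 0, n_points = sum(ref_mask$valid), converged = TRUE)
    } else {
      fb <- icp(ref_body, cur[cur$role %in% body_roles, , drop = FALSE],
                mode = mode, max_iter = max_iter, tol = tol)
      fm <- icp(ref_mask, cur[cur$role == "mask", , drop = FALSE],
                mode = mode, max_iter = max_iter, tol = tol)
      body[[k]] <- fb$transform
      mask[[k]] <- fm$transform
    }
    rows[[k]] <- tibble::tibble(
      frame = f, time_s = cur$time_s[1],
      rms_body_mm = fb$rms_mm, rms_mask_mm = fm$rms_mm,
      n_body = fb$n_points, n_mask = fm$n_points,
      registered = !is.null(body[[k]]) && !is.null(mask[[k]]))
    th <- dplyr::inner_join(ref_thigh, cur[cur$role == "thigh", ],
                            by = "marker", suffix = c("_ref", ""))
    if (nrow(th) > 0) {
      thigh[[k]] <- tibble::tibble(
        frame = f, time_s = cur$time_s[1], marker = th$marker,
        lr = th$x - th$x_ref, ap = th$y - th$y_ref, si = th$z - th$z_ref,
        valid = th$valid & th$valid_ref)
    }
  }
  structure(list(frames = dplyr::bind_rows(rows),
                 body = body, mask = mask,
                 thigh = dplyr::bind_rows(thigh),
                 setup_type = setup_type),
            class = "track_result")
}

#' @export
print.track_result <- function(x, ...) {
  n <- nrow(x$frames)
  cat(sprintf("<track_result> %s setup, %d frames (%d registered)\n",
              x$setup_type, n, sum(x$frames$registered)))
  invisible(x)
}
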