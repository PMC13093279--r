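#' Binarize an image patch
#'
#' Dark circular markers are segmented by thresholding: pixels at or below
#' the threshold become 0 (marker), pixels above become 1 (background).
#' The default threshold is Otsu's rule computed per patch; a fixed
#' threshold can be supplied instead.
#'
#' @param patch Integer/numeric matrix of 8-bit grayscale values (rows = v,
#'   columns = u).
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Threshold for `method = "fixed"` (0-255).
#' @return A 0/1 integer matrix of the same shape, attribute `threshold`
#'   holding the threshold used. A uniform patch under Otsu binarizes to all
#'   background (no dark pixels), which flags the detection invalid
#'   downstream.
#' @export
binarize <- function(patch, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  if (length(patch) == 0) stop("empty patch", call. = FALSE)
  thr <- switch(method,
                otsu = otsu_threshold(patch),
                fixed = {
                  if (is.null(threshold)) stop("fixed method needs a threshold", call. = FALSE)
                  threshold
                })
  out <- matrix(as.integer(patch > thr), nrow(patch), ncol(patch))
  attr(out, "threshold") <- thr
  out
}

# Otsu's threshold: maximise between-class variance over the 0..255
# histogram. Returns the largest maximiser; a uniform patch yields
# threshold >= max(patch) so no pixel is classified dark... the convention
# here keeps a uniform patch all-background (dark set empty).
otsu_threshold <- function(patch) {
  v <- as.integer(patch)
  if (min(v) == max(v)) return(min(v) - 1L)  # nothing at/below threshold
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  which.max(sigma_b) - 1L   # threshold t: dark class is {value <= t}
}

#' Centroid of the dark pixels of a binarized patch
#'
#' The sub-pixel marker position is the mean of the dark-pixel centres.
#' Pixel (i, j) of the patch (0-based row i, column j) has centre
#' (u, v) = (j, i); the patch offset places it in full-image coordinates.
#'
#' @param bin 0/1 matrix from [binarize()] (0 = dark/marker).
#' @param offset Length-2 (u, v) pixel offset of the patch top-left corner
#'   in the full image (default c(0, 0)).
#' @param min_area Minimum dark-pixel count for a valid detection.
#' @return A one-row tibble: `u`, `v` (sub-pixel, full-image coords),
#'   `valid`, `dark_px`.
#' @export
centroid_of_dark <- function(bin, offset = c(0, 0), min_area = 10) {
  dark <- which(bin == 0L, arr.ind = TRUE)
  n <- nrow(dark)
  if (n == 0 || n < min_area) {
    return(tibble::tibble(u = NA_real_, v = NA_real_, valid = FALSE,
                          dark_px = n))
  }
  tibble::tibble(u = mean(dark[, 2] - 1) + offset[1],
                 v = mean(dark[, 1] - 1) + offset[2],
                 valid = TRUE, dark_px = n)
}

#' Detect all configured markers in one camera frame
#'
#' Each marker has a static patch box; the patch is binarized and the dark
#' centroid computed. Markers whose patch yields fewer than `min_area` dark
#' pixels (occluded, removed, covered) are flagged invalid, never dropped.
#'
#' @param image 8-bit grayscale matrix (rows = v, columns = u), or `NULL`
#'   when `patches` supplies per-marker patch matrices directly.
#' @param boxes Tibble with columns `marker`, `u0`, `v0`, `width`, `height`
#'   (0-based top-left corner and size in px). Boxes must lie inside the
#'   image.
#' @param camera Camera id recorded in the output.
#' @param method,threshold,min_area Passed to [binarize()] /
#'   [centroid_of_dark()].
#' @param patches Optional named list of patch matrices (names = marker
#'   labels) overriding extraction from `image`.
#' @return Tibble with one row per configured marker: `marker`, `camera`,
#'   `u`, `v`, `valid`, `dark_px`.
#' @export
detect_frame <- function(image, boxes, camera = "front",
                         method = "otsu", threshold = NULL, min_area = 10,
                         patches = NULL) {
  purrr::pmap_dfr(boxes, function(marker, u0, v0, width, height, ...) {
    if (is.null(patches)) {
      if (u0 < 0 || v0 < 0 || v0 + height > nrow(image) ||
          u0 + width > ncol(image)) {
        stop(sprintf("patch box for marker %s lies outside the image", marker),
             call. = FALSE)
      }
      patch <- image[(v0 + 1):(v0 + height), (u0 + 1):(u0 + width), drop = FALSE]
    } else {
      patch <- patches[[marker]]
    }
    bin <- binarize(patch, method = method, threshold = threshold)
    det <- centroid_of_dark(bin, offset = c(u0, v0), min_area = min_area)
    dplyr::mutate(det, marker = marker, camera = camera, .before = 1)
  })
}

#' Render a synthetic marker patch
#'
#' Draws a dark anti-aliased disc on a light background by area-coverage
#' supersampling; used by the scene simulator to exercise the detection
#' stage with known sub-pixel ground truth.
#'
#' @param center Length-2 (u, v) disc centre in full-image px.
#' @param box One-row data frame / list with `u0`, `v0`, `width`, `height`.
#' @param radius_px Disc radius in px.
#' @param fg,bg Foreground (marker) and background gray levels (0-255).
#' @param supersample Sub-pixel sampling factor per axis.
#' @return Integer matrix `height` x `width` of 8-bit values.
#' @export
render_marker_patch <- function(center, box, radius_px, fg = 10, bg = 200,
                                supersample = 8) {
  w <- box$width; h <- box$height
  s <- supersample
  # sub-pixel sample centres in full-image coordinates
  us <- box$u0 + (seq_len(w * s) - 0.5) / s - 0.5
  vs <- box$v0 + (seq_len(h * s) - 0.5) / s - 0.5
  du2 <- (us - center[1])^2
  dv2 <- (vs - center[2])^2
  inside <- outer(dv2, du2, "+") <= radius_px^2
  # average coverage over each s x s block
  cov <- block_mean(inside, s)
  matrix(as.integer(round(bg + (fg - bg) * cov)), h, w)
}

block_mean <- function(m, s) {
  nr <- nrow(m) / s
  nc <- ncol(m) / s
  rowsum_r <- rowsum(m + 0, rep(seq_len(nr), each = s))
  t(rowsum(t(rowsum_r), rep(seq_len(nc), each = s))) / s^2
}
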