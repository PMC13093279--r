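#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. Implemented at formula level:
#' `t = (mean(x) - mean(y)) / sqrt(s1^2/n1 + s2^2/n2)`.
#'
#' @param x,y Numeric samples, each with at least 2 values.
#' @return A tibble: `test`, `statistic`, `df`, `p`, `n1`, `n2`.
#' @export
welch_t <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("each sample needs at least 2 finite values", call. = FALSE)
  }
  v1 <- stats::var(x); v2 <- stats::var(y)
  n1 <- length(x); n2 <- length(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 <= 0) stop("zero variance in both samples: t undefined", call. = FALSE)
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  tibble::tibble(test = "welch_t", statistic = t, df = df,
                 p = 2 * stats::pt(-abs(t), df), n1 = n1, n2 = n2)
}

#' Brown-Forsythe test for equality of variances
#'
#' Median-centred Levene procedure: each observation is replaced by its
#' absolute deviation from the group median, and a one-way ANOVA F test is
#' applied to those deviations.
#'
#' @param groups List of numeric samples (>= 2 groups, each >= 2 values).
#' @return A tibble: `test`, `statistic`, `df` (numerator), `df2`
#'   (denominator), `p`, `n` (total observations).
#' @export
brown_forsythe <- function(groups) {
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  }
  z <- lapply(groups, function(g) abs(g - stats::median(g)))
  allz <- unlist(z)
  if (all(allz == 0)) {
    stop("all absolute deviations are zero: Brown-Forsythe degenerate",
         call. = FALSE)
  }
  k <- length(z)
  N <- length(allz)
  zbar <- mean(allz)
  zm <- vapply(z, mean, numeric(1))
  ssb <- sum(lengths(z) * (zm - zbar)^2)
  ssw <- sum(unlist(Map(function(g, m) (g - m)^2, z, zm)))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  tibble::tibble(test = "brown_forsythe", statistic = f,
                 df = k - 1, df2 = N - k,
                 p = stats::pf(f, k - 1, N - k, lower.tail = FALSE), n = N)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Sorts the m p-values ascending, multiplies the i-th smallest by
#' (m - i + 1), enforces monotone non-decreasing adjusted values, caps at 1
#' and returns them in the input order.
#'
#' @param pvals Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
holm_bonferroni <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  m <- length(pvals)
  if (m == 0) return(numeric())
  ord <- order(pvals)
  adj <- pvals[ord] * (m - seq_len(m) + 1)
  adj <- cummax(adj)
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Pairwise setup comparisons with multiplicity adjustment
#'
#' For each requested pair of setups, compares per-subject metric values
#' with Welch's t-test (means) and the Brown-Forsythe test (variances).
#' When `adjust = TRUE` the Holm-Bonferroni correction is applied across
#' the pair family, separately per test, mirroring the all-pairs comparison
#' among head-and-neck setups; a single unadjusted comparison mirrors the
#' two-setup abdominal contrast.
#'
#' @param data Tibble with columns `setup`, `subject`, `value` (one metric
#'   value per subject per setup).
#' @param pairs List of length-2 character vectors of setup labels; default
#'   all pairs present.
#' @param alpha Significance level for the `significant` flag.
#' @param adjust Apply Holm-Bonferroni across the family of pairs.
#' @return A `comparison_report` tibble: `pair`, `test`, `statistic`, `df`,
#'   `p_raw`, `p_adj`, `significant`.
#' @export
compare_setups <- function(data, pairs = NULL, alpha = 0.05, adjust = TRUE) {
  stopifnot(all(c("setup", "subject", "value") %in% names(data)))
  setups <- unique(data$setup)
  if (is.null(pairs)) {
    pairs <- utils::combn(sort(setups), 2, simplify = FALSE)
  }
  bad <- setdiff(unlist(pairs), setups)
  if (length(bad) > 0) {
    stop(sprintf("unknown setup labels: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  res <- purrr::map_dfr(pairs, function(pr) {
    x <- data$value[data$setup == pr[1]]
    y <- data$value[data$setup == pr[2]]
    dplyr::bind_rows(welch_t(x, y), brown_forsythe(list(x, y))) |>
      dplyr::mutate(pair = paste(pr, collapse = " vs "), .before = 1)
  })
  res <- res |>
    dplyr::group_by(.data$test) |>
    dplyr::mutate(p_adj = if (adjust) holm_bonferroni(.data$p) else .data$p) |>
    dplyr::ungroup() |>
    dplyr::transmute(pair = .data$pair, test = .data$test,
                     statistic = .data$statistic, df = .data$df,
                     p_raw = .data$p, p_adj = .data$p_adj,
                     significant = .data$p_adj < alpha)
  class(res) <- c("comparison_report", class(res))
  res
}
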