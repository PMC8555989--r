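#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two independent samples, the test used for the
#' stimulated-versus-unstimulated interval comparisons. The U statistic is
#' computed from midranks; the p-value is exact (full enumeration of rank
#' assignments) when `n_x + n_y <= 20` and there are no ties, and otherwise
#' uses the normal approximation with tie correction and continuity
#' correction. Computation is delegated to [stats::wilcox.test()], whose W
#' statistic for `x` versus `y` is exactly the Mann-Whitney U of `x`.
#'
#' @param x,y numeric samples (each non-empty, finite).
#' @param alternative only `"two.sided"` is supported.
#' @param exact force (`TRUE`) or suppress (`FALSE`) the exact-distribution
#'   p-value; `NULL` (default) chooses by the rule above. Ties always fall
#'   back to the approximation.
#' @return list with elements `u` (U statistic of `x`), `p_value`, `exact`
#'   (logical, whether the exact distribution was used).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney_u <- function(x, y, alternative = "two.sided", exact = NULL) {
  alternative <- match.arg(alternative, "two.sided")
  if (length(x) < 1L || length(y) < 1L)
    stop("both samples must be non-empty", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("samples must be finite numeric", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  if (is.null(exact)) exact <- length(x) + length(y) <= 20L
  exact <- exact && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative,
                       exact = exact, correct = TRUE)
  )
  p <- wt$p.value
  if (is.nan(p)) p <- 1   # fully tied data carry no evidence either way
  list(u = unname(wt$statistic), p_value = p, exact = exact)
}

#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' Adjusts a vector of raw p-values by the step-down Sidak procedure: with
#' the m raw p-values sorted ascending, the i-th adjusted value is
#' `max_{j <= i} [1 - (1 - p_(j))^(m - j + 1)]`, clipped to 1, so adjusted
#' values are monotone non-decreasing in the sorted order. Results are
#' returned in the original order.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order as `p`.
#' @examples
#' holm_sidak_adjust(c(0.01, 0.04))  # 1 - 0.99^2 = 0.0199, then 0.04
#' @export
holm_sidak_adjust <- function(p) {
  if (!is.numeric(p) || length(p) == 0L || any(!is.finite(p)) ||
      any(p < 0 | p > 1))
    stop("`p` must be p-values in [0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj <- pmin(1, cummax(adj))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Pairwise Welch t-tests with Holm-Sidak correction
#'
#' Computes a Welch (unequal-variance) two-sample t-test for every pair of
#' groups and adjusts the resulting p-values with [holm_sidak_adjust()] —
#' the combination used for vessel dilation group comparisons. Degenerate
#' pairs (both groups with zero variance) are computed with a small variance
#' floor and flagged.
#'
#' @param values numeric vector of measurements.
#' @param groups group labels, same length as `values`; at least two groups
#'   with at least two values each.
#' @return data frame with one row per pair: `group1`, `group2`, `t`, `df`,
#'   `p_raw`, `p_adjusted`, `flagged`.
#' @export
holm_sidak <- function(values, groups) {
  if (length(values) != length(groups))
    stop("`values` and `groups` must have the same length", call. = FALSE)
  groups <- as.character(groups)
  g <- split(as.numeric(values), groups)
  if (length(g) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(lengths(g) < 2L))
    stop("each group needs at least two values", call. = FALSE)
  pairs <- utils::combn(names(g), 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- g[[pairs[1, k]]]; b <- g[[pairs[2, k]]]
    welch_t(a, b)
  })
  out <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    t = vapply(res, `[[`, numeric(1), "t"),
    df = vapply(res, `[[`, numeric(1), "df"),
    p_raw = vapply(res, `[[`, numeric(1), "p"),
    flagged = vapply(res, `[[`, logical(1), "flagged"),
    stringsAsFactors = FALSE
  )
  out$p_adjusted <- holm_sidak_adjust(out$p_raw)
  out[, c("group1", "group2", "t", "df", "p_raw", "p_adjusted", "flagged")]
}

## Welch t-test with a variance floor for degenerate (constant) groups.
welch_t <- function(a, b, var_floor = .Machine$double.eps) {
  va <- stats::var(a); vb <- stats::var(b)
  flagged <- va == 0 || vb == 0
  va <- max(va, var_floor); vb <- max(vb, var_floor)
  na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), flagged = flagged)
}
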