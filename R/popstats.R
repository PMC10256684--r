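#' Remove outliers by the median +/- 1.5 IQR rule
#'
#' Single-pass removal of values outside the closed interval
#' `[median - 1.5 * IQR, median + 1.5 * IQR]`, with quartiles computed by
#' linear interpolation (R quantile type 7). Boundary values are kept. The
#' rule is quartile-method-sensitive, hence the explicit choice.
#'
#' @param values Numeric vector of at least 4 values.
#' @return A list with `kept` (values inside the fence, original order),
#'   `removed_indices` (positions of removed values in the input) and
#'   `bounds` (the fence).
#' @examples
#' remove_outliers(c(1, 2, 3, 4, 100))
#' @export
remove_outliers <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 4) stop("need >= 4 values for outlier screening",
                               call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  bounds <- c(q[2] - 1.5 * iqr, q[2] + 1.5 * iqr)
  out <- values < bounds[1] | values > bounds[2]
  list(kept = values[!out], removed_indices = which(out), bounds = bounds)
}

#' Choose parametric vs nonparametric testing
#'
#' One-sample Kolmogorov-Smirnov test of the values against a normal
#' distribution with the sample mean and SD (parameters estimated from the
#' data, which makes the test conservative; kept because it mirrors the
#' common single-call usage). Returns `"parametric"` iff normality is not
#' rejected at `alpha`. Degenerate (zero-variance) input is `"nonparametric"`.
#'
#' @param values Numeric vector of at least 5 values.
#' @param alpha Rejection level (default 0.05).
#' @return `"parametric"` or `"nonparametric"`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  stopifnot(is.numeric(values))
  if (length(values) < 5) stop("need >= 5 values for the normality gate",
                               call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) return("nonparametric")
  p <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), s)$p.value)
  if (p > alpha) "parametric" else "nonparametric"
}

#' Two-sided Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (standard convention; this affects exact
#' small-n p-values). For n <= 25 remaining pairs with untied absolute
#' differences the exact signed-rank distribution is used; otherwise a normal
#' approximation with tie correction and continuity correction. If all
#' differences are zero, p = 1.
#'
#' @param x,y Paired numeric vectors of equal length >= 5.
#' @return Two-sided p-value.
#' @examples
#' paired_signrank(1:6, c(0.5, 1.2, 2.4, 3.1, 4.8, 5.2))
#' @export
paired_signrank <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5) stop("need >= 5 pairs", call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25 && !ties) {
    p <- 2 * min(stats::psignrank(w, n),
                 stats::psignrank(w - 1, n, lower.tail = FALSE))
    return(min(1, p))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (w - mu - 0.5 * sign(w - mu)) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Holm-Bonferroni adjustment of p-values
#'
#' Step-down Holm adjustment with monotonicity enforcement, mapped back to the
#' input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @examples
#' holm_correct(c(0.0002, 0.0002, 0.064))
#' @export
holm_correct <- function(p_values) {
  stopifnot(is.numeric(p_values))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "holm")
}

#' Kruskal-Wallis omnibus test with Dunn-Sidak pairwise comparisons
#'
#' Tie-corrected Kruskal-Wallis H across the groups, followed (regardless of
#' the omnibus outcome, so the caller can inspect everything) by Dunn's
#' pairwise z-tests on the pooled ranks with Sidak adjustment
#' `p_adj = 1 - (1 - p)^m` over the `m = k(k-1)/2` comparisons.
#'
#' @param groups A named (or unnamed) list of numeric vectors, each of length
#'   >= 3.
#' @return A list with `omnibus` (a one-row tibble: `statistic`, `df`,
#'   `p_value`) and `pairwise` (a tibble: `group1`, `group2`, `z`, `p_value`,
#'   `p_adjusted`).
#' @export
kruskal_dunnsidak <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) < 3)) {
    stop("each group needs >= 3 values", call. = FALSE)
  }
  if (is.null(names(groups))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  kw <- stats::kruskal.test(groups)
  omnibus <- tibble::tibble(statistic = unname(kw$statistic),
                            df = unname(kw$parameter),
                            p_value = kw$p.value)

  values <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, integer(1)))
  rk <- rank(values)
  N <- length(values)
  tie_tab <- table(rk)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  mean_ranks <- tapply(rk, g, mean)
  n_i <- tapply(rk, g, length)
  cmb <- utils::combn(names(groups), 2)
  m <- ncol(cmb)
  pairwise <- purrr::map_dfr(seq_len(m), function(j) {
    g1 <- cmb[1, j]; g2 <- cmb[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n_i[g1] + 1 / n_i[g2]))
    z <- unname((mean_ranks[g1] - mean_ranks[g2]) / se)
    p <- 2 * stats::pnorm(-abs(z))
    tibble::tibble(group1 = g1, group2 = g2, z = z, p_value = p,
                   p_adjusted = 1 - (1 - p)^m)
  })
  list(omnibus = omnibus, pairwise = pairwise)
}
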