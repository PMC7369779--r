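#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided p-value by the probability-mass rule: the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (the convention of
#' [stats::fisher.test()], on which this is built).
#'
#' @param tab 2x2 matrix of non-negative counts, or a length-4 vector
#'   `(a, b, c, d)` filled by row.
#' @return List with `statistic` (odds ratio estimate), `p_value`, `method`,
#'   `sidedness`.
#' @export
fisher_exact <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(tab, 2, 2, byrow = TRUE)
  stopifnot(dim(tab) == c(2, 2), all(tab >= 0), sum(tab) > 0)
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(statistic = unname(ft$estimate), p_value = ft$p.value,
       method = "fisher_exact", sidedness = "two-sided")
}

#' Mann-Whitney U test
#'
#' Exact p-value by enumeration of rank assignments when both samples are
#' tie-free and the smaller has at most 8 observations; otherwise the normal
#' approximation with continuity and tie correction. U is reported for the
#' first sample (number of (x, y) pairs with x > y, counting ties as 1/2).
#'
#' @param x,y Numeric samples (non-empty).
#' @param sidedness `"two-sided"` (default), `"greater"` or `"less"`.
#' @return List with `statistic` (U), `p_value`, `method`, `sidedness`.
#' @export
mann_whitney <- function(x, y, sidedness = c("two-sided", "greater", "less")) {
  sidedness <- match.arg(sidedness)
  stopifnot(length(x) > 0, length(y) > 0,
            all(is.finite(x)), all(is.finite(y)))
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && min(length(x), length(y)) <= 8
  alt <- switch(sidedness, "two-sided" = "two.sided",
                greater = "greater", less = "less")
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alt, exact = exact,
                       correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = min(1, wt$p.value),
       method = if (exact) "mann_whitney_exact" else "mann_whitney_normal",
       sidedness = sidedness)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted values in the input order, each in [0, 1], monotone along
#'   the sorted raw p-values.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = FALSE))
  stats::p.adjust(p, method = "BH")
}

#' Bonferroni adjustment over a fixed family of m tests
#'
#' @param p P-value(s) in [0, 1].
#' @param m Family size (>= 1).
#' @return `min(1, m * p)`, vectorized over `p`.
#' @export
bonferroni <- function(p, m) {
  stopifnot(all(p >= 0 & p <= 1), m >= 1, m == as.integer(m))
  pmin(1, m * p)
}
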