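#' Flag genes that would validate inside a random 11-gene panel
#'
#' The random-panel null repeatedly draws a panel of `panel_size` genes and
#' Bonferroni-adjusts their raw p-values within the draw. Because every draw
#' has the same fixed size, "adjusted p < alpha" inside a draw is exactly
#' "raw p < alpha / panel_size", so qualification reduces to a fixed per-gene
#' flag: raw p below `alpha / panel_size` AND absolute SLR at or above
#' `slr_threshold` (or strictly above with `strict = TRUE`).
#'
#' @param de_results Data.frame from [fit_de()] (validation cohort).
#' @param panel_size Panel size drawn per iteration (default 11).
#' @param alpha Within-draw significance level (default 0.05).
#' @param slr_threshold Absolute SLR cut-off (default 0.83).
#' @param strict If TRUE require |SLR| strictly above the threshold; default
#'   FALSE (at or above).
#' @return List with `flags` (logical per gene, named by gene id),
#'   `significant` and `high_slr` component flags, and `K` (number
#'   qualifying).
#' @export
flag_qualifying <- function(de_results, panel_size = 11L, alpha = 0.05,
                            slr_threshold = 0.83, strict = FALSE) {
  stopifnot(nrow(de_results) > 0, panel_size >= 1, slr_threshold >= 0)
  significant <- de_results$p_raw < alpha / panel_size
  high_slr <- if (strict) abs(de_results$slr) > slr_threshold
              else abs(de_results$slr) >= slr_threshold
  flags <- significant & high_slr
  names(flags) <- names(significant) <- names(high_slr) <- de_results$gene_id
  list(flags = flags, significant = significant, high_slr = high_slr,
       K = sum(flags))
}

#' Monte-Carlo probability that a random gene panel validates
#'
#' Draws `n_iter` panels of `panel_size` distinct genes uniformly from the
#' `N` genes and counts the iterations in which at least `min_hits` drawn
#' genes carry a qualifying flag (significant within-draw after Bonferroni
#' and with high absolute SLR, see [flag_qualifying()]). By default the two
#' conditions are required conjunctively of the same genes; with
#' `conjunctive = FALSE` an iteration instead succeeds when at least
#' `min_hits` drawn genes are significant and at least `min_hits` (possibly
#' different ones) have high SLR, in which case `significant` and `high_slr`
#' component flags must be supplied.
#'
#' @param flags Logical vector over the gene universe (from
#'   [flag_qualifying()]`$flags`), or the full list returned by
#'   [flag_qualifying()].
#' @param panel_size Genes drawn per iteration (default 11).
#' @param n_iter Iterations (default 10000).
#' @param min_hits Minimum qualifying genes for a success (default 2).
#' @param seed Integer seed for the single RNG stream of this call.
#' @param conjunctive Require both conditions of the same genes (default
#'   TRUE, the primary reading).
#' @return List of class `panel_null_estimate`: `probability` (= hits /
#'   n_iter), `hits`, `n_iter`, `mc_se` (binomial standard error),
#'   `closed_form` (exact hypergeometric counterpart, conjunctive mode only),
#'   `n_qualifying` (K), `universe` (N), `panel_size`, `min_hits`.
#' @export
estimate_probability <- function(flags, panel_size = 11L, n_iter = 10000L,
                                 min_hits = 2L, seed = 1L,
                                 conjunctive = TRUE) {
  comp <- NULL
  if (is.list(flags)) {
    comp <- flags
    flags <- comp$flags
  }
  stopifnot(is.logical(flags), n_iter >= 1, panel_size >= min_hits,
            min_hits >= 1)
  N <- length(flags)
  if (N < panel_size) stop("universe smaller than panel size")
  if (!conjunctive && is.null(comp)) {
    stop("non-conjunctive mode needs the component flags from flag_qualifying")
  }
  hits <- with_seed_opt(seed, {
    n_success <- 0L
    for (i in seq_len(n_iter)) {
      draw <- sample.int(N, panel_size)
      ok <- if (conjunctive) {
        sum(flags[draw]) >= min_hits
      } else {
        sum(comp$significant[draw]) >= min_hits &&
          sum(comp$high_slr[draw]) >= min_hits
      }
      if (ok) n_success <- n_success + 1L
    }
    n_success
  })
  p_hat <- hits / n_iter
  K <- sum(flags)
  structure(list(
    probability = p_hat,
    hits = hits,
    n_iter = n_iter,
    mc_se = sqrt(p_hat * (1 - p_hat) / n_iter),
    closed_form = if (conjunctive)
      closed_form_probability(N, K, panel_size, min_hits) else NA_real_,
    n_qualifying = K,
    universe = N,
    panel_size = panel_size,
    min_hits = min_hits
  ), class = "panel_null_estimate")
}

#' Exact probability that a random panel contains enough qualifying genes
#'
#' The number of qualifying genes in a uniformly drawn panel of `n` out of
#' `N` genes, of which `K` qualify, is hypergeometric; this returns the upper
#' tail `P(X >= min_hits)`. It is the exact counterpart of
#' [estimate_probability()] in conjunctive mode.
#'
#' @param N Universe size.
#' @param K Number of qualifying genes (0 <= K <= N).
#' @param n Panel size (n <= N).
#' @param min_hits Required qualifying genes.
#' @return Probability in [0, 1].
#' @export
closed_form_probability <- function(N, K, n, min_hits) {
  stopifnot(N >= 1, K >= 0, K <= N, n >= 1, n <= N, min_hits >= 1)
  stats::phyper(min_hits - 1, K, N - K, n, lower.tail = FALSE)
}

#' @export
print.panel_null_estimate <- function(x, ...) {
  cat(sprintf(
    "Random-panel null: %d/%d iterations validated (p_hat = %.3g, mc_se = %.2g)\n",
    x$hits, x$n_iter, x$probability, x$mc_se))
  cat(sprintf("  universe N = %d, qualifying K = %d, panel = %d, min hits = %d\n",
              x$universe, x$n_qualifying, x$panel_size, x$min_hits))
  if (!is.na(x$closed_form)) {
    cat(sprintf("  exact hypergeometric probability = %.3g\n", x$closed_form))
  }
  invisible(x)
}
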