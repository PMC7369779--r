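#' Efficiency-corrected relative quantity (Pfaffl)
#'
#' `Q = E ^ (Ct_calibrator - Ct_sample)`: one cycle of difference corresponds
#' to an E-fold abundance ratio. Replicate Ct values are arithmetic-averaged
#' before exponentiation.
#'
#' @param efficiency Amplification efficiency E in (1, 2] (2 = perfect
#'   doubling).
#' @param ct_calibrator Calibrator Ct value(s) (replicates averaged).
#' @param ct_sample Sample Ct value(s) (replicates averaged).
#' @return Positive relative quantity.
#' @export
relative_quantity <- function(efficiency, ct_calibrator, ct_sample) {
  if (efficiency <= 1 || efficiency > 2) stop("efficiency must be in (1, 2]")
  stopifnot(all(is.finite(ct_calibrator)), all(is.finite(ct_sample)))
  efficiency^(mean(ct_calibrator) - mean(ct_sample))
}

#' Normalization factor from reference-gene quantities
#'
#' Geometric mean of the relative quantities of the reference genes measured
#' in one sample.
#'
#' @param ref_q Positive numeric vector (one Q per reference gene).
#' @return Positive normalization factor.
#' @export
normalization_factor <- function(ref_q) {
  if (any(ref_q <= 0)) stop("reference quantities must be positive")
  geom_mean(ref_q)
}

#' Reference-gene stability (geNorm M)
#'
#' For each candidate reference j, `M_j` is the mean over the other
#' candidates k of the standard deviation across samples of
#' `log2(Q_j / Q_k)`. Lower M means more stable; the returned table is
#' sorted ascending (most stable first).
#'
#' @param q Positive numeric matrix of relative quantities, candidate genes x
#'   samples (rownames = gene ids).
#' @return Data.frame `gene_id`, `m` sorted by increasing `m`.
#' @export
reference_stability <- function(q) {
  stopifnot(is.matrix(q), nrow(q) >= 2, ncol(q) >= 2, all(q > 0))
  lq <- log2(q)
  g <- nrow(q)
  m <- vapply(seq_len(g), function(j) {
    mean(vapply(setdiff(seq_len(g), j), function(k) {
      stats::sd(lq[j, ] - lq[k, ])
    }, numeric(1)))
  }, numeric(1))
  out <- data.frame(gene_id = rownames(q), m = m, row.names = NULL)
  out[order(out$m), , drop = FALSE]
}

#' Normalized relative expression from a qPCR Ct table
#'
#' Full relative-quantification pass: duplicate Ct values are averaged per
#' sample x gene; each gene's relative quantity is computed against a
#' calibrator (the gene's mean Ct across all samples — the choice cancels
#' out of group comparisons); target quantities are divided by the geometric
#' mean of the reference-gene quantities of the same sample.
#'
#' @param ct_table Data.frame with columns `sample_id`, `gene_id`,
#'   `replicate`, `ct`, `efficiency`, `role` (`target`/`reference`), `group`
#'   (see [generate_qpcr()]).
#' @param calibrator Optional named numeric of calibrator Ct per gene;
#'   default is each gene's mean (replicate-averaged) Ct over samples.
#' @return Data.frame: `sample_id`, `gene_id`, `group`, `q`, `nf`,
#'   `normalized` (one row per sample x target gene).
#' @export
qpcr_normalize <- function(ct_table, calibrator = NULL) {
  need <- c("sample_id", "gene_id", "replicate", "ct", "efficiency",
            "role", "group")
  stopifnot(all(need %in% names(ct_table)))
  agg <- stats::aggregate(ct ~ sample_id + gene_id + efficiency + role + group,
                          data = ct_table, FUN = mean)
  if (is.null(calibrator)) {
    calibrator <- tapply(agg$ct, agg$gene_id, mean)
  }
  agg$q <- agg$efficiency^(calibrator[agg$gene_id] - agg$ct)
  refs <- agg[agg$role == "reference", ]
  if (nrow(refs) == 0) stop("no reference genes in table")
  nf <- tapply(refs$q, refs$sample_id, normalization_factor)
  targets <- agg[agg$role == "target", ]
  targets$nf <- as.numeric(nf[targets$sample_id])
  targets$normalized <- targets$q / targets$nf
  out <- targets[, c("sample_id", "gene_id", "group", "q", "nf", "normalized")]
  out[order(out$gene_id, out$sample_id), , drop = FALSE]
}

#' Compare normalized expression between the M0 and M1 groups
#'
#' Group medians plus a two-tailed Mann-Whitney U test.
#'
#' @param values Numeric vector of normalized expression values.
#' @param groups Matching vector of group labels (`M0`/`M1`).
#' @return List: `median_m0`, `median_m1`, `u`, `p_value`.
#' @export
compare_groups <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  x0 <- values[groups == "M0"]
  x1 <- values[groups == "M1"]
  if (length(x0) == 0 || length(x1) == 0) stop("both groups must be non-empty")
  mw <- mann_whitney(x0, x1, "two-sided")
  list(median_m0 = stats::median(x0), median_m1 = stats::median(x1),
       u = mw$statistic, p_value = mw$p_value)
}
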