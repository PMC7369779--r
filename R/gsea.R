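#' Filter a gene-set collection by size against a ranked universe
#'
#' Each set's membership is intersected with the universe of ranked genes;
#' sets whose intersected size lies within `[min_size, max_size]` are kept,
#' with their membership reduced to the intersection.
#'
#' @param sets Named list of member-gene vectors.
#' @param universe Character vector of ranked gene ids.
#' @param min_size,max_size Inclusive size bounds (defaults 10 and 600).
#' @return Filtered named list (intersected memberships).
#' @export
filter_gene_sets <- function(sets, universe, min_size = 10L, max_size = 600L) {
  if (min_size > max_size) stop("min_size exceeds max_size")
  trimmed <- lapply(sets, intersect, y = universe)
  keep <- lengths(trimmed) >= min_size & lengths(trimmed) <= max_size
  trimmed[keep]
}

# Core running-sum enrichment score from sorted hit positions.
# aw: |metric|^weight over the whole ranked list; d: miss decrement.
es_from_positions <- function(pos, aw, N) {
  k <- length(pos)
  d <- 1 / (N - k)
  w <- aw[pos]
  tot <- sum(w)
  w <- if (tot > 0) w / tot else rep(1 / k, k)
  cw <- cumsum(w)
  drop_before <- (pos - seq_len(k)) * d
  at_hit <- cw - drop_before          # running sum right after each hit
  before_hit <- c(0, cw[-k]) - drop_before # right before each hit
  hi <- max(at_hit)
  lo <- min(before_hit)
  if (hi >= -lo) {
    list(es = hi, peak = pos[which.max(at_hit)])
  } else {
    list(es = lo, peak = pos[which.min(before_hit)] - 1L)
  }
}

#' Weighted Kolmogorov-Smirnov enrichment score of a gene set
#'
#' Walks the ranked list top to bottom: member genes ("hits") increment the
#' running sum by `|metric|^weight` normalized over the set's hits, non-member
#' genes decrement it by `1 / (N - n_hits)`. The enrichment score is the
#' signed maximum deviation from zero; `weight = 0` gives the classical KS
#' statistic on the hit indicator.
#'
#' @param ranked Named numeric vector of ranking metrics (e.g. t-statistics),
#'   sorted in decreasing order, unique finite names.
#' @param members Character vector of set member gene ids.
#' @param weight Metric exponent (default 1).
#' @return List with `es` (in [-1, 1]) and `peak` (rank of the extreme).
#' @export
enrichment_score <- function(ranked, members, weight = 1) {
  stopifnot(!is.null(names(ranked)), !anyDuplicated(names(ranked)),
            all(is.finite(ranked)), !is.unsorted(rev(ranked)))
  pos <- sort(match(members, names(ranked)))
  pos <- pos[!is.na(pos)]
  N <- length(ranked)
  if (length(pos) == 0) stop("set has no members in the ranked universe")
  if (length(pos) == N) stop("set covers the whole universe")
  es_from_positions(pos, abs(ranked)^weight, N)
}

#' Permutation null for a gene set of a given size
#'
#' Scores `n_perm` uniformly drawn random gene sets of size `set_size` on the
#' fixed ranking ("random gene set permutations": genes are resampled, not
#' sample labels).
#'
#' @inheritParams enrichment_score
#' @param set_size Size of each random set.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return Numeric vector of `n_perm` enrichment scores.
#' @export
permutation_null <- function(ranked, set_size, n_perm = 10000L, seed = 1L,
                             weight = 1) {
  N <- length(ranked)
  stopifnot(set_size >= 1, set_size < N, n_perm >= 1)
  aw <- abs(ranked)^weight
  with_seed_opt(seed, {
    vapply(seq_len(n_perm), function(i) {
      es_from_positions(sort(sample.int(N, set_size)), aw, N)$es
    }, numeric(1))
  })
}

#' Score a gene-set collection: ES, NES, permutation p, BH-adjusted p
#'
#' For each (already size-filtered) set, computes the enrichment score, a
#' one-sided permutation p-value among same-sign permuted scores with +1
#' smoothing `(b + 1) / (m + 1)`, and the normalized enrichment score
#' NES = ES / mean(|permuted ES| of matching sign). Null distributions are
#' computed once per distinct set size and reused. BH adjustment is applied
#' across the collection.
#'
#' @inheritParams enrichment_score
#' @param sets Named list of member vectors (pre-filtered, see
#'   [filter_gene_sets()]).
#' @param n_perm Permutations per set size (default 10000).
#' @param seed Integer seed.
#' @return Data.frame: `set_id`, `size`, `es`, `nes`, `p_perm`, `p_adj`,
#'   `degenerate` (TRUE when no same-sign permutation existed).
#' @export
score_collection <- function(ranked, sets, n_perm = 10000L, seed = 1L,
                             weight = 1) {
  if (length(sets) == 0) {
    return(data.frame(set_id = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0),
                      p_perm = numeric(0), p_adj = numeric(0),
                      degenerate = logical(0)))
  }
  if (anyDuplicated(ranked)) {
    warning("ties in the ranking metric; ranks follow stable input order")
  }
  sizes <- vapply(sets, function(m) length(intersect(m, names(ranked))), 0L)
  nulls <- new.env(parent = emptyenv())
  null_for <- function(size) {
    key <- as.character(size)
    if (is.null(nulls[[key]])) {
      nulls[[key]] <- permutation_null(ranked, size, n_perm,
                                       seed = seed + size, weight = weight)
    }
    nulls[[key]]
  }
  rows <- lapply(names(sets), function(id) {
    es <- enrichment_score(ranked, sets[[id]], weight)$es
    perm <- null_for(sizes[[id]])
    if (es == 0) {
      return(data.frame(set_id = id, size = sizes[[id]], es = 0, nes = 0,
                        p_perm = 1, degenerate = FALSE))
    }
    same <- if (es > 0) perm[perm > 0] else perm[perm < 0]
    m <- length(same)
    degenerate <- m == 0
    if (degenerate) {
      p <- 1 / (n_perm + 1)
      nes <- es # no same-sign null mass to normalize against
      warning("no same-sign permutation for set ", id)
    } else {
      b <- sum(abs(same) >= abs(es))
      p <- (b + 1) / (m + 1)
      nes <- es / mean(abs(same))
    }
    data.frame(set_id = id, size = sizes[[id]], es = es, nes = nes,
               p_perm = p, degenerate = degenerate)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_fdr(out$p_perm)
  out[, c("set_id", "size", "es", "nes", "p_perm", "p_adj", "degenerate")]
}

#' Remove redundant gene sets by member-gene overlap
#'
#' Pairwise similarity is the Jaccard index of member-gene sets; whenever two
#' sets exceed the cutoff, the one with the larger p-value is dropped,
#' iterated until no retained pair exceeds the cutoff (equivalently: keep
#' sets in ascending p-value order, dropping any set too similar to an
#' already-kept one).
#'
#' @param results Data.frame of scored sets (needs `set_id` and the `p_col`
#'   column), typically the significant subset.
#' @param sets Named list of memberships covering `results$set_id`.
#' @param similarity_cutoff Jaccard cutoff in [0, 1] (default 0.7).
#' @param p_col Column used as the deciding p-value (default `"p_perm"`).
#' @return `results` reduced to the retained rows (original order).
#' @export
prune_redundant <- function(results, sets, similarity_cutoff = 0.7,
                            p_col = "p_perm") {
  if (similarity_cutoff < 0 || similarity_cutoff > 1) {
    stop("similarity cutoff must lie in [0, 1]")
  }
  stopifnot(all(results$set_id %in% names(sets)))
  if (nrow(results) <= 1) return(results)
  ord <- order(results[[p_col]], results$set_id)
  kept <- character(0)
  for (id in results$set_id[ord]) {
    mem <- sets[[id]]
    redundant <- any(vapply(kept, function(k) {
      jaccard(mem, sets[[k]]) > similarity_cutoff
    }, logical(1)))
    if (!redundant) kept <- c(kept, id)
  }
  results[results$set_id %in% kept, , drop = FALSE]
}

jaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

#' Cross-cohort concordance of significant gene sets
#'
#' Builds the 2x2 table (significant in A) x (significant in B) over the
#' sets analyzed in both cohorts and tests it with the Fisher exact test;
#' among the both-significant sets, counts those with a concordant NES sign.
#'
#' @param results_A,results_B Scored collections ([score_collection()]) for
#'   the two cohorts.
#' @param alpha Adjusted-p significance level (default 0.05).
#' @return List: `n_analyzed`, `n_sig_A`, `n_sig_B`, `n_both`,
#'   `n_both_concordant`, `fisher_p`, `contingency` (2x2 matrix),
#'   `both_ids`.
#' @export
concordance <- function(results_A, results_B, alpha = 0.05) {
  shared <- intersect(results_A$set_id, results_B$set_id)
  if (length(shared) == 0) stop("result lists share no analyzed gene sets")
  a <- results_A[match(shared, results_A$set_id), ]
  b <- results_B[match(shared, results_B$set_id), ]
  sig_a <- a$p_adj < alpha
  sig_b <- b$p_adj < alpha
  both <- sig_a & sig_b
  tab <- matrix(c(sum(both), sum(sig_a & !sig_b),
                  sum(!sig_a & sig_b), sum(!sig_a & !sig_b)),
                2, 2, byrow = TRUE,
                dimnames = list(sig_A = c("yes", "no"),
                                sig_B = c("yes", "no")))
  concordant <- both & sign(a$nes) == sign(b$nes)
  list(n_analyzed = length(shared),
       n_sig_A = sum(sig_a), n_sig_B = sum(sig_b),
       n_both = sum(both), n_both_concordant = sum(concordant),
       fisher_p = fisher_exact(tab)$p_value,
       contingency = tab,
       both_ids = shared[both])
}

#' Report top concordant gene sets
#'
#' Lists the sets significant in both cohorts whose discovery-cohort |NES|
#' exceeds `nes_cutoff`, after redundancy pruning on the discovery results,
#' sorted by discovery NES (most negative first).
#'
#' @inheritParams concordance
#' @param sets Named list of memberships (for pruning).
#' @param nes_cutoff Absolute discovery NES cutoff (default 2.0).
#' @param similarity_cutoff Jaccard cutoff for pruning (default 0.7).
#' @return Data.frame: `set_id`, `size`, `nes_A`, `p_adj_A`, `nes_B`,
#'   `p_adj_B`.
#' @export
report_top_sets <- function(results_A, results_B, sets, alpha = 0.05,
                            nes_cutoff = 2.0, similarity_cutoff = 0.7) {
  conc <- concordance(results_A, results_B, alpha)
  a <- results_A[results_A$set_id %in% conc$both_ids, , drop = FALSE]
  a <- prune_redundant(a, sets, similarity_cutoff)
  a <- a[abs(a$nes) > nes_cutoff, , drop = FALSE]
  b <- results_B[match(a$set_id, results_B$set_id), , drop = FALSE]
  out <- data.frame(set_id = a$set_id, size = a$size,
                    nes_A = a$nes, p_adj_A = a$p_adj,
                    nes_B = b$nes, p_adj_B = b$p_adj,
                    row.names = NULL)
  out[order(out$nes_A), , drop = FALSE]
}
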