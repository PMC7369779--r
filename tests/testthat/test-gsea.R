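ranked_fixture <- function(n, seed = 1) {
  withr::with_seed(seed, {
    sort(stats::setNames(rnorm(n), sprintf("g%04d", 1:n)), decreasing = TRUE)
  })
}

test_that("size filtering intersects with the universe before counting", {
  uni <- sprintf("g%04d", 1:700)
  sets <- list(tiny = uni[1:5], lo = uni[1:10], hi = uni[1:600],
               over = c(uni[1:600], "x1"),
               partial = c(uni[1:15], sprintf("z%02d", 1:5)))
  out <- filter_gene_sets(sets, uni, 10, 600)
  expect_setequal(names(out), c("lo", "hi", "over", "partial"))
  expect_length(out$partial, 15)
  expect_length(out$over, 600) # the off-universe member does not count
  expect_length(filter_gene_sets(list(), uni), 0)
  expect_error(filter_gene_sets(sets, uni, 20, 10), "exceeds")
})

test_that("enrichment score hits its extremes on single-hit toys", {
  r <- sort(stats::setNames(c(3, 2, 1, 0.5), sprintf("g%d", 1:4)),
            decreasing = TRUE)
  expect_equal(enrichment_score(r, "g1")$es, 1)
  # single hit at the bottom: the running sum falls to -(N-1)/(N-1) = -1
  # just before the hit
  bottom <- enrichment_score(r, "g4")
  expect_equal(bottom$es, -1)
  expect_error(enrichment_score(r, sprintf("g%d", 1:4)), "whole universe")
  expect_error(enrichment_score(r, "absent"), "no members")
})

test_that("position-based score equals the naive running-sum walk", {
  for (seed in 1:50) {
    r <- ranked_fixture(80, seed)
    members <- withr::with_seed(seed + 100, sample(names(r), sample(3:20, 1)))
    for (w in c(0, 1, 2)) {
      expect_equal(enrichment_score(r, members, weight = w)$es,
                   es_naive(r, members, weight = w), tolerance = 1e-12)
    }
  }
})

test_that("weight 0 reduces to the classical KS statistic on hit positions", {
  for (seed in 1:50) {
    N <- 60
    r <- ranked_fixture(N, seed)
    members <- withr::with_seed(seed, sample(names(r), 8))
    es <- enrichment_score(r, members, weight = 0)$es
    pos <- which(names(r) %in% members)
    ks <- suppressWarnings(
      stats::ks.test(pos, setdiff(seq_len(N), pos))$statistic)
    expect_equal(abs(es), unname(ks), tolerance = 1e-10)
  }
})

test_that("weighted score agrees with the established GSEA reference", {
  for (seed in 1:20) {
    r <- ranked_fixture(100, seed)
    members <- withr::with_seed(seed + 7, sample(names(r), 12))
    mine <- enrichment_score(r, members, weight = 1)$es
    ref <- fgsea::calcGseaStat(r, selectedStats = which(names(r) %in% members),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("score negation: flipping and reversing the metric negates es", {
  for (seed in 1:20) {
    r <- ranked_fixture(50, seed)
    members <- withr::with_seed(seed, sample(names(r), 6))
    flipped <- sort(-r, decreasing = TRUE)
    expect_equal(enrichment_score(flipped, members)$es,
                 -enrichment_score(r, members)$es, tolerance = 1e-12)
  }
})

test_that("permutation null is seeded, sized, and contract-shaped", {
  r <- ranked_fixture(200, 3)
  expect_length(permutation_null(r, 10, n_perm = 1, seed = 1), 1)
  a <- permutation_null(r, 15, n_perm = 50, seed = 9)
  b <- permutation_null(r, 15, n_perm = 50, seed = 9)
  expect_identical(a, b)
  expect_true(all(abs(a) <= 1))
})

test_that("collection scoring: smoothing floor, NES sign, BH monotonicity", {
  r <- ranked_fixture(300, 11)
  sets <- generate_gene_sets(15, c(10, 40), names(r), seed = 2)
  res <- score_collection(r, sets, n_perm = 200, seed = 4)
  expect_equal(nrow(res), 15)
  expect_true(all(res$p_perm >= 1 / 201))
  expect_true(all(sign(res$nes) == sign(res$es) | res$es == 0))
  expect_true(all(res$p_adj >= res$p_perm))
  ord <- order(res$p_perm)
  expect_false(is.unsorted(res$p_adj[ord]))
})

test_that("a planted M0-up-shifted set recovers a significant negative NES", {
  cfg <- sim_config(n_genes = 1500, planted_slr = numeric(0),
                    planted_set_shift = stats::setNames(
                      rep(0.5, 60), sprintf("G%04d", 1400:1459)),
                    seed = 19)
  b <- generate_cohort(cfg, "B")
  de <- fit_de(b$expr, b$annotation)
  r <- sort(stats::setNames(de$t_stat, de$gene_id), decreasing = TRUE)
  planted <- sprintf("G%04d", 1400:1459)
  sets <- c(list(planted = planted),
            generate_gene_sets(10, c(20, 80), rownames(b$expr), seed = 8))
  res <- score_collection(r, sets, n_perm = 500, seed = 13)
  row <- res[res$set_id == "planted", ]
  expect_lt(row$nes, 0)
  expect_lt(row$p_adj, 0.05)
})

test_that("redundancy pruning keeps the lower-p member of similar pairs", {
  sets <- list(A = letters[1:10], B = letters[1:10], C = letters[11:20])
  res <- data.frame(set_id = c("A", "B", "C"), p_perm = c(0.01, 0.02, 0.5))
  out <- prune_redundant(res, sets)
  expect_setequal(out$set_id, c("A", "C"))

  # disjoint sets all retained
  disj <- list(A = letters[1:5], B = letters[6:10], C = letters[11:15])
  expect_equal(nrow(prune_redundant(res, disj)), 3)

  # chain A~B, B~C similar, A~C dissimilar, p(A)<p(B)<p(C): B drops, C stays
  chain <- list(A = as.character(1:10), B = as.character(3:12),
                C = as.character(c(5:14)))
  stopifnot(length(intersect(chain$A, chain$B)) / length(union(chain$A, chain$B)) > 0.6)
  res2 <- data.frame(set_id = c("A", "B", "C"), p_perm = c(0.01, 0.02, 0.03))
  out2 <- prune_redundant(res2, chain, similarity_cutoff = 0.6)
  expect_setequal(out2$set_id, c("A", "C"))
  expect_error(prune_redundant(res2, chain, similarity_cutoff = 7),
               "\\[0, 1\\]")
})

test_that("cross-cohort concordance builds the right table and Fisher p", {
  ids <- sprintf("s%d", 1:10)
  mk <- function(sig, nes) {
    data.frame(set_id = ids, size = 20,
               es = nes / 2, nes = nes,
               p_perm = ifelse(sig, 0.001, 0.5),
               p_adj = ifelse(sig, 0.01, 0.8))
  }
  A <- mk(ids %in% c("s1", "s2", "s3"),
          ifelse(ids %in% c("s1", "s2"), -2, 2))
  B <- mk(ids %in% c("s1", "s2", "s4"),
          ifelse(ids == "s1", -1.7, ifelse(ids == "s2", 1.9, 1.5)))
  cc <- concordance(A, B)
  expect_equal(cc$n_both, 2)
  expect_equal(cc$n_both_concordant, 1)
  expect_equal(as.vector(t(cc$contingency)), c(2, 1, 1, 6))
  expect_equal(cc$fisher_p,
               fisher_enum_p(matrix(c(2, 1, 1, 6), 2, byrow = TRUE)),
               tolerance = 1e-10)

  none <- mk(rep(FALSE, 10), rep(1, 10))
  expect_equal(concordance(none, B)$n_both, 0)
  same <- mk(ids %in% c("s1", "s5"), rep(-2, 10))
  cc2 <- concordance(same, same)
  expect_equal(cc2$n_both, 2)
  expect_equal(cc2$n_both_concordant, 2)
})

test_that("top-set report filters on both-significance and discovery NES", {
  ids <- sprintf("s%d", 1:6)
  mk <- function(nes, p_adj) {
    data.frame(set_id = ids, size = 15, es = nes / 2, nes = nes,
               p_perm = p_adj / 10, p_adj = p_adj)
  }
  sets <- stats::setNames(lapply(1:6, function(i) as.character(i * 10 + 1:10)),
                          ids)
  A <- mk(c(-2.5, -2.2, -1.5, 2.6, 1.0, -3.0),
          c(0.01, 0.01, 0.01, 0.01, 0.5, 0.01))
  B <- mk(c(-1.8, -2.0, -1.2, 1.7, 1.1, 2.0),
          c(0.02, 0.02, 0.02, 0.03, 0.6, 0.04))
  top <- report_top_sets(A, B, sets, nes_cutoff = 2.0)
  # s6 is discordant in sign but still both-significant with |NES_A| > 2
  expect_setequal(top$set_id, c("s1", "s2", "s4", "s6"))
  expect_false(is.unsorted(top$nes_A))
  expect_equal(nrow(report_top_sets(A, B, sets, nes_cutoff = Inf)), 0)
  all_sig <- report_top_sets(A, B, sets, nes_cutoff = 0)
  expect_setequal(all_sig$set_id, c("s1", "s2", "s3", "s4", "s6"))
})
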