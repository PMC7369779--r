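test_that("Pfaffl relative quantity follows the efficiency model", {
  expect_equal(relative_quantity(2, 10, 10), 1)
  expect_equal(relative_quantity(2, 10, 7), 8)
  expect_equal(relative_quantity(1.9, 5, 4), 1.9)
  # replicates averaged before exponentiation
  expect_equal(relative_quantity(2, c(10, 12), c(8, 8)), 2^3)
  expect_error(relative_quantity(1, 5, 4), "efficiency")
})

test_that("normalization factor is the geometric mean and is homogeneous", {
  expect_equal(normalization_factor(c(1, 1, 1)), 1)
  expect_equal(normalization_factor(c(2, 4, 8)), 4)
  q <- c(0.5, 3, 7)
  expect_equal(normalization_factor(3 * q), 3 * normalization_factor(q),
               tolerance = 1e-12)
  expect_error(normalization_factor(c(1, 0, 2)), "positive")
})

test_that("geNorm M is zero for proportional references and flags unstable ones", {
  q <- rbind(A = c(1, 2, 4), B = c(2, 4, 8))
  rownames(q) <- c("A", "B")
  st <- reference_stability(q)
  expect_equal(st$m, c(0, 0))

  hand <- rbind(A = c(1, 2, 4), B = c(2, 4, 8), C = c(1, 1, 16))
  st3 <- reference_stability(hand)
  # pairwise log2-ratio SDs computed by hand: sd(A/B) = 0, sd(A/C) = sd(B/C)
  # = sd of (0,1,-2) = sqrt(7/3)
  s <- stats::sd(c(0, 1, -2))
  expect_equal(st3$m[st3$gene_id == "A"], s / 2, tolerance = 1e-12)
  expect_equal(st3$m[st3$gene_id == "B"], s / 2, tolerance = 1e-12)
  expect_equal(st3$m[st3$gene_id == "C"], s, tolerance = 1e-12)
  expect_equal(st3$gene_id[3], "C") # least stable ranks last

  # rescaling one gene's quantities leaves the ranking unchanged
  scaled <- hand; scaled["C", ] <- hand["C", ] * 100
  expect_equal(reference_stability(scaled)$m, st3$m, tolerance = 1e-12)
  expect_error(reference_stability(hand[1, , drop = FALSE]))
})

test_that("with E = 2 everywhere normalization equals classical 2^-ddCt", {
  tb <- generate_qpcr(n_m0 = 6, n_m1 = 4, efficiency_range = c(2, 2),
                      target_effect = c(IGFBP3 = 0.7), seed = 14)
  norm <- qpcr_normalize(tb)
  agg <- stats::aggregate(ct ~ sample_id + gene_id + role, tb, mean)
  refs <- agg[agg$role == "reference", ]
  tgt <- agg[agg$role == "target", ]
  # classical quantity: 2^-(dCt_target - dCt_refmean) with the same
  # calibrator convention (per-gene mean Ct)
  cal <- tapply(agg$ct, agg$gene_id, mean)
  dct_t <- tgt$ct - cal[tgt$gene_id]
  ref_d <- tapply(refs$ct - cal[refs$gene_id], refs$sample_id, mean)
  classical <- 2^-(dct_t - ref_d[tgt$sample_id])
  expect_equal(norm$normalized[match(tgt$sample_id, norm$sample_id)],
               unname(classical), tolerance = 1e-10)
})

test_that("calibrator choice rescales all samples alike, leaving comparisons invariant", {
  tb <- generate_qpcr(n_m0 = 5, n_m1 = 5, seed = 23)
  base <- qpcr_normalize(tb)
  genes <- unique(tb$gene_id)
  alt <- qpcr_normalize(tb, calibrator = stats::setNames(
    rep(20, length(genes)), genes))
  ratio <- alt$normalized / base$normalized
  expect_lt(diff(range(ratio)), 1e-10) # one common factor per target gene
  cmp_base <- compare_groups(base$normalized, base$group)
  cmp_alt <- compare_groups(alt$normalized, alt$group)
  expect_equal(cmp_alt$p_value, cmp_base$p_value, tolerance = 1e-12)
  expect_equal(cmp_alt$median_m1 / cmp_alt$median_m0,
               cmp_base$median_m1 / cmp_base$median_m0, tolerance = 1e-10)
})

test_that("group comparison returns medians and the enumeration p", {
  same <- c(4, 9, 1, 7)
  res <- compare_groups(c(same, same), rep(c("M0", "M1"), each = 4))
  expect_equal(res$p_value, 1, tolerance = 1e-9)

  res2 <- compare_groups(c(1, 2, 3, 4), c("M0", "M0", "M1", "M1"))
  expect_equal(res2$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(res2$median_m0, 1.5)
  expect_equal(res2$median_m1, 3.5)
  expect_error(compare_groups(1:3, rep("M0", 3)), "non-empty")
})

test_that("null target effect gives near-uniform group-comparison p-values", {
  ps <- vapply(1:40, function(s) {
    tb <- generate_qpcr(n_m0 = 54, n_m1 = 9, target_effect = c(IGFBP3 = 0),
                        seed = 1000 + s)
    norm <- qpcr_normalize(tb)
    compare_groups(norm$normalized, norm$group)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
  expect_gt(mean(ps > 0.05), 0.8)
})
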