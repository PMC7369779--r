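test_that("default cohort A has the study's dimensions and group sizes", {
  cfg <- sim_config(seed = 11)
  a <- generate_cohort(cfg, "A")
  expect_equal(dim(a$expr), c(12001L, 71L))
  expect_equal(sum(a$annotation$group == "M1"), 15L)
  expect_equal(sum(a$annotation$group == "M0"), 56L)
  expect_equal(as.vector(table(a$annotation$batch)[c("U133A", "U133Plus2")]),
               c(44L, 27L))
  expect_true(all(is.finite(a$expr)))
  expect_false(anyDuplicated(rownames(a$expr)) > 0)

  b <- generate_cohort(cfg, "B")
  expect_equal(dim(b$expr), c(12001L, 52L))
  expect_equal(sum(b$annotation$group == "M1"), 21L)
})

test_that("zero noise and no planted effects collapse each batch to a constant", {
  cfg <- sim_config(n_genes = 50, noise_sd = 0, batch_sd = 0.5,
                    planted_slr = numeric(0), seed = 4)
  a <- generate_cohort(cfg, "A")
  for (b in unique(a$annotation$batch)) {
    sub <- a$expr[, a$annotation$batch == b, drop = FALSE]
    expect_equal(apply(sub, 1, stats::sd), rep(0, nrow(sub)),
                 ignore_attr = TRUE)
  }
})

test_that("cohort generation is seed-deterministic", {
  cfg <- sim_config(n_genes = 100, seed = 7)
  expect_identical(generate_cohort(cfg, "A"), generate_cohort(cfg, "A"))
  cfg2 <- sim_config(n_genes = 100, seed = 8)
  expect_false(identical(generate_cohort(cfg, "A")$expr,
                         generate_cohort(cfg2, "A")$expr))
  expect_error(generate_cohort(cfg, "Z"), "unknown cohort")
})

test_that("planted SLR shifts M1 and planted set shift raises M0", {
  cfg <- sim_config(n_genes = 200, noise_sd = 0, batch_sd = 0,
                    planted_slr = c(G0005 = 0.83),
                    planted_set_shift = c(G0100 = 0.5), seed = 5)
  b <- generate_cohort(cfg, "B")
  m1 <- b$annotation$group == "M1"
  expect_equal(mean(b$expr["G0005", m1]) - mean(b$expr["G0005", !m1]), 0.83)
  expect_equal(mean(b$expr["G0100", m1]) - mean(b$expr["G0100", !m1]), -0.5)
})

test_that("generated gene sets respect size bounds and planting", {
  uni <- sprintf("G%04d", 1:800)
  sets <- generate_gene_sets(50, c(10, 600), uni, seed = 3)
  expect_length(sets, 50)
  expect_true(all(lengths(sets) >= 10 & lengths(sets) <= 600))
  expect_true(all(unlist(sets) %in% uni))
  expect_true(all(vapply(sets, anyDuplicated, 0L) == 0))

  expect_length(generate_gene_sets(0, c(10, 20), uni), 0)
  expect_error(generate_gene_sets(5, c(10, 1000), uni), "universe")

  planted <- uni[700:760]
  sets2 <- generate_gene_sets(10, c(10, 100), uni, planted_ids = "S001",
                              planted_members = planted, seed = 6)
  expect_true(all(planted %in% sets2$S001))
})

test_that("qPCR generator honours the duplicate design and jitter contract", {
  tb <- generate_qpcr(n_m0 = 5, n_m1 = 3, jitter_sd = 0, seed = 2)
  per <- table(tb$sample_id, tb$gene_id)
  expect_true(all(per == 2))
  sp <- split(tb$ct, interaction(tb$sample_id, tb$gene_id))
  expect_true(all(vapply(sp, function(v) diff(range(v)), 0) == 0))
  expect_true(all(tb$efficiency >= 1 & tb$efficiency <= 2))
  expect_error(generate_qpcr(efficiency_range = c(0.9, 2)), "\\[1, 2\\]")
  expect_identical(generate_qpcr(seed = 9), generate_qpcr(seed = 9))
})

test_that("qPCR planted group effect survives normalization", {
  # deterministic table: zero jitter, zero biological noise, heavy loading
  # differences that normalization must cancel
  tb <- generate_qpcr(n_m0 = 8, n_m1 = 8, target_effect = c(IGFBP3 = 1),
                      abundance_sd = 0, loading_sd = 1, jitter_sd = 0,
                      seed = 12)
  norm <- qpcr_normalize(tb)
  med <- tapply(norm$normalized, norm$group, stats::median)
  expect_equal(unname(log2(med["M1"] / med["M0"])), 1, tolerance = 1e-10)
})

test_that("null cohort yields uniform raw p-values", {
  cfg <- sim_config(planted_slr = numeric(0), seed = 21)
  b <- generate_cohort(cfg, "B")
  de <- fit_de(b$expr, b$annotation)
  expect_true(abs(mean(de$p_raw < 0.05) - 0.05) <= 0.01)
})

test_that("a constant shift of one batch leaves SLR estimates unchanged", {
  cfg <- sim_config(n_genes = 300, seed = 31)
  a <- generate_cohort(cfg, "A")
  de1 <- fit_de(a$expr, a$annotation)
  shifted <- a$expr
  shifted[, a$annotation$batch == "U133A"] <-
    shifted[, a$annotation$batch == "U133A"] + 3.7
  de2 <- fit_de(shifted, a$annotation)
  expect_equal(de2$slr, de1$slr, tolerance = 1e-10)
  expect_equal(de2$t_stat, de1$t_stat, tolerance = 1e-10)
})

test_that("cohort tables round-trip through the TSV writers", {
  cfg <- sim_config(n_genes = 30, seed = 41)
  a <- generate_cohort(cfg, "A")
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_expression(a$expr, f1)
  write_annotation(a$annotation, f2)
  expect_equal(read_expression(f1), a$expr, tolerance = 1e-12)
  expect_equal(read_annotation(f2), a$annotation)

  sets <- generate_gene_sets(5, c(3, 10), rownames(a$expr), seed = 1)
  f3 <- tempfile(fileext = ".gmt")
  write_gmt(sets, f3)
  back <- read_gmt(f3)
  expect_equal(unname(lapply(back, identity)), unname(sets))
  expect_equal(names(back), names(sets))
})
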