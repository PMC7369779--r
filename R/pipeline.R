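#' Analysis configuration for the full two-cohort workflow
#'
#' Bundles every stage's parameters and seeds. Defaults reproduce the study
#' conditions: BH discovery at alpha 0.05, an 11-gene Bonferroni validation
#' panel, the 10,000-iteration random-panel null with |SLR| >= 0.83,
#' pre-ranked GSEA with set sizes 10-600, 10,000 gene-set permutations,
#' Jaccard redundancy cutoff 0.7 and an |NES| > 2 report threshold.
#'
#' @param sim A [sim_config()] describing the synthetic cohorts.
#' @param alpha Significance level used by every stage.
#' @param panel_size Validation panel size (default 11).
#' @param slr_threshold Absolute SLR threshold of the panel null (default
#'   0.83).
#' @param n_iter Random-panel iterations (default 10000).
#' @param moderation Empirical-Bayes variance moderation in [fit_de()]
#'   (default FALSE).
#' @param gsea List of GSEA parameters: `n_sets`, `min_size`, `max_size`,
#'   `n_perm`, `similarity_cutoff`, `nes_report_cutoff`, `planted_sets`
#'   (number of planted immune-like sets), `planted_set_size`,
#'   `planted_shift` (log2 M0 up-shift per member gene).
#' @param qpcr List of qPCR stage parameters: `n_m0`, `n_m1`, `target_effect`
#'   (log2 shift of the target in M1), `jitter_sd`.
#' @param seeds Named list of per-stage seeds (`panel_null`, `gsea_A`,
#'   `gsea_B`, `gene_sets`, `qpcr`).
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(sim = sim_config(),
                            alpha = 0.05,
                            panel_size = 11L,
                            slr_threshold = 0.83,
                            n_iter = 10000L,
                            moderation = FALSE,
                            gsea = list(n_sets = 60L, min_size = 10L,
                                        max_size = 600L, n_perm = 10000L,
                                        similarity_cutoff = 0.7,
                                        nes_report_cutoff = 2.0,
                                        planted_sets = 2L,
                                        planted_set_size = 60L,
                                        planted_shift = 0.5),
                            qpcr = list(n_m0 = 54L, n_m1 = 9L,
                                        target_effect = 0,
                                        jitter_sd = 0.1),
                            seeds = list(panel_null = 101L, gsea_A = 201L,
                                         gsea_B = 202L, gene_sets = 301L,
                                         qpcr = 401L)) {
  stopifnot(inherits(sim, "sim_config"), alpha > 0, alpha < 1,
            panel_size >= 1, slr_threshold >= 0, n_iter >= 1)
  structure(list(sim = sim, alpha = alpha, panel_size = panel_size,
                 slr_threshold = slr_threshold, n_iter = n_iter,
                 moderation = moderation, gsea = gsea, qpcr = qpcr,
                 seeds = seeds),
            class = "analysis_config")
}

#' Save / load an analysis configuration (JSON)
#'
#' @param config An [analysis_config()].
#' @param path File path.
#' @export
save_config <- function(config, path) {
  raw <- unclass(config)
  raw$sim <- unclass(raw$sim)
  # named vectors must serialize as JSON objects, not bare arrays
  raw$sim$planted_slr <- as.list(raw$sim$planted_slr)
  raw$sim$planted_set_shift <- as.list(raw$sim$planted_set_shift)
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- raw$sim
  designs <- lapply(sim$designs, function(d) as.data.frame(d))
  cfg <- sim_config(
    n_genes = sim$n_genes, designs = designs,
    baseline_range = sim$baseline_range, noise_sd = sim$noise_sd,
    batch_sd = sim$batch_sd,
    planted_slr = unlist(sim$planted_slr),
    planted_set_shift = if (length(sim$planted_set_shift))
      unlist(sim$planted_set_shift) else numeric(0),
    seed = sim$seed)
  analysis_config(sim = cfg, alpha = raw$alpha,
                  panel_size = raw$panel_size,
                  slr_threshold = raw$slr_threshold, n_iter = raw$n_iter,
                  moderation = raw$moderation, gsea = raw$gsea,
                  qpcr = raw$qpcr, seeds = raw$seeds)
}

#' Run the full discovery-validation workflow on synthetic cohorts
#'
#' Executes the study's stage order: simulate cohorts A and B sharing one
#' gene-level truth; batch-aware differential expression on A with BH
#' adjustment; selection of the significant genes as the validation panel
#' (capped at `panel_size`, most significant first); Bonferroni validation on
#' cohort B; the Monte-Carlo random-panel null with its exact hypergeometric
#' counterpart; pre-ranked GSEA on both cohorts (planted immune-like sets are
#' up-shifted in M0 so recover negative NES for the M1-vs-M0 ranking);
#' cross-cohort concordance; and the qPCR relative-quantification stage.
#'
#' @param config An [analysis_config()].
#' @param out_dir Optional directory; when given, every stage's table is
#'   written there as TSV plus a `summary.json`.
#' @param quiet Suppress per-stage messages (default TRUE).
#' @return List with elements `cohort_A`, `cohort_B`, `de_A`, `de_B`,
#'   `panel`, `validation`, `panel_null`, `gene_sets`, `gsea_A`, `gsea_B`,
#'   `concordance`, `top_sets`, `qpcr`, `summary`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "analysis_config"))
  say <- function(...) if (!quiet) message(...)

  say("simulating cohorts")
  gene_ids <- gene_ids_for(config$sim$n_genes)
  gs_cfg <- config$gsea
  planted_ids <- if (gs_cfg$planted_sets > 0)
    sprintf("S%03d", seq_len(gs_cfg$planted_sets)) else character(0)
  planted_members <- if (gs_cfg$planted_sets > 0) {
    # immune-like genes: drawn from the tail of the gene list, away from the
    # planted-SLR genes at its head
    tail(gene_ids, gs_cfg$planted_set_size)
  } else character(0)
  sim <- config$sim
  if (length(planted_members)) {
    shift <- stats::setNames(rep(gs_cfg$planted_shift,
                                 length(planted_members)), planted_members)
    sim <- sim_config(n_genes = sim$n_genes, designs = sim$designs,
                      baseline_range = sim$baseline_range,
                      noise_sd = sim$noise_sd, batch_sd = sim$batch_sd,
                      planted_slr = sim$planted_slr,
                      planted_set_shift = shift, seed = sim$seed)
  }
  cohort_A <- generate_cohort(sim, "A")
  cohort_B <- generate_cohort(sim, "B")

  say("differential expression, discovery cohort A (BH)")
  de_A <- fit_de(cohort_A$expr, cohort_A$annotation,
                 moderation = config$moderation, adjustment = "BH",
                 alpha = config$alpha)
  sig_A <- de_A[!is.na(de_A$p_adj) & de_A$p_adj < config$alpha, ]
  sig_A <- sig_A[order(sig_A$p_raw), ]
  panel <- utils::head(sig_A$gene_id, config$panel_size)

  say("differential expression + panel validation, cohort B (Bonferroni)")
  de_B <- fit_de(cohort_B$expr, cohort_B$annotation,
                 moderation = config$moderation, adjustment = "BH",
                 alpha = config$alpha)
  validation <- validate_panel(panel, de_B, config$alpha)

  say("random-panel Monte-Carlo null")
  flags <- flag_qualifying(de_B, panel_size = config$panel_size,
                           alpha = config$alpha,
                           slr_threshold = config$slr_threshold)
  panel_null <- estimate_probability(flags, panel_size = config$panel_size,
                                     n_iter = config$n_iter,
                                     min_hits = 2L,
                                     seed = config$seeds$panel_null)

  say("gene set enrichment, both cohorts")
  sets <- generate_gene_sets(gs_cfg$n_sets,
                             c(gs_cfg$min_size, gs_cfg$max_size),
                             universe = gene_ids,
                             planted_ids = planted_ids,
                             planted_members = planted_members,
                             seed = config$seeds$gene_sets)
  sets_f <- filter_gene_sets(sets, gene_ids, gs_cfg$min_size, gs_cfg$max_size)
  rank_of <- function(de) {
    sort(stats::setNames(de$t_stat, de$gene_id), decreasing = TRUE)
  }
  gsea_A <- score_collection(rank_of(de_A), sets_f, n_perm = gs_cfg$n_perm,
                             seed = config$seeds$gsea_A)
  gsea_B <- score_collection(rank_of(de_B), sets_f, n_perm = gs_cfg$n_perm,
                             seed = config$seeds$gsea_B)
  conc <- concordance(gsea_A, gsea_B, config$alpha)
  top_sets <- report_top_sets(gsea_A, gsea_B, sets_f, alpha = config$alpha,
                              nes_cutoff = gs_cfg$nes_report_cutoff,
                              similarity_cutoff = gs_cfg$similarity_cutoff)

  say("qPCR relative quantification")
  qp_cfg <- config$qpcr
  ct_table <- generate_qpcr(n_m0 = qp_cfg$n_m0, n_m1 = qp_cfg$n_m1,
                            target_effect = c(IGFBP3 = qp_cfg$target_effect),
                            jitter_sd = qp_cfg$jitter_sd,
                            seed = config$seeds$qpcr)
  qpcr_norm <- qpcr_normalize(ct_table)
  qpcr_cmp <- compare_groups(qpcr_norm$normalized, qpcr_norm$group)

  summary <- list(
    n_genes = config$sim$n_genes,
    n_significant_A = nrow(sig_A),
    panel = panel,
    validated_genes = validation$gene_id[validation$validated],
    panel_null_probability = panel_null$probability,
    panel_null_closed_form = panel_null$closed_form,
    n_qualifying = panel_null$n_qualifying,
    n_sets_significant_A = conc$n_sig_A,
    n_sets_significant_B = conc$n_sig_B,
    n_sets_both_concordant = conc$n_both_concordant,
    concordance_fisher_p = conc$fisher_p,
    qpcr_median_m0 = qpcr_cmp$median_m0,
    qpcr_median_m1 = qpcr_cmp$median_m1,
    qpcr_p = qpcr_cmp$p_value
  )

  result <- list(cohort_A = cohort_A, cohort_B = cohort_B, de_A = de_A,
                 de_B = de_B, panel = panel, validation = validation,
                 panel_null = panel_null, gene_sets = sets_f,
                 gsea_A = gsea_A, gsea_B = gsea_B, concordance = conc,
                 top_sets = top_sets, qpcr = qpcr_norm, summary = summary)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_expression(cohort_A$expr, file.path(out_dir, "expr_A.tsv"))
    write_expression(cohort_B$expr, file.path(out_dir, "expr_B.tsv"))
    write_annotation(rbind(cohort_A$annotation, cohort_B$annotation),
                     file.path(out_dir, "annotation.tsv"))
    write_table_tsv(format_de_table(de_A), file.path(out_dir, "de_A.tsv"))
    write_table_tsv(format_de_table(de_B), file.path(out_dir, "de_B.tsv"))
    write_table_tsv(validation, file.path(out_dir, "panel_validation.tsv"))
    write_table_tsv(data.frame(
      probability = panel_null$probability, hits = panel_null$hits,
      n_iter = panel_null$n_iter, mc_se = panel_null$mc_se,
      closed_form = panel_null$closed_form,
      n_qualifying = panel_null$n_qualifying,
      universe = panel_null$universe),
      file.path(out_dir, "panel_null.tsv"))
    write_gmt(sets_f, file.path(out_dir, "gene_sets.gmt"))
    write_table_tsv(gsea_A, file.path(out_dir, "gsea_A.tsv"))
    write_table_tsv(gsea_B, file.path(out_dir, "gsea_B.tsv"))
    write_table_tsv(top_sets, file.path(out_dir, "gsea_top_sets.tsv"))
    write_table_tsv(qpcr_norm, file.path(out_dir, "qpcr_normalized.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(result)
}

#' Format a differential-expression table at report precision
#'
#' SLR to 2 decimals, fold change to 2 decimals, p-values to 3 significant
#' figures; the machine-precision columns are what [fit_de()] returns.
#'
#' @param de Data.frame from [fit_de()].
#' @return Data.frame with report-rounded columns.
#' @export
format_de_table <- function(de) {
  data.frame(gene_id = de$gene_id,
             slr = round_half_up(de$slr, 2),
             fc = round_half_up(de$fc, 2),
             t = signif(de$t_stat, 4),
             p_raw = signif(de$p_raw, 3),
             p_adj = signif(de$p_adj, 3),
             mean_m1_log2 = round_half_up(de$mean_m1_log2, 1),
             mean_m0_log2 = round_half_up(de$mean_m0_log2, 1))
}

#' Summarize a clinical cohort table
#'
#' Categorical variables are summarized as counts with percentages (one
#' decimal, half-up) overall and per M0/M1 group, compared with the Fisher
#' exact test; continuous variables as median (range), compared with the
#' two-tailed Mann-Whitney U test.
#'
#' @param clinical Data.frame, one row per patient, containing `group`
#'   (`M0`/`M1`) plus the variables to summarize.
#' @param variables Columns to summarize (default: all but `group` and
#'   `sample_id`).
#' @return Data.frame: `variable`, `level`, `overall`, `m1`, `m0`,
#'   `p_value` (p on the first row of each variable).
#' @export
summarize_cohort <- function(clinical, variables = NULL) {
  stopifnot(nrow(clinical) > 0, "group" %in% names(clinical))
  if (is.null(variables)) {
    variables <- setdiff(names(clinical), c("group", "sample_id"))
  }
  g <- factor(clinical$group, levels = c("M0", "M1"))
  fmt_count <- function(k, n) {
    sprintf("%d (%s%%)", k, formatC(round_half_up(100 * k / n, 1),
                                    format = "f", digits = 1))
  }
  rows <- lapply(variables, function(v) {
    x <- clinical[[v]]
    if (is.numeric(x)) {
      fmt <- function(idx) sprintf("%.1f (%.1f-%.1f)",
                                   stats::median(x[idx]),
                                   min(x[idx]), max(x[idx]))
      p <- mann_whitney(x[g == "M0"], x[g == "M1"])$p_value
      data.frame(variable = v, level = "median (range)",
                 overall = fmt(seq_along(x)),
                 m1 = fmt(which(g == "M1")), m0 = fmt(which(g == "M0")),
                 p_value = p)
    } else {
      x <- factor(x)
      tab <- table(x, g)
      p <- stats::fisher.test(tab)$p.value
      do.call(rbind, lapply(seq_len(nlevels(x)), function(i) {
        data.frame(variable = v, level = levels(x)[i],
                   overall = fmt_count(sum(x == levels(x)[i]), length(x)),
                   m1 = fmt_count(tab[i, "M1"], sum(g == "M1")),
                   m0 = fmt_count(tab[i, "M0"], sum(g == "M0")),
                   p_value = if (i == 1) p else NA_real_)
      }))
    }
  })
  do.call(rbind, rows)
}

#' Percentage formatted as the clinical tables print it
#'
#' @param k Count.
#' @param n Total.
#' @return Percentage rounded half-up to one decimal.
#' @export
percentage <- function(k, n) {
  stopifnot(n > 0, k >= 0)
  round_half_up(100 * k / n, 1)
}
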