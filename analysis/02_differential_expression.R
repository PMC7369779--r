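#!/usr/bin/env Rscript
# Stage 2: batch-aware differential expression, M1 vs M0.
#
# Discovery (cohort A): per-gene linear model with the microarray platform as
# a batch covariate, BH-adjusted p-values; the significant genes (capped at
# 11, most significant first) become the validation panel. Validation
# (cohort B): the same model, Bonferroni over the panel only. Also reports
# where the validated genes' absolute SLRs rank genome-wide.

suppressPackageStartupMessages(library(ptcmeta))
sim_dir <- "results/01_simulate"
out <- "results/02_differential_expression"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ann <- read_annotation(file.path(sim_dir, "annotation.tsv"))
expr_A <- read_expression(file.path(sim_dir, "expr_A.tsv"))
expr_B <- read_expression(file.path(sim_dir, "expr_B.tsv"))

de_A <- fit_de(expr_A, ann[ann$cohort == "A", ])
sig_A <- de_A[de_A$p_adj < 0.05, ]
sig_A <- sig_A[order(sig_A$p_raw), ]
panel <- head(sig_A$gene_id, 11)
message(sprintf("cohort A: %d genes BH-significant at 0.05; panel = %s",
                nrow(sig_A), paste(panel, collapse = ", ")))

de_B <- fit_de(expr_B, ann[ann$cohort == "B", ])
val <- validate_panel(panel, de_B)
message(sprintf("cohort B validation: %d of %d panel genes confirmed (%s)",
                sum(val$validated), nrow(val),
                paste(val$gene_id[val$validated], collapse = ", ")))

for (g in val$gene_id[val$validated]) {
  slr <- de_B$slr[de_B$gene_id == g]
  message(sprintf(
    "  %s: SLR %.2f (FC %.2f); %.2f%% of genes have a larger |SLR|",
    g, slr, slr_to_fc(slr), 100 * slr_percentile(slr, de_B$slr)))
}

write_table_tsv(format_de_table(de_A), file.path(out, "de_A.tsv"))
write_table_tsv(format_de_table(de_B), file.path(out, "de_B.tsv"))
write_table_tsv(val, file.path(out, "panel_validation.tsv"))
writeLines(panel, file.path(out, "panel.txt"))
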