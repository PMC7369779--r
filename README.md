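# ptcmeta

Do primary papillary thyroid carcinomas (PTC) that go on to metastasize
express different genes than those that do not? Answering that requires a
discovery/validation design — a discovery microarray cohort spanning two
array platforms, an independent validation cohort on a third platform, and a
qPCR cohort — and a chain of statistics: batch-aware per-gene linear models,
panel validation under Bonferroni correction, a bespoke Monte-Carlo null for
"how often would a random gene panel validate this well?", pre-ranked gene
set enrichment with cross-cohort concordance testing, and efficiency-corrected
qPCR quantification. `ptcmeta` implements that entire workflow as a tested R
package, driven by a synthetic-data generator that reproduces the study
structure (two cohorts, 12,001 shared genes, per-gene batch offsets, planted
effects), so every stage is verifiable without patient data.

It is aimed at analysts who want a transparent, reproducible implementation
of this class of two-cohort transcriptomic comparison — and at anyone who
wants to probe how such a pipeline behaves when the truth is known.

## The statistics inside

**Differential expression.** For each gene *g*, expression on the log2 scale
is modeled as

```
y_gs = alpha_g + beta_g * 1(sample s is M1) + gamma_gb * 1(s in batch b) + e_gs
```

The group coefficient `beta_g` is the signal log ratio (SLR); the fold
change is `FC = 2^SLR`. Tests use `t = beta / se(beta)`, optionally with
empirical-Bayes variance moderation (prior estimated by moments on log
variances, posterior variance a df-weighted average, df augmented).
Discovery-cohort p-values are Benjamini–Hochberg adjusted genome-wide;
validation applies Bonferroni over the preselected panel only.

**Random-panel null.** Repeatedly draw a panel of 11 genes from the
N = 12,001; a draw "validates" if at least 2 drawn genes are significant
after within-draw Bonferroni (equivalently raw p < 0.05/11) *and* have
|SLR| ≥ 0.83. Because qualification reduces to a fixed per-gene flag, the
Monte-Carlo estimate has an exact counterpart: the upper tail
`P(X ≥ 2)` of `X ~ Hypergeometric(N, K, 11)`, where K counts qualifying
genes. The package computes both.

**Gene set enrichment.** Genes are ranked by t-statistic; each set is scored
with the weighted Kolmogorov–Smirnov running sum (hits add
`|t|^w / sum |t|^w`, misses subtract `1/(N − n_hits)`; ES is the signed
extreme). P-values come from random same-size gene-set permutations with
`(b+1)/(m+1)` smoothing; NES divides ES by the mean same-sign permuted
magnitude; BH across the collection; redundancy is pruned by Jaccard overlap
(cutoff 0.7, lower p wins). Cross-cohort agreement is a Fisher exact test on
the (significant in A) × (significant in B) table, with sign-concordant NES
counted among the both-significant sets.

**qPCR.** Pfaffl efficiency-corrected quantities `Q = E^(Ct_cal − Ct_sample)`
(duplicate wells averaged), normalized by the geometric mean of three
reference genes; reference stability ranked by the geNorm M measure (mean
SD of pairwise log ratios); groups compared by the two-tailed Mann–Whitney
U test.

## Worked example

The numbered drivers under `analysis/` run the whole study on synthetic
cohorts and narrate what they find (outputs under `results/`):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential_expression.R
Rscript analysis/03_panel_null.R
Rscript analysis/04_gsea_concordance.R
Rscript analysis/05_qpcr.R
Rscript analysis/06_cohort_summary.R
```

A run prints, among other things:

```
cohort A: 12001 genes x 71 samples (15 M1, batches: U133A, U133Plus2)
cohort B: 12001 genes x 52 samples (21 M1)
cohort A: 3 genes BH-significant at 0.05; panel = G0002, G0001, G11960
cohort B validation: 3 of 3 panel genes confirmed (G0002, G0001, G11960)
  G0002: SLR 1.97 (FC 3.90); 0.00% of genes have a larger |SLR|
  G0001: SLR 1.40 (FC 2.65); 0.01% of genes have a larger |SLR|
Random-panel null: 0/10000 iterations validated (p_hat = 0, mc_se = 0)
  universe N = 12001, qualifying K = 8, panel = 11, min hits = 2
  exact hypergeometric probability = 2.13e-05
significant sets: A 2, B 2; both 2 (2 concordant in sign); Fisher p = 0.000529
  IMMUNE_A (n=40): NES -3.05 / -2.98, adj p 0.0305 / 0.0301
```

Reading this: the two genes planted with true group effects (G0001, G0002)
are discovered in cohort A, confirmed in cohort B with large SLRs ranking in
the top percentile of absolute effects, and a random 11-gene panel
essentially never validates that well (estimated probability 0 at 10,000
iterations; exactly 2.1 × 10⁻⁵ by the hypergeometric closed form). The two
immune-like gene sets planted with higher expression in non-metastatic (M0)
tumors come out with negative NES in both cohorts, and the cohorts'
significant-set lists overlap far beyond chance.

The same functions work on real data: `read_expression()` /
`read_annotation()` take the TSV layouts documented in their help pages,
`read_gmt()` reads standard GMT collections, and `run_pipeline()` ties the
stages together from an `analysis_config()`.

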