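#' Per-gene differential expression, M1 vs M0, with a batch covariate
#'
#' Fits, for every gene, the least-squares linear model
#' `log2 expression ~ intercept + group + batch` (batch as indicator
#' covariates, omitted when the cohort has a single batch). The group
#' coefficient is the signal log ratio (SLR, log2 fold change M1 vs M0
#' adjusted for batch); `t = slr / se` with the ordinary residual variance,
#' or with empirical-Bayes moderated variance (posterior variance = weighted
#' mean of the gene variance and a moments-estimated prior, with augmented
#' degrees of freedom) when `moderation = TRUE`. P-values are two-sided from
#' the t distribution.
#'
#' Multiple testing: `adjustment = "BH"` adjusts across all genes
#' (discovery); `adjustment = "bonferroni"` adjusts only the genes in `panel`
#' with family size equal to the panel size (validation of a preselected
#' panel), leaving other genes' `p_adj` as `NA`.
#'
#' @param expr Numeric log2 matrix, genes x samples (rownames, colnames set).
#' @param ann Annotation data.frame with `sample_id`, `group` (M0/M1),
#'   `batch`; rows matched to `colnames(expr)` by `sample_id`.
#' @param moderation Use empirical-Bayes variance shrinkage (default FALSE).
#' @param adjustment `"BH"` or `"bonferroni"`.
#' @param panel Gene ids for Bonferroni panel adjustment.
#' @param alpha Significance level recorded for downstream use (default 0.05).
#' @return Data.frame (one row per gene): `gene_id`, `slr`, `fc` (= 2^slr),
#'   `t_stat`, `p_raw`, `p_adj`, `mean_m1_log2`, `mean_m0_log2`, `se`, `df`,
#'   `zero_variance`.
#' @export
fit_de <- function(expr, ann, moderation = FALSE,
                   adjustment = c("BH", "bonferroni"), panel = NULL,
                   alpha = 0.05) {
  adjustment <- match.arg(adjustment)
  stopifnot(is.matrix(expr), !is.null(rownames(expr)),
            !is.null(colnames(expr)),
            all(colnames(expr) %in% ann$sample_id))
  ann <- ann[match(colnames(expr), ann$sample_id), , drop = FALSE]
  group <- factor(ann$group, levels = c("M0", "M1"))
  stopifnot(!anyNA(group))
  if (any(table(group) < 2)) stop("each group needs at least 2 samples")
  batch <- factor(ann$batch)
  design <- if (nlevels(batch) > 1) {
    stats::model.matrix(~ group + batch)
  } else {
    stats::model.matrix(~ group)
  }
  qx <- qr(design)
  if (qx$rank < ncol(design)) {
    stop("design is rank-deficient: batch confounded with group")
  }
  n <- nrow(design)
  df_resid <- n - qx$rank

  fit <- stats::lm.fit(design, t(expr))
  coefs <- fit$coefficients
  if (is.null(dim(coefs))) { # single-gene matrix: lm.fit drops dimensions
    coefs <- matrix(coefs, ncol = 1, dimnames = list(names(coefs), NULL))
  }
  res <- as.matrix(fit$residuals) # n x genes
  rss <- colSums(res^2)
  s2 <- rss / df_resid
  zero_var <- s2 < .Machine$double.eps
  s2 <- pmax(s2, .Machine$double.eps)

  slr <- coefs["groupM1", ]
  xtx_inv <- solve(crossprod(design))
  c_gg <- xtx_inv["groupM1", "groupM1"]

  if (moderation) {
    sq <- squeeze_var(s2, df_resid)
    s2_use <- sq$var_post
    # augmented df, capped at the pooled residual df of the whole matrix
    df_use <- pmin(df_resid + sq$df_prior, df_resid * length(s2))
  } else {
    s2_use <- s2
    df_use <- rep(df_resid, length(s2))
  }
  se <- sqrt(s2_use * c_gg)
  t_stat <- slr / se
  p_raw <- 2 * stats::pt(-abs(t_stat), df_use)

  p_adj <- if (adjustment == "BH") {
    bh_fdr(p_raw)
  } else {
    if (is.null(panel)) stop("bonferroni adjustment requires a panel")
    if (!all(panel %in% rownames(expr))) stop("panel gene absent from matrix")
    out <- rep(NA_real_, length(p_raw))
    idx <- match(panel, rownames(expr))
    out[idx] <- bonferroni(p_raw[idx], length(panel))
    out
  }

  data.frame(
    gene_id = rownames(expr),
    slr = unname(slr),
    fc = unname(2^slr),
    t_stat = unname(t_stat),
    p_raw = unname(p_raw),
    p_adj = p_adj,
    mean_m1_log2 = unname(rowMeans(expr[, group == "M1", drop = FALSE])),
    mean_m0_log2 = unname(rowMeans(expr[, group == "M0", drop = FALSE])),
    se = unname(se),
    df = unname(df_use),
    zero_variance = unname(zero_var),
    row.names = NULL
  )
}

# Empirical-Bayes variance shrinkage: moments estimation of the scaled
# inverse-chi-square prior (df_prior, var_prior) from log sample variances,
# then posterior variances as the df-weighted mean.
squeeze_var <- function(s2, df) {
  stopifnot(length(df) == 1, df > 0)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  e_mean <- mean(e)
  e_var <- stats::var(e) - trigamma(df / 2)
  if (is.na(e_var) || e_var <= 0) {
    # no excess spread beyond sampling noise: variances exchangeable
    df_prior <- Inf
    var_prior <- mean(s2)
  } else {
    df_prior <- 2 * trigamma_inverse(e_var)
    var_prior <- exp(e_mean + digamma(df_prior / 2) - log(df_prior / 2))
  }
  var_post <- if (is.infinite(df_prior)) {
    rep(var_prior, length(s2))
  } else {
    (df_prior * var_prior + df * s2) / (df_prior + df)
  }
  list(df_prior = df_prior, var_prior = var_prior, var_post = var_post)
}

# Solve trigamma(y) = x by Newton iteration on 1/trigamma (monotone, smooth).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Convert a signal log ratio to a linear fold change
#' @param slr Log2 ratio(s), finite.
#' @return `2^slr`.
#' @export
slr_to_fc <- function(slr) {
  stopifnot(all(is.finite(slr)))
  2^slr
}

#' Fraction of genes with larger absolute SLR than a query
#'
#' Ranks an effect size within a cohort's genome-wide SLR distribution: the
#' proportion of genes whose |SLR| strictly exceeds |query|.
#'
#' @param query_slr Single SLR value.
#' @param all_slr Non-empty numeric vector of SLRs.
#' @return Fraction in [0, 1].
#' @export
slr_percentile <- function(query_slr, all_slr) {
  stopifnot(length(all_slr) > 0)
  mean(abs(all_slr) > abs(query_slr))
}

#' Validate a preselected gene panel by Bonferroni correction
#'
#' Applies Bonferroni with family size = panel size to the raw p-values of
#' the panel genes only; a gene is validated when its adjusted p-value is
#' below `alpha`.
#'
#' @param panel Character vector of gene ids (all present in `de_results`).
#' @param de_results Data.frame from [fit_de()] on the validation cohort.
#' @param alpha Significance level (default 0.05).
#' @return Data.frame: `gene_id`, `slr`, `p_raw`, `p_adj`, `validated`.
#' @export
validate_panel <- function(panel, de_results, alpha = 0.05) {
  if (length(panel) == 0) {
    return(data.frame(gene_id = character(0), slr = numeric(0),
                      p_raw = numeric(0), p_adj = numeric(0),
                      validated = logical(0)))
  }
  idx <- match(panel, de_results$gene_id)
  if (anyNA(idx)) {
    stop("panel gene absent from results: ",
         paste(panel[is.na(idx)], collapse = ", "))
  }
  p_adj <- bonferroni(de_results$p_raw[idx], length(panel))
  data.frame(gene_id = panel,
             slr = de_results$slr[idx],
             p_raw = de_results$p_raw[idx],
             p_adj = p_adj,
             validated = p_adj < alpha,
             row.names = NULL)
}
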