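# Independent oracles used across the suite: brute-force enumerations and
# naive reference implementations, deliberately kept separate from the
# package's own code paths.

# Two-sided Mann-Whitney p by full enumeration of group assignments
# (tie-free inputs): P(|U - E[U]| >= |u_obs - E[U]|) under the permutation
# null.
mw_enum_p <- function(x, y) {
  n <- length(x)
  pooled <- c(x, y)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_of(x, y)
  eu <- n * length(y) / 2
  combs <- utils::combn(length(pooled), n)
  us <- apply(combs, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  mean(abs(us - eu) >= abs(u_obs - eu) - 1e-12)
}

# Two-sided Fisher p by enumeration of all 2x2 tables with the observed
# margins (probability-mass rule).
fisher_enum_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(xs, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pooled two-sample t (equal variances) on one gene: closed-form oracle for
# the single-batch linear model.
pooled_t <- function(m0, m1) {
  n0 <- length(m0); n1 <- length(m1)
  sp2 <- ((n0 - 1) * stats::var(m0) + (n1 - 1) * stats::var(m1)) / (n0 + n1 - 2)
  se <- sqrt(sp2 * (1 / n0 + 1 / n1))
  t <- (mean(m1) - mean(m0)) / se
  df <- n0 + n1 - 2
  list(slr = mean(m1) - mean(m0), t = t, se = se, df = df,
       p = 2 * stats::pt(-abs(t), df))
}

# Naive O(N) running-sum walk for the enrichment score.
es_naive <- function(ranked, members, weight = 1) {
  hit <- names(ranked) %in% members
  aw <- abs(ranked)^weight
  s <- sum(aw[hit])
  inc <- if (s > 0) ifelse(hit, aw / s, 0) else ifelse(hit, 1 / sum(hit), 0)
  dec <- ifelse(hit, 0, 1 / (length(ranked) - sum(hit)))
  rs <- cumsum(inc - dec)
  if (max(rs) >= -min(rs)) max(rs) else min(rs)
}

# Small single-batch annotation for toy matrices.
toy_ann <- function(n0, n1, batch = "b1") {
  data.frame(sample_id = sprintf("s%02d", seq_len(n0 + n1)),
             group = rep(c("M0", "M1"), c(n0, n1)),
             batch = batch, cohort = "A")
}

toy_matrix <- function(values, n_samples) {
  m <- matrix(values, ncol = n_samples, byrow = TRUE)
  rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  colnames(m) <- sprintf("s%02d", seq_len(n_samples))
  m
}
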