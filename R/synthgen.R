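#' Simulation configuration for synthetic expression cohorts
#'
#' Describes the two-cohort structure the generator emulates: a discovery
#' cohort "A" of 71 arrays spanning two microarray platforms (44 + 27 arrays,
#' 15 of the patients metastatic) and a validation cohort "B" of 52 arrays on
#' a single platform (21 metastatic), sharing 12,001 genes. Expression is
#' simulated on the log2 scale as
#' baseline + per-gene batch offset + group effect + noise.
#'
#' @param n_genes Number of genes shared across platforms (default 12001).
#' @param designs Named list of cohort designs. Each design is a data.frame
#'   with columns `batch`, `n_m0`, `n_m1` (one row per batch). Defaults follow
#'   the study layout: cohort A on batches `U133A` (35 M0 + 9 M1) and
#'   `U133Plus2` (21 M0 + 6 M1), cohort B on `Gene10ST` (31 M0 + 21 M1). The
#'   paper states only cohort totals; the M1 split across A's two batches is a
#'   proportional convention of this generator.
#' @param baseline_range Range (log2 units) from which per-gene baseline means
#'   are drawn uniformly. Default `c(3, 12)`, mimicking the span of printed
#'   group means (3.3-10.5).
#' @param noise_sd Standard deviation of independent per-gene, per-sample
#'   Gaussian noise on the log2 scale. Default 0.8.
#' @param batch_sd Standard deviation of per-gene, per-batch offsets (log2).
#'   Default 0.5. Offsets are drawn once per gene x batch.
#' @param planted_slr Named numeric vector mapping gene ids to true signal log
#'   ratios (log2 M1/M0 group difference, added to M1 samples). Defaults plant
#'   two genes at the study's headline effect sizes, 0.83 and 1.08.
#' @param planted_set_shift Named numeric vector mapping gene ids to a log2
#'   up-shift applied to **M0** samples (immune-like coordinated signal:
#'   higher expression in patients without distant metastases, hence negative
#'   enrichment for an M1-vs-M0 ranking). Default none.
#' @param seed Integer seed; every generator call is reproducible from it.
#'
#' @return An object of class `sim_config` (a list of the above).
#' @export
sim_config <- function(n_genes = 12001,
                       designs = default_cohort_designs(),
                       baseline_range = c(3, 12),
                       noise_sd = 0.8,
                       batch_sd = 0.5,
                       planted_slr = c(G0001 = 0.83, G0002 = 1.08),
                       planted_set_shift = numeric(0),
                       seed = 1L) {
  stopifnot(n_genes >= 1, length(baseline_range) == 2,
            baseline_range[1] <= baseline_range[2],
            noise_sd >= 0, batch_sd >= 0)
  for (d in designs) {
    stopifnot(is.data.frame(d), all(c("batch", "n_m0", "n_m1") %in% names(d)),
              all(d$n_m0 >= 0), all(d$n_m1 >= 0), sum(d$n_m0 + d$n_m1) > 0)
  }
  structure(list(n_genes = n_genes, designs = designs,
                 baseline_range = baseline_range, noise_sd = noise_sd,
                 batch_sd = batch_sd, planted_slr = planted_slr,
                 planted_set_shift = planted_set_shift, seed = seed),
            class = "sim_config")
}

#' Default two-cohort study design
#'
#' @return Named list of per-cohort data.frames (`batch`, `n_m0`, `n_m1`).
#' @export
default_cohort_designs <- function() {
  list(
    A = data.frame(batch = c("U133A", "U133Plus2"),
                   n_m0 = c(35L, 21L), n_m1 = c(9L, 6L)),
    B = data.frame(batch = "Gene10ST", n_m0 = 31L, n_m1 = 21L)
  )
}

gene_ids_for <- function(n_genes) sprintf("G%04d", seq_len(n_genes))

#' Generate one synthetic expression cohort
#'
#' Draws a log2 expression matrix (genes x samples) plus its sample
#' annotation. Per gene g and sample s in batch b and group z:
#' `y[g,s] = mu[g] + delta[g,b] + slr[g] * 1(z == M1) + shift[g] * 1(z == M0)
#' + e[g,s]`, with `mu` uniform on `baseline_range`, `delta` normal with sd
#' `batch_sd`, `e` normal with sd `noise_sd`, `slr` from `planted_slr` and
#' `shift` from `planted_set_shift`. Baselines, batch offsets and planted
#' effects are shared across cohorts drawn from the same config seed; noise is
#' cohort-specific, so cohorts A and B are independent replicates of the same
#' truth.
#'
#' @param config A [sim_config()].
#' @param cohort Cohort label present in `config$designs` (e.g. `"A"`).
#' @return List with `expr` (numeric matrix, rownames = gene ids, colnames =
#'   sample ids) and `annotation` (data.frame: `sample_id`, `group`, `batch`,
#'   `cohort`).
#' @export
generate_cohort <- function(config, cohort) {
  stopifnot(inherits(config, "sim_config"))
  if (!cohort %in% names(config$designs)) {
    stop("unknown cohort label: ", cohort)
  }
  design <- config$designs[[cohort]]
  genes <- gene_ids_for(config$n_genes)
  all_batches <- sort(unique(unlist(lapply(config$designs, `[[`, "batch"))))

  # Gene-level truth is drawn from the config seed alone so that every cohort
  # of a config shares baselines and batch offsets.
  truth <- with_seed_opt(config$seed, {
    mu <- stats::runif(config$n_genes, config$baseline_range[1],
                       config$baseline_range[2])
    delta <- matrix(stats::rnorm(config$n_genes * length(all_batches),
                                 sd = config$batch_sd),
                    nrow = config$n_genes,
                    dimnames = list(genes, all_batches))
    list(mu = mu, delta = delta)
  })

  slr <- stats::setNames(numeric(config$n_genes), genes)
  known <- intersect(names(config$planted_slr), genes)
  slr[known] <- config$planted_slr[known]
  shift <- stats::setNames(numeric(config$n_genes), genes)
  known_s <- intersect(names(config$planted_set_shift), genes)
  shift[known_s] <- config$planted_set_shift[known_s]

  n_total <- sum(design$n_m0 + design$n_m1)
  ann <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    data.frame(group = rep(c("M0", "M1"), c(design$n_m0[i], design$n_m1[i])),
               batch = design$batch[i])
  }))
  ann$sample_id <- sprintf("%s%03d", cohort, seq_len(n_total))
  ann$cohort <- cohort
  ann <- ann[, c("sample_id", "group", "batch", "cohort")]

  cohort_seed <- config$seed + 7919L * match(cohort, names(config$designs))
  expr <- with_seed_opt(cohort_seed, {
    e <- matrix(stats::rnorm(config$n_genes * n_total, sd = config$noise_sd),
                nrow = config$n_genes)
    m <- truth$mu + e +
      truth$delta[, ann$batch, drop = FALSE] +
      outer(slr, as.numeric(ann$group == "M1")) +
      outer(shift, as.numeric(ann$group == "M0"))
    dimnames(m) <- list(genes, ann$sample_id)
    m
  })
  stopifnot(all(is.finite(expr)))
  list(expr = expr, annotation = ann)
}

#' Generate random gene sets over a gene universe
#'
#' Sets are drawn without replacement from `universe`, with sizes uniform in
#' `size_range`. Sets named in `planted_ids` are built to contain the supplied
#' `planted_members` (e.g. the genes a cohort generator up-shifts in M0), so a
#' collection can carry a known enrichment signal.
#'
#' @param n_sets Number of sets.
#' @param size_range Length-2 integer range of set sizes (inclusive).
#' @param universe Character vector of gene ids.
#' @param planted_ids Character vector of set ids (subset of the generated
#'   ids `S001`, `S002`, ...) that must contain `planted_members`.
#' @param planted_members Gene ids forced into each planted set.
#' @param seed Integer seed.
#' @return Named list of character vectors (members), one per set, with a
#'   `description` attribute per element left to the GMT writer.
#' @export
generate_gene_sets <- function(n_sets, size_range, universe,
                               planted_ids = character(0),
                               planted_members = character(0),
                               seed = 1L) {
  stopifnot(n_sets >= 0, length(size_range) == 2,
            size_range[1] >= 1, size_range[1] <= size_range[2])
  if (size_range[2] > length(universe)) {
    stop("size_range exceeds universe size")
  }
  if (n_sets == 0) return(stats::setNames(list(), character(0)))
  ids <- sprintf("S%03d", seq_len(n_sets))
  stopifnot(all(planted_ids %in% ids), all(planted_members %in% universe))
  with_seed_opt(seed, {
    sets <- lapply(ids, function(id) {
      size <- sample(seq(size_range[1], size_range[2]), 1)
      if (id %in% planted_ids) {
        size <- max(size, length(planted_members))
        extra <- sample(setdiff(universe, planted_members),
                        size - length(planted_members))
        sort(c(planted_members, extra))
      } else {
        sort(sample(universe, size))
      }
    })
    stats::setNames(sets, ids)
  })
}

#' Generate a synthetic qPCR Ct table
#'
#' Emulates the validation qPCR design: each sample is measured in duplicate
#' for a handful of target genes plus reference (normalization) genes. Each
#' gene's underlying relative abundance is log-normal on the log2 scale
#' (`base_log2` + group effect for targets in M1 + sample-level scaling noise
#' shared across genes, which normalization must remove); the threshold cycle
#' follows the amplification-efficiency model
#' `Ct = ct0 - log2(abundance) / log2(E)`, plus replicate jitter.
#'
#' @param n_m0,n_m1 Samples per group (defaults 54 and 9, the qPCR set-C
#'   design).
#' @param targets Character vector of target gene ids.
#' @param references Character vector of reference gene ids (default the three
#'   normalization genes used in the study).
#' @param target_effect Named numeric, log2 shift added to M1 samples per
#'   target (default 0 for all).
#' @param efficiency_range Range of per-gene amplification efficiencies, within
#'   [1, 2] (2 = perfect doubling per cycle).
#' @param abundance_sd Per-sample x gene biological log2 sd (default 0.5).
#' @param loading_sd Sd of the per-sample log2 loading offset shared by all
#'   genes of that sample (default 1); this is what reference normalization
#'   removes.
#' @param jitter_sd Replicate-to-replicate Ct sd (default 0.1).
#' @param seed Integer seed.
#' @return Data.frame with columns `sample_id`, `gene_id`, `replicate`, `ct`,
#'   `efficiency`, `role` (`target`/`reference`), `group`.
#' @export
generate_qpcr <- function(n_m0 = 54L, n_m1 = 9L,
                          targets = "IGFBP3",
                          references = c("EIF3S10", "HADHA", "UBE2D2"),
                          target_effect = NULL,
                          efficiency_range = c(1.8, 2.0),
                          abundance_sd = 0.5,
                          loading_sd = 1,
                          jitter_sd = 0.1,
                          seed = 1L) {
  stopifnot(n_m0 >= 1, n_m1 >= 1, length(targets) >= 1,
            length(references) >= 1)
  if (any(efficiency_range < 1) || any(efficiency_range > 2)) {
    stop("efficiencies must lie in [1, 2]")
  }
  if (is.null(target_effect)) {
    target_effect <- stats::setNames(numeric(length(targets)), targets)
  }
  genes <- c(targets, references)
  role <- rep(c("target", "reference"), c(length(targets), length(references)))
  samples <- data.frame(
    sample_id = sprintf("C%03d", seq_len(n_m0 + n_m1)),
    group = rep(c("M0", "M1"), c(n_m0, n_m1)))
  with_seed_opt(seed, {
    eff <- stats::setNames(
      stats::runif(length(genes), efficiency_range[1], efficiency_range[2]),
      genes)
    base_log2 <- stats::setNames(
      stats::runif(length(genes), 2, 8), genes)
    loading <- stats::rnorm(nrow(samples), sd = loading_sd)
    rows <- vector("list", nrow(samples) * length(genes))
    k <- 0L
    for (i in seq_len(nrow(samples))) {
      for (j in seq_along(genes)) {
        g <- genes[j]
        eff_g <- eff[[g]]
        ab <- base_log2[[g]] + loading[i] +
          stats::rnorm(1, sd = abundance_sd) +
          if (role[j] == "target" && samples$group[i] == "M1")
            target_effect[[g]] else 0
        ct0 <- 35 # cycles to threshold at unit abundance
        ct_true <- ct0 - ab / log2(eff_g)
        k <- k + 1L
        rows[[k]] <- data.frame(
          sample_id = samples$sample_id[i], gene_id = g,
          replicate = 1:2,
          ct = ct_true + stats::rnorm(2, sd = jitter_sd),
          efficiency = eff_g, role = role[j], group = samples$group[i])
      }
    }
    do.call(rbind, rows)
  })
}
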