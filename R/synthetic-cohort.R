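#' Simulation configuration for synthetic twin cohorts
#'
#' Defines the generative model the downstream analysis assumes: biallelic
#' Hardy-Weinberg genotypes with a minor-allele-frequency spectrum and random
#' missingness; log-normal TPM expression with planted per-allele cis effects
#' inside the 1 Mb window around gene TSSs plus shared latent factors;
#' Weibull proportional-hazards survival driven by standardized expression of
#' planted genes and by T/N/M stage; administrative censoring at a follow-up
#' horizon; and a second cohort sharing a configurable subset of planted
#' effects.
#'
#' Planted effects are organized into regulatory clusters emulating
#' multi-gene eQTL loci: one variant regulates several co-expressed
#' neighboring genes (within-cluster residual correlation `cluster_share`),
#' and each cluster's survival effect enters through its lead gene. This
#' keeps the total log-hazard variance at the cluster count rather than the
#' pair count, the realistic regime for a tumour cohort.
#'
#' Default scale mirrors a ~100-patient tumour cohort: 100 samples, 300
#' genes, 3000 variants, 10 single-gene planted eQTLs (slope 1 on the
#' log-expression scale, residual sd 1) of which the first three also carry
#' a survival coefficient of 1 per standard deviation of log expression.
#' Hazard effects are kept to a handful because every planted survival gene
#' acts as unexplained frailty for the others; likewise, multi-gene
#' clusters concentrate variance into directions the latent-factor
#' covariates can absorb (factor methods are known to soak up multi-gene
#' eQTL signals), so tight clusters should be used deliberately, not by
#' default.
#'
#' @param n_samples Samples per cohort.
#' @param n_genes,n_variants Number of genes and variants.
#' @param n_chrom Number of chromosomes genes are spread over.
#' @param gene_spacing Base pairs between consecutive gene TSSs.
#' @param maf_range Range the per-variant allele frequency is drawn from.
#' @param missing_rate Fraction of genotypes set missing at random.
#' @param planted Optional `data.frame` with one row per planted gene-variant
#'   pair: `cluster` (positive integer; rows of a cluster share one variant),
#'   `gene` (index), `beta` (eQTL slope per ALT allele on log expression),
#'   `gamma` (log-hazard per SD of the gene's log expression; conventionally
#'   nonzero only on each cluster's lead gene) and `replication` in
#'   `c("strict", "lenient", "discordant", "null")` describing how the
#'   cluster's effects carry into the second cohort.
#' @param sharing Fraction of planted clusters shared with the second cohort;
#'   only used to build the default `planted` table (leading clusters
#'   `"strict"`, the rest `"null"`).
#' @param planted_maf Allele frequency used for planted variants.
#' @param sigma Residual sd of log expression given dosage.
#' @param cluster_share Fraction of the planted genes' residual variance
#'   shared within their cluster (within-cluster co-expression).
#' @param n_latent,latent_sd Number and sd of shared latent expression
#'   factors (cohort-wide confounders).
#' @param base_log_tpm_mean,base_log_tpm_sd Distribution of per-gene baseline
#'   log TPM.
#' @param depth Mean library depth factor linking TPM to Poisson counts.
#' @param weibull_shape,weibull_scale Baseline Weibull survival parameters
#'   (shape 1 = exponential; scale in days).
#' @param horizon Administrative censoring horizon in days.
#' @param clinical_coefs Named log-hazard coefficients for `t_stage`,
#'   `n_stage`, `m_stage`.
#' @param lenient_factor Multiplier applied to `gamma` in the second cohort
#'   for clusters labelled `"lenient"` (direction kept, significance
#'   typically lost).
#' @param maf_jitter Sd of the logit-scale MAF shift applied in the second
#'   cohort.
#' @param seed Integer seed; every generator call is deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 100, n_genes = 300, n_variants = 3000,
                       n_chrom = 5, gene_spacing = 400000L,
                       maf_range = c(0.05, 0.5), missing_rate = 0.02,
                       planted = NULL, sharing = 1, planted_maf = 0.3,
                       sigma = 1, cluster_share = 0.5,
                       n_latent = 2, latent_sd = 0.5,
                       base_log_tpm_mean = 1.5, base_log_tpm_sd = 1.5,
                       depth = 30, weibull_shape = 1, weibull_scale = 3000,
                       horizon = 4000,
                       clinical_coefs = c(t_stage = 0.4, n_stage = 0.5,
                                          m_stage = 0.7),
                       lenient_factor = 0.15, maf_jitter = 0.3,
                       seed = 1L) {
  stopifnot(length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            missing_rate >= 0, missing_rate < 1,
            weibull_shape > 0, weibull_scale > 0, horizon >= 0,
            sharing >= 0, sharing <= 1,
            cluster_share >= 0, cluster_share <= 1)
  if (is.null(planted)) {
    n_pl <- 10L
    n_shared <- round(sharing * n_pl)
    planted <- data.frame(
      cluster = seq_len(n_pl),
      gene = seq_len(n_pl),
      beta = rep(1, n_pl),
      gamma = as.numeric(seq_len(n_pl) <= 3),
      replication = rep(c("strict", "null"), c(n_shared, n_pl - n_shared)),
      stringsAsFactors = FALSE)
  }
  planted <- as.data.frame(planted, stringsAsFactors = FALSE)
  if (!("cluster" %in% names(planted)))
    planted$cluster <- seq_len(nrow(planted))
  stopifnot(all(planted$replication %in%
                  c("strict", "lenient", "discordant", "null")),
            all(is.finite(planted$beta)), all(is.finite(planted$gamma)),
            all(planted$gene >= 1), all(planted$gene <= n_genes),
            !anyDuplicated(planted$gene))
  n_clusters <- length(unique(planted$cluster))
  stopifnot(all(sort(unique(planted$cluster)) == seq_len(n_clusters)))
  if (n_clusters > n_variants)
    stop("more planted clusters than variants")
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 n_variants = n_variants, n_chrom = n_chrom,
                 gene_spacing = as.integer(gene_spacing),
                 maf_range = maf_range, missing_rate = missing_rate,
                 planted = planted, n_clusters = n_clusters,
                 planted_maf = planted_maf,
                 sigma = sigma, cluster_share = cluster_share,
                 n_latent = n_latent, latent_sd = latent_sd,
                 base_log_tpm_mean = base_log_tpm_mean,
                 base_log_tpm_sd = base_log_tpm_sd, depth = depth,
                 weibull_shape = weibull_shape,
                 weibull_scale = weibull_scale, horizon = horizon,
                 clinical_coefs = clinical_coefs,
                 lenient_factor = lenient_factor, maf_jitter = maf_jitter,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Gene map: genes laid out evenly along n_chrom chromosomes.
sim_gene_map <- function(cfg) {
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chrom)
  idx <- seq_len(cfg$n_genes) - 1L
  data.frame(
    gene_id = sprintf("G%04d", seq_len(cfg$n_genes)),
    chrom = paste0("chr", idx %/% per_chrom + 1L),
    tss = (idx %% per_chrom) * cfg$gene_spacing + 1000000L,
    stringsAsFactors = FALSE)
}

#' Simulate a genotype matrix
#'
#' Per variant, an allele frequency is drawn uniformly from `maf_range` and
#' genotypes follow Hardy-Weinberg binomial(2, p) sampling; entries are then
#' set missing at `missing_rate`. Variant positions are scattered along the
#' simulated gene map so that each gene has cis variants within 1 Mb of its
#' TSS. One planted variant per cluster (row `c` of the matrix for cluster
#' `c`) is placed at the centroid TSS of the cluster's genes at allele
#' frequency `planted_maf`; every cluster gene must fall within 1 Mb of it.
#'
#' @param cfg A [sim_config()].
#' @param maf Optional vector of per-variant allele frequencies overriding
#'   the draw (used for the twin cohort).
#' @param variants Optional variant table (`chrom`, `pos`, `ref`, `alt`) to
#'   reuse, so twin cohorts are genotyped on one shared panel.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(cfg, maf = NULL, variants = NULL) {
  set.seed(cfg$seed)
  gmap <- sim_gene_map(cfg)
  n_cl <- cfg$n_clusters
  if (!is.null(variants)) {
    stopifnot(nrow(variants) == cfg$n_variants)
    if (is.null(maf))
      maf <- stats::runif(cfg$n_variants, cfg$maf_range[1], cfg$maf_range[2])
    d <- matrix(stats::rbinom(cfg$n_variants * cfg$n_samples, 2,
                              rep(maf, cfg$n_samples)),
                nrow = cfg$n_variants)
    if (cfg$missing_rate > 0) {
      miss <- matrix(stats::runif(length(d)) < cfg$missing_rate, nrow = nrow(d))
      d[miss] <- NA_real_
    }
    samples <- sprintf("S%03d", seq_len(cfg$n_samples))
    return(genotype_matrix(d, variants[, c("chrom", "pos", "ref", "alt")],
                           samples))
  }
  cl_chrom <- character(n_cl); cl_pos <- integer(n_cl)
  for (cc in seq_len(n_cl)) {
    gg <- gmap[cfg$planted$gene[cfg$planted$cluster == cc], ]
    if (length(unique(gg$chrom)) > 1)
      stop("cluster ", cc, " spans multiple chromosomes")
    cl_chrom[cc] <- gg$chrom[1]
    cl_pos[cc] <- as.integer(round(mean(gg$tss))) + 10000L
    if (any(abs(gg$tss - cl_pos[cc]) > 1e6))
      stop("cluster ", cc, " genes exceed the 1 Mb window of its variant")
  }
  n_bg <- cfg$n_variants - n_cl
  bg_gene <- gmap[sample.int(cfg$n_genes, n_bg, replace = TRUE), ]
  chrom <- c(cl_chrom, bg_gene$chrom)
  pos <- c(cl_pos, bg_gene$tss + sample(-900000:900000, n_bg, replace = TRUE))
  pos <- pmax(pos, 1L)
  if (is.null(maf)) {
    maf <- stats::runif(cfg$n_variants, cfg$maf_range[1], cfg$maf_range[2])
    maf[seq_len(n_cl)] <- cfg$planted_maf
  }
  d <- matrix(stats::rbinom(cfg$n_variants * cfg$n_samples, 2,
                            rep(maf, cfg$n_samples)),
              nrow = cfg$n_variants)
  if (cfg$missing_rate > 0) {
    miss <- matrix(stats::runif(length(d)) < cfg$missing_rate, nrow = nrow(d))
    d[miss] <- NA_real_
  }
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, cfg$n_variants, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), character(1))
  key <- paste(chrom, pos)
  while (anyDuplicated(key)) {      # de-duplicate coincident positions
    dup <- duplicated(key)
    pos[dup] <- pos[dup] + 1L
    key <- paste(chrom, pos)
  }
  variants <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         stringsAsFactors = FALSE)
  samples <- sprintf("S%03d", seq_len(cfg$n_samples))
  genotype_matrix(d, variants, samples)
}

#' Simulate expression with planted cis effects
#'
#' Latent log expression per gene is baseline + planted slope x mean-imputed
#' dosage of the cluster variant + shared latent factors + residual noise.
#' Planted genes split their residual (total sd `sigma`) into a
#' within-cluster shared component (variance fraction `cluster_share`) and
#' an idiosyncratic remainder, giving the co-expression structure of a
#' multi-gene locus. TPM is the exponential of the latent value; counts are
#' Poisson with mean proportional to TPM x per-sample depth.
#'
#' @param g A [genotype_matrix()] from [simulate_genotypes()].
#' @param cfg The same [sim_config()].
#' @param beta Optional vector overriding the planted slopes (one per planted
#'   row; used for the twin cohort).
#' @return An [expression_matrix()] with counts.
#' @export
simulate_expression <- function(g, cfg, beta = NULL) {
  set.seed(cfg$seed + 1L)
  gmap <- sim_gene_map(cfg)
  n <- cfg$n_samples
  pl <- cfg$planted
  if (is.null(beta)) beta <- pl$beta
  stopifnot(length(beta) == nrow(pl))
  base <- stats::rnorm(cfg$n_genes, cfg$base_log_tpm_mean, cfg$base_log_tpm_sd)
  # planted effects sit on robustly expressed genes, as in real eQTL studies
  # where only genes passing expression thresholds are mapped
  base[pl$gene] <- stats::rnorm(nrow(pl), 2.5, 0.5)
  latent <- matrix(stats::rnorm(n * cfg$n_latent), n, cfg$n_latent)
  loadings <- matrix(stats::rnorm(cfg$n_genes * cfg$n_latent, 0, cfg$latent_sd),
                     cfg$n_genes, cfg$n_latent)
  log_tpm <- matrix(stats::rnorm(cfg$n_genes * n, 0, cfg$sigma), cfg$n_genes, n)
  for (cc in seq_len(cfg$n_clusters)) {
    rows <- which(pl$cluster == cc)
    dos <- mean_impute_dosage(g$dosage[cc, ])
    shared <- stats::rnorm(n, 0, cfg$sigma * sqrt(cfg$cluster_share))
    for (i in rows) {
      idio <- stats::rnorm(n, 0, cfg$sigma * sqrt(1 - cfg$cluster_share))
      log_tpm[pl$gene[i], ] <- beta[i] * dos + shared + idio
    }
  }
  log_tpm <- log_tpm + base + loadings %*% t(latent)
  tpm <- exp(log_tpm)
  depth <- cfg$depth * exp(stats::rnorm(n, 0, 0.2))
  counts <- matrix(stats::rpois(length(tpm), t(t(tpm) * depth) / 10),
                   nrow = nrow(tpm))
  expression_matrix(tpm, gmap, g$samples, counts = counts)
}

#' Simulate proportional-hazards survival
#'
#' Event times are Weibull with the log hazard shifted by the planted
#' per-gene coefficients (per standard deviation of log expression) plus the
#' clinical stage effects; follow-up is administratively censored at the
#' horizon.
#'
#' @param e An [expression_matrix()] from [simulate_expression()].
#' @param cfg The same [sim_config()].
#' @param gamma Optional vector overriding the planted log-hazard
#'   coefficients.
#' @return A [clinical_table()].
#' @export
simulate_survival <- function(e, cfg, gamma = NULL) {
  set.seed(cfg$seed + 2L)
  n <- length(e$samples)
  if (is.null(gamma)) gamma <- cfg$planted$gamma
  stopifnot(length(gamma) == nrow(cfg$planted))
  t_stage <- sample(1:4, n, replace = TRUE, prob = c(0.35, 0.3, 0.25, 0.1))
  n_stage <- sample(0:2, n, replace = TRUE, prob = c(0.75, 0.15, 0.1))
  m_stage <- sample(0:1, n, replace = TRUE, prob = c(0.8, 0.2))
  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.75, 0.25))
  age <- sample(35:91, n, replace = TRUE)
  eta <- cfg$clinical_coefs["t_stage"] * (t_stage - mean(t_stage)) +
    cfg$clinical_coefs["n_stage"] * (n_stage - mean(n_stage)) +
    cfg$clinical_coefs["m_stage"] * (m_stage - mean(m_stage))
  for (i in seq_len(nrow(cfg$planted))) {
    if (gamma[i] == 0) next
    z <- log(e$tpm[cfg$planted$gene[i], ])
    if (stats::sd(z) > 0)
      eta <- eta + gamma[i] * (z - mean(z)) / stats::sd(z)
  }
  u <- stats::runif(n)
  t_event <- cfg$weibull_scale * (-log(u) * exp(-eta))^(1 / cfg$weibull_shape)
  time <- pmin(t_event, cfg$horizon)
  event <- as.integer(t_event <= cfg$horizon)
  time <- pmax(time, 1)
  clinical_table(data.frame(
    sample_id = e$samples, sex = sex, age = age,
    t_stage = t_stage, n_stage = n_stage, m_stage = m_stage,
    time = time, event = event, stringsAsFactors = FALSE))
}

#' Simulate one aligned cohort
#'
#' Convenience wrapper chaining [simulate_genotypes()],
#' [simulate_expression()], [simulate_survival()] and [align_cohort()].
#'
#' @param cfg A [sim_config()].
#' @inheritParams simulate_expression
#' @inheritParams simulate_survival
#' @param maf Optional per-variant allele frequencies.
#' @param variants Optional shared variant panel (see [simulate_genotypes()]).
#' @return A `cohort` (see [align_cohort()]) with the planted truth attached
#'   as attribute `truth` (one row per planted gene-variant pair with
#'   `gene_id` and `variant_id`).
#' @export
simulate_cohort <- function(cfg, maf = NULL, beta = NULL, gamma = NULL,
                            variants = NULL) {
  g <- simulate_genotypes(cfg, maf = maf, variants = variants)
  e <- simulate_expression(g, cfg, beta = beta)
  cl <- simulate_survival(e, cfg, gamma = gamma)
  co <- align_cohort(g, e, cl)
  truth <- cfg$planted
  truth$gene_id <- e$genes$gene_id[truth$gene]
  truth$variant_id <- g$variants$variant_id[truth$cluster]
  attr(co, "truth") <- truth
  co
}

#' Generate paired discovery/validation cohorts
#'
#' The validation cohort re-draws genotypes at logit-jittered allele
#' frequencies and carries each planted cluster according to its
#' `replication` label: `"strict"` keeps both the eQTL slopes and the
#' survival coefficients, `"lenient"` keeps the slopes but attenuates the
#' survival coefficients by `lenient_factor` (direction preserved,
#' significance typically lost), `"discordant"` keeps the slopes but flips
#' the sign of the survival coefficients, and `"null"` zeroes both.
#'
#' @param cfg A [sim_config()] describing the discovery cohort.
#' @return A list with `discovery` and `validation` cohorts and the planted
#'   `truth` table.
#' @export
make_paired_cohorts <- function(cfg) {
  discovery <- simulate_cohort(cfg)
  truth <- attr(discovery, "truth")
  set.seed(cfg$seed + 3L)
  g <- discovery$genotypes
  # jitter background MAFs on the logit scale; keep planted MAFs
  maf_a <- apply(g$dosage, 1, alt_allele_frequency)
  maf_a <- pmin(pmax(maf_a, 0.02), 0.98)
  lg <- stats::qlogis(maf_a) + stats::rnorm(length(maf_a), 0, cfg$maf_jitter)
  maf_b <- pmin(pmax(stats::plogis(lg), 0.02), 0.5)
  maf_b[seq_len(cfg$n_clusters)] <- cfg$planted_maf
  mult <- c(strict = 1, lenient = cfg$lenient_factor, discordant = -1,
            null = 0)[truth$replication]
  cfg_b <- cfg
  cfg_b$seed <- cfg$seed + 1000L
  validation <- simulate_cohort(cfg_b, maf = maf_b,
                                beta = truth$beta * (truth$replication != "null"),
                                gamma = truth$gamma * unname(mult),
                                variants = g$variants)
  list(discovery = discovery, validation = validation, truth = truth)
}
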