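# Shared fixtures, built in code. The cache avoids re-simulating the same
# cohort across test files.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# Small genotype matrix with GQ/DP for IO and QC tests.
tiny_genotypes <- function() {
  dosage <- matrix(c(0, 1,
                     2, NA,
                     1, 0), nrow = 3, byrow = TRUE)
  variants <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                         pos = c(100L, 250L, 50L),
                         ref = c("A", "G", "T"), alt = c("T", "C", "A"),
                         rsid = c("rs1", NA, "rs3"))
  gq <- matrix(c(99, 55, 60, NA, 40, 80), nrow = 3, byrow = TRUE)
  dp <- matrix(c(10, 12, 8, NA, 30, 5), nrow = 3, byrow = TRUE)
  genotype_matrix(dosage, variants, c("S1", "S2"), gq = gq, dp = dp)
}

tiny_expression <- function(n_genes = 10, n_samples = 4, seed = 1) {
  set.seed(seed)
  genes <- data.frame(gene_id = sprintf("G%02d", seq_len(n_genes)),
                      chrom = "chr1",
                      tss = seq_len(n_genes) * 1000L)
  tpm <- matrix(round(rexp(n_genes * n_samples, 0.1), 3), n_genes, n_samples)
  counts <- matrix(rpois(n_genes * n_samples, 20), n_genes, n_samples)
  expression_matrix(tpm, genes, sprintf("S%d", seq_len(n_samples)),
                    counts = counts)
}

tiny_clinical <- function(samples, seed = 1) {
  set.seed(seed)
  n <- length(samples)
  clinical_table(data.frame(
    sample_id = samples,
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = sample(35:80, n, replace = TRUE),
    t_stage = sample(1:4, n, replace = TRUE),
    n_stage = sample(0:2, n, replace = TRUE),
    m_stage = sample(0:1, n, replace = TRUE),
    time = sample(30:4000, n, replace = TRUE),
    event = rbinom(n, 1, 0.6)))
}

# A modest simulated cohort shared by several test files (~60 samples).
small_cohort <- function() {
  cached("small_cohort", {
    cfg <- sim_config(n_samples = 80, n_genes = 50, n_variants = 400,
                      n_chrom = 2,
                      planted = data.frame(cluster = 1:3, gene = 1:3,
                                           beta = 1.5, gamma = c(1, 1, 0),
                                           replication = "strict"),
                      seed = 101)
    simulate_cohort(cfg)
  })
}

# Brute-force BH step-up used as an oracle against p.adjust-based paths.
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}
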