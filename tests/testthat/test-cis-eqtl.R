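test_that("cis pairing is inclusive at exactly 1 Mb on the same chromosome", {
  genes <- data.frame(gene_id = "G1", chrom = "chr1", tss = 1000000L)
  variants <- data.frame(variant_id = c("in", "out", "other"),
                         chrom = c("chr1", "chr1", "chr2"),
                         pos = c(2000000L, 2000001L, 2000000L))
  p <- cis_pairs(genes, variants)
  expect_equal(p$variant_id, "in")
  expect_equal(p$tss_distance, 1000000L)
})

test_that("the nominal scan matches the closed-form OLS oracle", {
  d <- c(0, 0, 1, 1, 2, 2)
  y <- c(1.0, 1.2, 1.4, 1.6, 1.9, 2.1)
  oracle <- summary(stats::lm(y ~ d))
  g <- genotype_matrix(matrix(d, 1), data.frame(chrom = "chr1", pos = 500,
                                                ref = "A", alt = "G"),
                       paste0("S", 1:6))
  pairs <- data.frame(gene_id = "G1", variant_id = g$variants$variant_id,
                      tss_distance = 400L)
  expr <- matrix(y, 1, dimnames = list("G1", paste0("S", 1:6)))
  rec <- nominal_scan(pairs, expr, g)$records
  expect_equal(rec$slope, 0.45)                       # Sxy/Sxx = 1.8/4
  expect_equal(rec$slope, unname(coef(oracle)[2, 1]), tolerance = 1e-12)
  expect_equal(rec$nominal_p, unname(coef(oracle)[2, 4]), tolerance = 1e-12)
  expect_equal(rec$nominal_p, 2 * pt(-abs(rec$slope / rec$slope_se), df = 4),
               tolerance = 1e-12)
})

test_that("covariate scan equals the full regression (Frisch-Waugh)", {
  set.seed(21)
  for (i in 1:10) {
    n <- 40
    d <- rbinom(n, 2, 0.3)
    C <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("c", 1:3)))
    y <- 0.5 * d + C %*% c(1, -1, 0.5) + rnorm(n)
    g <- genotype_matrix(matrix(d, 1), data.frame(chrom = "chr1", pos = 100,
                                                  ref = "A", alt = "G"),
                         sprintf("S%02d", 1:n))
    pairs <- data.frame(gene_id = "G1", variant_id = g$variants$variant_id,
                        tss_distance = 0L)
    expr <- matrix(as.numeric(y), 1, dimnames = list("G1", g$samples))
    rec <- nominal_scan(pairs, expr, g, covariates = C)$records
    full <- summary(stats::lm(y ~ d + C))
    expect_equal(rec$slope, unname(coef(full)["d", 1]), tolerance = 1e-8)
    expect_equal(rec$nominal_p, unname(coef(full)["d", 4]), tolerance = 1e-8)
  }
})

test_that("a dosage collinear with the covariates is skipped with a reason", {
  n <- 30
  d <- rbinom(n, 2, 0.4)
  g <- genotype_matrix(matrix(d, 1), data.frame(chrom = "chr1", pos = 100,
                                                ref = "A", alt = "G"),
                       sprintf("S%02d", 1:n))
  pairs <- data.frame(gene_id = "G1", variant_id = g$variants$variant_id,
                      tss_distance = 0L)
  expr <- matrix(rnorm(n), 1, dimnames = list("G1", g$samples))
  res <- nominal_scan(pairs, expr, g,
                      covariates = matrix(d, ncol = 1,
                                          dimnames = list(NULL, "same")))
  expect_null(res$records)
  expect_equal(nrow(res$skipped), 1L)
})

test_that("permutation empirical p-values are bounded and deterministic", {
  set.seed(31)
  n <- 50
  d <- matrix(rbinom(5 * n, 2, 0.3), 5, n,
              dimnames = list(paste0("v", 1:5), NULL))
  y <- rnorm(n)
  set.seed(1); a <- permutation_pass(y, d, min_perm = 500, max_perm = 1000)
  set.seed(1); b <- permutation_pass(y, d, min_perm = 500, max_perm = 1000)
  expect_identical(a, b)
  expect_gte(a$empirical_p, 1 / (a$n_perm + 1))
  expect_lte(a$empirical_p, 1)
  expect_true(a$beta_shape1 > 0 && a$beta_shape2 > 0)
})

test_that("tiny cohorts fall back to exhaustive permutation enumeration", {
  set.seed(33)
  d <- matrix(c(0, 0, 1, 1, 2, 2), 1, dimnames = list("v1", NULL))
  y <- c(0.1, 0.3, 0.2, 0.6, 0.5, 0.9)
  res <- permutation_pass(y, d, min_perm = 1000, max_perm = 10000)
  expect_equal(res$n_perm, factorial(6) - 1)   # all non-identity shuffles
})

test_that("eGene calling applies BH step-up to the gene-level p-values", {
  gr <- data.frame(gene_id = paste0("G", 1:4),
                   beta_approx_p = c(0.01, 0.02, 0.03, 0.04))
  out <- call_egenes(gr)
  expect_equal(out$qval, rep(0.04, 4))
  expect_true(all(out$egene))
  one <- call_egenes(data.frame(gene_id = "G1", beta_approx_p = 0.2))
  expect_equal(one$qval, 0.2)
  expect_false(one$egene)
  # BH equals a brute-force step-up on random vectors
  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(5:40, 1))^sample(1:3, 1)
    expect_equal(stats::p.adjust(p, "BH"), bh_brute_force(p),
                 tolerance = 1e-12)
  }
})

test_that("pair-level FDR counts unique eQTLs and their targets", {
  rec <- data.frame(gene_id = c("g1", "g2", "g3"),
                    variant_id = c("v1", "v1", "v2"),
                    nominal_p = c(1e-12, 1e-11, 1e-10))
  out <- call_significant_pairs(rec)
  expect_equal(out$n_unique_eqtls, 2L)
  expect_equal(unname(out$targets_per_eqtl["v1"]), 2L)
  one <- call_significant_pairs(data.frame(gene_id = "g", variant_id = "v",
                                           nominal_p = 1e-12))
  expect_true(one$pairs$significant)
})

test_that("the sensitivity screen applies the count-and-significance rule", {
  set.seed(41)
  # het = 2, homalt = 1, all models non-significant -> excluded
  d <- c(rep(0, 17), 1, 1, 2)
  y <- rnorm(20)
  s <- sensitivity_screen(y, d)
  expect_equal(s$het_count, 2L)
  expect_equal(s$homalt_count, 1L)
  if (all(na.omit(c(s$p_additive, s$p_dominant, s$p_recessive)) >= 0.05))
    expect_false(s$passed)
  # plenty of heterozygotes -> retained even when nothing is significant
  d2 <- c(rep(0, 30), rep(1, 50), rep(2, 20))
  s2 <- sensitivity_screen(rnorm(100), d2)
  expect_true(s2$passed)
  # a significant model retains the finding despite tiny counts
  d3 <- c(rep(0, 19), 1)
  y3 <- c(rnorm(19, 0, 0.1), 5)
  s3 <- sensitivity_screen(y3, d3)
  expect_true(s3$p_additive < 0.05)
  expect_true(s3$passed)
  # recessive recoding with no homalt carriers is reported as NA
  expect_true(is.na(s3$p_recessive))
})

test_that("cis mapping recovers planted effects in a small cohort", {
  co <- small_cohort()
  truth <- attr(co, "truth")
  co$genotypes <- filter_variants(co$genotypes)$genotypes
  co$expression <- filter_genes(co$expression)
  cov <- cohort_covariates(co, n_pcs = 3, n_factors = 5)
  res <- map_cis_eqtls(co, cov, seed = 9, min_perm = 500, max_perm = 2000)
  found <- truth$gene_id %in% res$genes$gene_id[res$genes$egene]
  expect_gte(sum(found), 2)
  expect_true(all(res$genes$empirical_p >= 1 / (res$genes$n_perm + 1)))
  expect_true(all(res$genes$empirical_p <= 1))
})
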