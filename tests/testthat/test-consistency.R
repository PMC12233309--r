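test_that("the pair-consistency truth table holds in all eight cases", {
  for (gd in c("favourable", "unfavourable")) {
    for (sl in c(1, -1)) {
      for (vd in c("favourable", "unfavourable")) {
        cls <- classify_pair(gd, sl, vd)
        pred_sign <- ifelse(gd == "favourable", 1, -1) * sl
        predicted <- ifelse(pred_sign > 0, "favourable", "unfavourable")
        expect_equal(cls$consistent, predicted == vd)
      }
    }
  }
  expect_error(classify_pair("favourable", 0, "favourable"), "zero")
})

test_that("reported locus examples classify as consistent", {
  # unfavourable gene, negative slope -> protective ALT allele
  a <- classify_pair("unfavourable", -0.470105, "favourable")
  expect_true(a$consistent)
  # favourable gene, negative slope -> risk ALT allele
  b <- classify_pair("favourable", -0.854169, "unfavourable")
  expect_true(b$consistent)
  c3 <- classify_pair("favourable", 1, "unfavourable")
  expect_false(c3$consistent)
})

mk_vrec <- function(entity, coef, p, inheritance = "allelic",
                    adjusted = FALSE, term = "dosage") {
  data.frame(entity = entity, level = "variant", inheritance = inheritance,
             adjusted = adjusted, term = term, coef = coef,
             wald_p = p, stringsAsFactors = FALSE)
}

test_that("variant direction uses the homozygous contrast when present", {
  rec <- rbind(mk_vrec("v1", -0.2, 0.01, "codominant", FALSE, "het"),
               mk_vrec("v1", 0.5, 0.02, "codominant", FALSE, "hom"))
  cls <- classify_pair("favourable", 1, rec)
  expect_equal(cls$variant_direction, "unfavourable")  # hom coef wins
  # the het contrast is not used for direction once hom is present
  expect_false(cls$direction_conflict)
})

test_that("enumeration keeps exactly the constructed consistent pairs", {
  genes <- paste0("g", 1:10)
  prog <- structure(list(
    union_set = genes,
    direction = stats::setNames(rep(c("favourable", "unfavourable"), 5),
                                genes)), class = "prognostic_sets")
  # pairs 1-5 consistent by construction, 6-10 inconsistent; with slope +1
  # the predicted variant direction equals the gene direction, and a
  # favourable variant direction means a negative Cox coefficient
  slope <- rep(1, 10)
  pred <- ifelse(unname(prog$direction) == "favourable", 1, -1)
  coef <- -0.5 * pred          # matching direction for every pair
  coef[6:10] <- -coef[6:10]    # then break pairs 6-10
  vrec <- do.call(rbind, lapply(1:10, function(i)
    mk_vrec(paste0("v", i), coef[i], 0.01)))
  sp <- data.frame(gene_id = genes, variant_id = paste0("v", 1:10),
                   slope = slope)
  res <- enumerate_consistent(prog, sp, vrec)
  expect_equal(res$summary[["n_pairs"]], 5L)
  expect_setequal(res$consistent$gene_id, genes[1:5])
  # counting inequality: pairs >= max(genes, eqtls)
  expect_gte(res$summary[["n_pairs"]],
             max(res$summary[["n_genes"]], res$summary[["n_eqtls"]]))
  # empty prognostic set -> empty output
  prog0 <- structure(list(union_set = character(0), direction = character(0)),
                     class = "prognostic_sets")
  expect_equal(nrow(enumerate_consistent(prog0, sp, vrec)$pairs), 0L)
})

test_that("variant matching harmonizes allele swaps by flipping dosage", {
  v <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                  pos = c(100L, 200L, 300L),
                  ref = c("A", "T", "G"), alt = c("G", "A", "C"))
  d <- matrix(c(0, 1, 2,
                2, 1, 0,
                1, 1, 1), 3, byrow = TRUE)
  gm <- genotype_matrix(d, v, c("S1", "S2", "S3"))
  mm <- match_variants(c("chr1_100_A_G",      # exact
                         "chr1_200_A_T",      # swap of chr1_200_T_A
                         "chr2_300_G_T"),     # different alt -> unmatched
                       gm)
  expect_equal(mm$matched, c(TRUE, TRUE, FALSE))
  expect_equal(mm$flipped, c(FALSE, TRUE, FALSE))
  dos <- attr(mm, "dosage")
  expect_equal(unname(dos["chr1_100_A_G", ]), c(0, 1, 2))
  expect_equal(unname(dos["chr1_200_A_T", ]), c(0, 1, 2))  # 2 - (2,1,0)
})

test_that("replication tiers follow the significance and direction rules", {
  d <- mk_vrec("v", 0.5, 0.01)
  expect_equal(classify_tier(d, mk_vrec("v", 0.3, 0.01)), "strict")
  expect_equal(classify_tier(d, mk_vrec("v", 0.3, 0.2)), "lenient")
  expect_equal(classify_tier(d, mk_vrec("v", -0.3, 0.01)), "discordant")
  # codominant model: significance on the hom contrast suffices
  d2 <- rbind(mk_vrec("v", 0.4, 0.03, "codominant", FALSE, "het"),
              mk_vrec("v", 0.8, 0.04, "codominant", FALSE, "hom"))
  v2 <- rbind(mk_vrec("v", 0.1, 0.50, "codominant", FALSE, "het"),
              mk_vrec("v", 0.9, 0.01, "codominant", FALSE, "hom"))
  expect_equal(classify_tier(d2, v2), "strict")
})

test_that("LD r-squared behaves as a squared correlation", {
  expect_equal(ld_r2(c(0, 0, 1, 1, 2), c(0, 0, 1, 1, 2)), 1)
  expect_equal(ld_r2(c(0, 0, 1, 1, 2), c(2, 2, 1, 1, 0)), 1)
  a <- c(0, 1, 2, 0, 1, 2, 1, 0)
  b <- c(0, 1, 1, 0, 2, 2, 0, 1)
  expect_equal(ld_r2(a, b), ld_r2(2 - a, b))
  expect_error(ld_r2(c(0, 1), c(1, 0)), "5")
  expect_error(ld_r2(rep(1, 6), c(0, 1, 2, 0, 1, 2)), "variance")
})

test_that("locus clustering is single-linkage over the r-squared graph", {
  set.seed(12)
  n <- 40
  base <- rbinom(n, 2, 0.5)
  noisy <- function(p) ifelse(runif(n) < p, sample(0:2, n, TRUE), base)
  d <- rbind(a = base, b = noisy(0.1), c = noisy(0.2),
             ind = rbinom(n, 2, 0.5))
  cl <- cluster_loci(d, threshold = 0.1)
  expect_equal(cl[["a"]], cl[["b"]])
  expect_equal(cl[["a"]], cl[["c"]])
  expect_false(cl[["ind"]] == cl[["a"]])
  # equals brute-force connected components on random variants
  set.seed(13)
  d2 <- matrix(rbinom(20 * 30, 2, 0.4), 20, 30,
               dimnames = list(paste0("v", 1:20), NULL))
  cl2 <- cluster_loci(d2, threshold = 0.1)
  r2 <- suppressWarnings(cor(t(d2))^2)
  adj <- !is.na(r2) & r2 >= 0.1
  # BFS components as an independent oracle
  comp <- rep(0L, 20)
  cur <- 0L
  for (i in 1:20) {
    if (comp[i] > 0) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0))
    }
  }
  expect_equal(length(unique(cl2)), length(unique(comp)))
  expect_true(all(tapply(comp, cl2, function(x) length(unique(x))) == 1))
})

test_that("allele flips leave consistency and tier verdicts unchanged", {
  # flipping a variant (dosage -> 2 - d) flips the eQTL slope and every Cox
  # coefficient; the verdicts must not move
  set.seed(19)
  slope <- 0.8
  vrec <- mk_vrec("v", 0.6, 0.01)
  orig <- classify_pair("unfavourable", slope, vrec)
  flip <- classify_pair("unfavourable", -slope, mk_vrec("v", -0.6, 0.01))
  expect_equal(orig$consistent, flip$consistent)
  d <- mk_vrec("v", 0.5, 0.01)
  v_ok <- mk_vrec("v", 0.3, 0.02)
  expect_equal(classify_tier(d, v_ok),
               classify_tier(mk_vrec("v", -0.5, 0.01),
                             mk_vrec("v", -0.3, 0.02)))
  # end-to-end on data: flipped dosage gives mirrored Cox coefficient
  cl <- tiny_clinical(sprintf("S%02d", 1:60), seed = 31)
  dv <- rbinom(60, 2, 0.4)
  a <- variant_survival(dv, cl)
  b <- variant_survival(2 - dv, cl)
  expect_equal(b$coef, -a$coef, tolerance = 1e-6)
  expect_equal(b$wald_p, a$wald_p, tolerance = 1e-8)
})
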