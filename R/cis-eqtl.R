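#' Enumerate candidate cis gene-variant pairs
#'
#' A pair is cis when the variant lies on the gene's chromosome within the
#' mapping window of the transcription start site, boundary inclusive.
#' Distances are signed (variant position - TSS).
#'
#' @param genes `data.frame` with `gene_id`, `chrom`, `tss`.
#' @param variants `data.frame` with `variant_id`, `chrom`, `pos`.
#' @param window Window half-width in bases (default 1 Mb).
#' @return `data.frame` with `gene_id`, `variant_id`, `tss_distance`.
#' @export
cis_pairs <- function(genes, variants, window = 1e6) {
  out <- vector("list", nrow(genes))
  by_chrom <- split(seq_len(nrow(variants)), variants$chrom)
  for (i in seq_len(nrow(genes))) {
    vi <- by_chrom[[genes$chrom[i]]]
    if (is.null(vi)) next
    dist <- variants$pos[vi] - genes$tss[i]
    sel <- abs(dist) <= window
    if (!any(sel)) next
    out[[i]] <- data.frame(gene_id = genes$gene_id[i],
                           variant_id = variants$variant_id[vi[sel]],
                           tss_distance = dist[sel],
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(), variant_id = character(),
                      tss_distance = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Projection residuals on [1, C]; returns a function mapping matrix/vector
# (samples in rows for matrices) to residuals.
residualizer <- function(n, covariates = NULL) {
  x <- if (is.null(covariates)) matrix(1, n, 1) else cbind(1, unclass(covariates))
  q <- qr.Q(qr(x))
  function(y) {
    y <- as.matrix(y)
    y - q %*% crossprod(q, y)
  }
}

# Simple-regression statistics of y on each column of a centered matrix.
slope_stats <- function(d_centered, y_resid, df) {
  sxx <- colSums(d_centered^2)
  sxy <- drop(crossprod(d_centered, y_resid))
  syy <- sum(y_resid^2)
  slope <- sxy / sxx
  rss <- pmax(syy - slope * sxy, 0)
  se <- sqrt(rss / (df * sxx))
  tval <- slope / se
  p <- 2 * stats::pt(-abs(tval), df)
  list(slope = slope, se = se, p = p, sxx = sxx)
}

#' Nominal cis-eQTL scan
#'
#' Ordinary least squares of expression on mean-imputed ALT dosage plus
#' covariates, computed by residualizing both expression and dosage on the
#' covariates first (Frisch-Waugh equivalence with the full regression; the
#' t test uses residual df `n - 2 - n_covariates`). Pairs whose dosage has
#' zero variance after imputation are skipped with a reason.
#'
#' @param pairs `data.frame` from [cis_pairs()].
#' @param expr Genes x samples numeric matrix of mapping phenotypes
#'   (e.g. inverse-normal transformed TPM), rownames = gene ids.
#' @param geno A [genotype_matrix()] (dosages are mean-imputed internally).
#' @param covariates Optional samples x k covariate matrix.
#' @return A list with `records` (one row per tested pair: `gene_id`,
#'   `variant_id`, `tss_distance`, `maf`, `slope`, `slope_se`, `nominal_p`,
#'   `n`) and `skipped` (`data.frame` of untested pairs with reasons).
#' @export
nominal_scan <- function(pairs, expr, geno, covariates = NULL) {
  n <- ncol(expr)
  k <- if (is.null(covariates)) 0 else ncol(covariates)
  df <- n - 2 - k
  if (df < 1) stop("not enough samples for the covariate count")
  res <- residualizer(n, covariates)
  maf_all <- apply(geno$dosage, 1, minor_allele_frequency)
  dmat <- t(apply(geno$dosage, 1, mean_impute_dosage))
  rownames(dmat) <- rownames(geno$dosage)
  dres <- res(t(dmat))                      # samples x variants residuals
  colnames(dres) <- rownames(dmat)
  eres <- res(t(expr))                      # samples x genes residuals
  colnames(eres) <- rownames(expr)
  recs <- vector("list", 0)
  skipped <- vector("list", 0)
  for (gene in unique(pairs$gene_id)) {
    pg <- pairs[pairs$gene_id == gene, , drop = FALSE]
    dg <- dres[, pg$variant_id, drop = FALSE]
    dg <- sweep(dg, 2, colMeans(dg))
    st <- slope_stats(dg, eres[, gene], df)
    ok <- st$sxx > n * 1e-12
    if (any(!ok))
      skipped[[length(skipped) + 1]] <- data.frame(
        gene_id = gene, variant_id = pg$variant_id[!ok],
        reason = "zero dosage variance after covariate residualization",
        stringsAsFactors = FALSE)
    if (any(ok))
      recs[[length(recs) + 1]] <- data.frame(
        gene_id = gene, variant_id = pg$variant_id[ok],
        tss_distance = pg$tss_distance[ok],
        maf = unname(maf_all[pg$variant_id[ok]]),
        slope = st$slope[ok], slope_se = st$se[ok],
        nominal_p = st$p[ok], n = n, stringsAsFactors = FALSE)
  }
  empty_skip <- data.frame(gene_id = character(), variant_id = character(),
                           reason = character(), stringsAsFactors = FALSE)
  list(records = if (length(recs)) do.call(rbind, recs) else NULL,
       skipped = if (length(skipped)) do.call(rbind, skipped) else empty_skip)
}

# All permutations of 1..n (n small), as a matrix with one permutation per row.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# Beta(a, b) maximum-likelihood fit with method-of-moments fallback.
fit_beta <- function(p) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  m <- mean(p); v <- stats::var(p)
  v <- max(min(v, m * (1 - m) * 0.999), 1e-10)
  scale0 <- m * (1 - m) / v - 1
  start <- log(c(m * scale0, (1 - m) * scale0))
  nll <- function(ls) -sum(stats::dbeta(p, exp(ls[1]), exp(ls[2]), log = TRUE))
  fit <- tryCatch(stats::optim(start, nll, method = "L-BFGS-B",
                               lower = log(1e-6), upper = log(1e6)),
                  error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value)) exp(start) else exp(fit$par)
}

#' Adaptive permutation pass for one gene
#'
#' Covariate-residualized expression is shuffled across samples with a seeded
#' generator; each permutation records the minimum nominal p over the gene's
#' cis variants. Permutations run in blocks until at least 100 permutation
#' minima fall at or below the observed minimum (adaptive stop) or `max_perm`
#' is reached, with at least `min_perm` performed. The gene-level empirical
#' p-value is `(r + 1) / (m + 1)`; a Beta distribution fitted by maximum
#' likelihood to the permutation minima gives the smoothed
#' `beta_approx_p = P(Beta(a, b) <= observed minimum)`. When fewer than
#' `min_perm` distinct shuffles exist (tiny n) every non-identity permutation
#' is enumerated instead.
#'
#' @param y Expression vector for the gene (one value per sample).
#' @param dosages Variants x samples dosage matrix of the gene's cis
#'   variants (rownames = variant ids; mean-imputed internally).
#' @param covariates Optional samples x k covariate matrix.
#' @param min_perm,max_perm Permutation bounds (defaults 1000 and 10000).
#' @param stop_exceed Adaptive stopping count (default 100 exceedances).
#' @return A one-row `data.frame`: `top_variant`, `nominal_p` (observed
#'   minimum), `empirical_p`, `beta_shape1`, `beta_shape2`, `beta_approx_p`,
#'   `n_perm`.
#' @export
permutation_pass <- function(y, dosages, covariates = NULL,
                             min_perm = 1000, max_perm = 10000,
                             stop_exceed = 100) {
  if (is.null(dim(dosages))) dosages <- matrix(dosages, nrow = 1)
  n <- length(y)
  k <- if (is.null(covariates)) 0 else ncol(covariates)
  df <- n - 2 - k
  res <- residualizer(n, covariates)
  imp <- apply(dosages, 1, mean_impute_dosage)   # samples x variants
  if (is.null(dim(imp))) imp <- matrix(imp, ncol = 1)
  dres <- res(imp)
  dres <- sweep(dres, 2, colMeans(dres))
  keep <- colSums(dres^2) > n * 1e-12
  if (!any(keep)) stop("no cis variant with non-zero dosage variance")
  dres <- dres[, keep, drop = FALSE]
  ids <- rownames(dosages)[keep]
  yr <- drop(res(y))
  dn <- sweep(dres, 2, sqrt(colSums(dres^2)), "/")
  yn <- yr / sqrt(sum(yr^2))
  # |correlation| -> two-sided p at fixed df is monotone, so the permutation
  # minimum p corresponds to the maximum |r|
  r_obs <- drop(crossprod(dn, yn))
  p_obs <- 2 * stats::pt(-abs(r_obs) * sqrt(df / pmax(1 - r_obs^2, 1e-300)), df)
  top <- which.min(p_obs)
  r_to_p <- function(r) {
    2 * stats::pt(-abs(r) * sqrt(df / pmax(1 - r^2, 1e-300)), df)
  }
  # Permuted phenotypes are re-residualized on the covariates so that the
  # permuted correlations live in the same covariate-orthogonal subspace as
  # the observed one; without this the observed statistic is stochastically
  # larger than the permuted ones and the empirical p is anti-conservative.
  perm_min_p <- function(pm) {
    pm <- res(t(pm))                       # samples x B residuals
    pm <- sweep(pm, 2, sqrt(colSums(pm^2)), "/")
    rmax <- apply(abs(crossprod(pm, dn)), 1, max)
    r_to_p(rmax)
  }
  exhaustive <- factorial(n) <= min_perm
  if (exhaustive) {
    perms <- all_permutations(n)
    perms <- perms[-1, , drop = FALSE]    # drop the identity
    pmin_perm <- perm_min_p(matrix(yn[t(perms)], ncol = n, byrow = TRUE))
  } else {
    pmin_perm <- numeric(0)
    block <- 200L
    while (TRUE) {
      pm <- matrix(yn[vapply(seq_len(block), function(i) sample.int(n),
                             integer(n))], ncol = n, byrow = TRUE)
      pmin_perm <- c(pmin_perm, perm_min_p(pm))
      m <- length(pmin_perm)
      exceed <- sum(pmin_perm <= p_obs[top])
      if ((m >= min_perm && exceed >= stop_exceed) || m >= max_perm) break
    }
  }
  m <- length(pmin_perm)
  r_exceed <- sum(pmin_perm <= p_obs[top])
  shapes <- fit_beta(pmin_perm)
  data.frame(top_variant = ids[top], nominal_p = p_obs[top],
             empirical_p = (r_exceed + 1) / (m + 1),
             beta_shape1 = shapes[1], beta_shape2 = shapes[2],
             beta_approx_p = stats::pbeta(p_obs[top], shapes[1], shapes[2]),
             n_perm = m, stringsAsFactors = FALSE)
}

#' Call eGenes from gene-level permutation results
#'
#' Benjamini-Hochberg q-values on the beta-approximated gene-level p-values;
#' a gene is an eGene when its q-value is below `fdr`.
#'
#' @param gene_results `data.frame` with one row per gene containing
#'   `beta_approx_p`.
#' @param fdr FDR threshold (default 0.05).
#' @return The input with `qval` and logical `egene` columns appended.
#' @export
call_egenes <- function(gene_results, fdr = 0.05) {
  gene_results$qval <- stats::p.adjust(gene_results$beta_approx_p, "BH")
  gene_results$egene <- gene_results$qval < fdr
  gene_results
}

#' Call significant cis pairs
#'
#' Benjamini-Hochberg correction across all nominally tested pairs jointly;
#' a pair is significant when its q-value is below `fdr`. Also summarizes the
#' unique-eQTL count and per-eQTL target-gene counts.
#'
#' @param records Pair-level `data.frame` from [nominal_scan()].
#' @param fdr FDR threshold (default 0.05).
#' @return A list with `pairs` (all records with `qval`, `significant`),
#'   `significant` (the significant subset), `n_unique_eqtls` and
#'   `targets_per_eqtl` (named vector over significant eQTLs).
#' @export
call_significant_pairs <- function(records, fdr = 0.05) {
  records$qval <- stats::p.adjust(records$nominal_p, "BH")
  records$significant <- records$qval < fdr
  sig <- records[records$significant, , drop = FALSE]
  targets <- if (nrow(sig)) table(sig$variant_id) else table(character(0))
  list(pairs = records, significant = sig,
       n_unique_eqtls = length(targets),
       targets_per_eqtl = c(targets))
}

#' Inheritance-model sensitivity screen for a top association
#'
#' Regresses expression on three genotype recodings - additive (0,1,2),
#' dominant (0,1,1) and recessive (0,0,1) - using simple linear regression on
#' hard-called genotypes (imputed dosages rounded to the nearest of 0, 1, 2).
#' A recoding with zero variance yields `NA` for that model. The finding
#' fails the screen (is excluded) only when every tested model has p >= 0.05
#' AND both the heterozygous and homozygous-ALT groups have fewer than three
#' samples.
#'
#' @param y Expression vector.
#' @param dosages Dosage vector for the variant.
#' @return One-row `data.frame`: `p_additive`, `p_dominant`, `p_recessive`,
#'   `het_count`, `homalt_count`, `passed`.
#' @export
sensitivity_screen <- function(y, dosages) {
  hard <- pmin(pmax(round(mean_impute_dosage(dosages)), 0), 2)
  het <- sum(hard == 1)
  homalt <- sum(hard == 2)
  codes <- list(additive = hard,
                dominant = as.numeric(hard >= 1),
                recessive = as.numeric(hard == 2))
  pvals <- vapply(codes, function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    xc <- x - mean(x)
    st <- slope_stats(matrix(xc, ncol = 1), y - mean(y), length(y) - 2)
    st$p
  }, numeric(1))
  tested <- pvals[!is.na(pvals)]
  none_significant <- length(tested) == 0 || all(tested >= 0.05)
  passed <- !(none_significant && het < 3 && homalt < 3)
  data.frame(p_additive = pvals[["additive"]],
             p_dominant = pvals[["dominant"]],
             p_recessive = pvals[["recessive"]],
             het_count = het, homalt_count = homalt, passed = passed)
}

#' Full cis-eQTL mapping for an aligned cohort
#'
#' Orchestrates the mapping stage: builds the mapping phenotype (rank-based
#' inverse-normal transformed TPM by default), enumerates cis pairs, runs the
#' nominal scan, the per-gene adaptive permutation pass, eGene calling, joint
#' pair-level FDR, and the inheritance-model sensitivity screen on each
#' eGene's top variant. Deterministic given `seed`.
#'
#' @param cohort A `cohort` from [align_cohort()] or [simulate_cohort()].
#' @param covariates Optional samples x k covariate matrix
#'   (see [cohort_covariates()]).
#' @param window Cis window half-width (default 1 Mb).
#' @param fdr FDR threshold for eGenes and pairs (default 0.05).
#' @param inverse_normal Use the rank-based inverse-normal transform of TPM as
#'   the mapping phenotype (default TRUE); otherwise `log(TPM + 1)`.
#' @param min_perm,max_perm Permutation bounds per gene.
#' @param seed Integer seed for the permutation generator.
#' @return A list with `genes` (gene-level results with q-values, eGene flags
#'   and sensitivity columns), `pairs`, `significant_pairs`,
#'   `n_unique_eqtls`, `targets_per_eqtl` and `skipped`.
#' @export
map_cis_eqtls <- function(cohort, covariates = NULL, window = 1e6,
                          fdr = 0.05, inverse_normal = TRUE,
                          min_perm = 1000, max_perm = 10000, seed = 1L) {
  e <- cohort$expression
  g <- cohort$genotypes
  phen <- if (inverse_normal) inverse_normal_transform(e$tpm) else log1p(e$tpm)
  dimnames(phen) <- dimnames(e$tpm)
  pairs <- cis_pairs(e$genes, g$variants, window = window)
  scan <- nominal_scan(pairs, phen, g, covariates)
  if (is.null(scan$records)) stop("no testable cis pairs")
  set.seed(seed)
  genes <- unique(scan$records$gene_id)
  glist <- lapply(genes, function(gene) {
    vids <- scan$records$variant_id[scan$records$gene_id == gene]
    pp <- permutation_pass(phen[gene, ], g$dosage[vids, , drop = FALSE],
                           covariates, min_perm = min_perm,
                           max_perm = max_perm)
    cbind(gene_id = gene, pp, stringsAsFactors = FALSE)
  })
  gene_res <- call_egenes(do.call(rbind, glist), fdr = fdr)
  sens <- do.call(rbind, lapply(seq_len(nrow(gene_res)), function(i) {
    sensitivity_screen(phen[gene_res$gene_id[i], ],
                       g$dosage[gene_res$top_variant[i], ])
  }))
  gene_res <- cbind(gene_res, sens)
  sig <- call_significant_pairs(scan$records, fdr = fdr)
  list(genes = gene_res, pairs = sig$pairs, significant_pairs = sig$significant,
       n_unique_eqtls = sig$n_unique_eqtls,
       targets_per_eqtl = sig$targets_per_eqtl, skipped = scan$skipped)
}
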