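#' TMM normalization of read counts
#'
#' Computes trimmed-mean-of-M-values scaling factors between samples
#' (delegating to edgeR's implementation, trim fractions 0.3 on M-values and
#' 0.05 on A-values, reference = sample whose count sum is closest to the
#' median) and returns counts-per-million on the effective library sizes.
#' Factors have geometric mean 1.
#'
#' @param counts Nonnegative count matrix, genes x samples (>= 2 samples).
#' @return A list with `factors` (per-sample scaling factors) and
#'   `normalized` (CPM matrix on effective library sizes).
#' @export
tmm_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs at least two samples")
  libsize <- colSums(counts)
  if (any(libsize == 0)) stop("sample(s) with all-zero counts: ",
                              paste(colnames(counts)[libsize == 0], collapse = ", "))
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  eff <- libsize * f
  normalized <- t(t(counts) / eff) * 1e6
  list(factors = f, normalized = normalized)
}

#' Expression-threshold gene filter
#'
#' Keeps a gene iff TPM exceeds `tpm_threshold` in at least
#' `min_fraction` of samples AND its read count is at least
#' `count_threshold` in at least `min_fraction` of samples.
#'
#' @param e An [expression_matrix()] with both TPM and counts.
#' @param tpm_threshold TPM cut (exclusive), default 0.1.
#' @param count_threshold Count cut (inclusive), default 6.
#' @param min_fraction Required fraction of samples, default 0.2.
#' @return The filtered [expression_matrix()].
#' @export
filter_genes <- function(e, tpm_threshold = 0.1, count_threshold = 6,
                         min_fraction = 0.2) {
  if (is.null(e$counts)) stop("filter_genes needs both TPM and counts")
  n <- length(e$samples)
  keep <- rowMeans(e$tpm > tpm_threshold) >= min_fraction &
    rowMeans(e$counts >= count_threshold) >= min_fraction
  expression_matrix(e$tpm[keep, , drop = FALSE],
                    e$genes[keep, , drop = FALSE], e$samples,
                    counts = e$counts[keep, , drop = FALSE])
}

#' Rank-based inverse-normal transform
#'
#' Maps each row of a matrix (or a vector) to normal scores
#' `qnorm((rank - 0.5) / n)`, the convention of standard QTL pipelines; ties
#' get average ranks.
#'
#' @param x Numeric vector or matrix (rows transformed independently).
#' @return Object of the same shape.
#' @export
inverse_normal_transform <- function(x) {
  f <- function(v) stats::qnorm((rank(v, ties.method = "average") - 0.5) / length(v))
  if (is.matrix(x)) t(apply(x, 1, f)) else f(x)
}

pca_signed <- function(mat, k) {
  # rows = features, columns = samples; returns samples x k scores with a
  # deterministic sign convention (largest-magnitude loading positive)
  x <- scale(t(mat))  # samples x features, each feature standardized
  sv <- svd(x, nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- colnames(mat)
  scores
}

#' Latent expression factors
#'
#' Top-k principal components of the standardized expression matrix, used as
#' hidden-confounder covariates in the cis regression (a transparent,
#' deterministic proxy for factor-analysis methods such as PEER). Sign
#' convention: the largest-magnitude score of each component is positive.
#'
#' @param e An [expression_matrix()] or a genes x samples numeric matrix.
#' @param k Number of factors (default 15); must be < min(genes, samples).
#' @param log_transform Take `log(TPM + 1)` before standardizing (default
#'   TRUE; ignored when `e` is already a plain matrix).
#' @return A samples x k matrix of factor scores.
#' @export
latent_factors <- function(e, k = 15, log_transform = TRUE) {
  mat <- if (inherits(e, "expression_matrix")) {
    if (log_transform) log1p(e$tpm) else e$tpm
  } else as.matrix(e)
  if (k <= 0) stop("k must be positive")
  if (k >= min(dim(mat))) stop("k must be < min(genes, samples)")
  keep <- apply(mat, 1, stats::sd) > 0
  scores <- pca_signed(mat[keep, , drop = FALSE], k)
  colnames(scores) <- paste0("factor", seq_len(k))
  scores
}

#' Genotype principal components
#'
#' PCA of the mean-imputed, per-variant standardized dosage matrix, the
#' standard population-stratification covariates. Monomorphic variants
#' (zero variance after imputation) are dropped before standardization.
#'
#' @param g A [genotype_matrix()].
#' @param k Number of components (default 5).
#' @return A samples x k matrix of PC scores.
#' @export
genotype_pcs <- function(g, k = 5) {
  d <- t(apply(g$dosage, 1, mean_impute_dosage))
  keep <- apply(d, 1, stats::sd) > 0
  if (sum(keep) < k)
    stop("fewer non-monomorphic variants (", sum(keep), ") than requested PCs")
  pca_signed(d[keep, , drop = FALSE], k)
}

#' Assemble the covariate matrix for cis-eQTL mapping
#'
#' Binds genotype PCs, latent expression factors and the numeric clinical
#' encodings: sex male = 1 / female = 0, age dichotomized at 50
#' (> 50 -> 1), and T (1-4), N (0-2), M (0-1) as integers. The result must
#' have full column rank (asserted) and no missing values.
#'
#' @param pcs Samples x k matrix from [genotype_pcs()].
#' @param factors Samples x k matrix from [latent_factors()].
#' @param clinical A [clinical_table()] in the same sample order.
#' @return A samples x covariates numeric matrix of class `covariate_matrix`.
#' @export
assemble_covariates <- function(pcs, factors, clinical) {
  stopifnot(nrow(pcs) == nrow(clinical), nrow(factors) == nrow(clinical))
  need <- c("sex", "age", "t_stage", "n_stage", "m_stage")
  for (f in need) {
    if (any(is.na(clinical[[f]])))
      stop("missing clinical ", f, " for samples: ",
           paste(clinical$sample_id[is.na(clinical[[f]])], collapse = ", "))
  }
  clin <- cbind(sex = as.numeric(clinical$sex == "male"),
                age_group = as.numeric(clinical$age > 50),
                t_stage = clinical$t_stage,
                n_stage = clinical$n_stage,
                m_stage = clinical$m_stage)
  x <- cbind(pcs, factors, clin)
  rownames(x) <- clinical$sample_id
  const <- apply(x, 2, function(v) stats::sd(v) == 0)
  if (any(const))
    stop("constant covariate column(s): ",
         paste(colnames(x)[const], collapse = ", "))
  if (qr(cbind(1, x))$rank < ncol(x) + 1)
    stop("covariate matrix is rank deficient")
  class(x) <- c("covariate_matrix", class(x))
  x
}

#' Default covariates for a cohort
#'
#' Convenience wrapper computing genotype PCs and latent expression factors
#' from an aligned cohort and assembling them with the clinical encodings.
#'
#' @param cohort A `cohort` from [align_cohort()].
#' @param n_pcs,n_factors Component counts (defaults 5 and 15).
#' @return A `covariate_matrix`.
#' @export
cohort_covariates <- function(cohort, n_pcs = 5, n_factors = 15) {
  pcs <- genotype_pcs(cohort$genotypes, k = n_pcs)
  fac <- latent_factors(cohort$expression, k = n_factors)
  assemble_covariates(pcs, fac, cohort$clinical)
}
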