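#' Genotype quality-control thresholds
#'
#' Post-calling filters applied before cis-eQTL mapping: genotype-level
#' masking on recalculated genotype quality (GQ) and read depth (DP), then
#' variant-level removal of monomorphic sites, high-missingness sites and
#' low-frequency sites.
#'
#' @param maf_min Variants with minor allele frequency `<= maf_min` are
#'   removed (retain iff MAF strictly above the bound).
#' @param max_missing_fraction Variants with genotype missingness strictly
#'   above this fraction are removed.
#' @param gq_min Genotypes with GQ below this value are set missing.
#' @param dp_min Genotypes with DP below this value are set missing.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.01, max_missing_fraction = 0.25,
                          gq_min = 20, dp_min = 3) {
  stopifnot(is.finite(maf_min), is.finite(max_missing_fraction),
            max_missing_fraction >= 0, max_missing_fraction <= 1,
            maf_min >= 0, maf_min <= 1)
  structure(list(maf_min = maf_min,
                 max_missing_fraction = max_missing_fraction,
                 gq_min = gq_min, dp_min = dp_min),
            class = "qc_thresholds")
}

#' Mask low-quality genotypes
#'
#' Sets individual genotype calls to missing when GQ < `gq_min` or
#' DP < `dp_min`. The variant count is unchanged; only the unqualified
#' genotypes become missing. Absent GQ/DP matrices leave the dosages
#' untouched.
#'
#' @param g A [genotype_matrix()] carrying GQ and/or DP.
#' @param t A [qc_thresholds()].
#' @return The masked [genotype_matrix()].
#' @export
mask_low_quality_genotypes <- function(g, t = qc_thresholds()) {
  d <- g$dosage
  if (!is.null(g$gq)) d[!is.na(g$gq) & g$gq < t$gq_min] <- NA_real_
  if (!is.null(g$dp)) d[!is.na(g$dp) & g$dp < t$dp_min] <- NA_real_
  genotype_matrix(d, g$variants, g$samples, gq = g$gq, dp = g$dp)
}

#' Allele frequencies from dosages
#'
#' `alt_allele_frequency()` is the ALT-allele count divided by twice the
#' number of non-missing genotypes; `minor_allele_frequency()` folds it to
#' `min(f, 1 - f)`.
#'
#' @param dosages Numeric vector of dosages in `{0, 1, 2, NA}`.
#' @return A frequency in `[0, 1]` (`[0, 0.5]` for the MAF).
#' @export
alt_allele_frequency <- function(dosages) {
  ok <- !is.na(dosages)
  if (!any(ok)) stop("all dosages missing")
  sum(dosages[ok]) / (2 * sum(ok))
}

#' @rdname alt_allele_frequency
#' @export
minor_allele_frequency <- function(dosages) {
  f <- alt_allele_frequency(dosages)
  min(f, 1 - f)
}

#' Variant-level filtering
#'
#' Removes variants that are monomorphic (no called ALT allele), have a
#' missing-genotype fraction above `max_missing_fraction`, or have minor
#' allele frequency at or below `maf_min`. Each removed variant is tagged
#' with the first triggering reason, checked in the order monomorphic,
#' missingness, MAF. Apply [mask_low_quality_genotypes()] first so the
#' filters see the post-masking data.
#'
#' @param g A [genotype_matrix()].
#' @param t A [qc_thresholds()].
#' @return A list with `genotypes` (the retained [genotype_matrix()]) and
#'   `exclusions` (`data.frame` of `variant_id`, `reason`).
#' @export
filter_variants <- function(g, t = qc_thresholds()) {
  d <- g$dosage
  n_missing <- rowSums(is.na(d))
  n_called <- ncol(d) - n_missing
  ac <- rowSums(d, na.rm = TRUE)
  all_missing <- n_called == 0
  miss_frac <- n_missing / ncol(d)
  maf <- ifelse(all_missing, NA,
                pmin(ac / (2 * pmax(n_called, 1)),
                     1 - ac / (2 * pmax(n_called, 1))))
  reason <- rep(NA_character_, nrow(d))
  reason[all_missing | ac == 0] <- "monomorphic"
  sel <- is.na(reason) & miss_frac > t$max_missing_fraction
  reason[sel] <- "missingness"
  sel <- is.na(reason) & maf <= t$maf_min
  reason[sel] <- "maf"
  keep <- is.na(reason)
  exclusions <- data.frame(variant_id = g$variants$variant_id[!keep],
                           reason = reason[!keep], stringsAsFactors = FALSE)
  g2 <- genotype_matrix(d[keep, , drop = FALSE],
                        g$variants[keep, , drop = FALSE], g$samples,
                        gq = if (!is.null(g$gq)) g$gq[keep, , drop = FALSE],
                        dp = if (!is.null(g$dp)) g$dp[keep, , drop = FALSE])
  list(genotypes = g2, exclusions = exclusions)
}

#' Mean-impute missing dosages
#'
#' Missing entries are replaced by the mean of the non-missing dosages, the
#' convention used inside the cis regression; called entries are unchanged.
#'
#' @param dosages Numeric vector with at least one non-missing value.
#' @return A complete numeric vector.
#' @export
mean_impute_dosage <- function(dosages) {
  ok <- !is.na(dosages)
  if (!any(ok)) stop("all dosages missing")
  dosages[!ok] <- mean(dosages[ok])
  dosages
}
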