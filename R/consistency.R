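direction_sign <- function(direction) {
  # favourable = +1, unfavourable = -1
  ifelse(direction == "favourable", 1, -1)
}

variant_direction <- function(records) {
  # direction of a variant from its significant Cox records; codominant fits
  # use the homozygous coefficient when present, else the heterozygous one.
  # Returns list(direction, conflict, models)
  recs <- records[!is.na(records$wald_p) & records$wald_p < 0.05, , drop = FALSE]
  if (nrow(recs) == 0) return(NULL)
  pick <- recs
  cod <- pick$inheritance == "codominant"
  if (any(cod)) {
    # within each codominant model keep hom if present else het
    keyc <- paste(pick$inheritance, pick$adjusted)
    keep <- rep(TRUE, nrow(pick))
    for (kk in unique(keyc[cod])) {
      i <- which(keyc == kk)
      if (any(pick$term[i] == "hom")) keep[i[pick$term[i] != "hom"]] <- FALSE
    }
    pick <- pick[keep, , drop = FALSE]
  }
  signs <- sign(pick$coef)
  if (any(signs == 0)) stop("coefficient exactly zero: direction undefined")
  best <- which.min(pick$wald_p)
  list(direction = if (signs[best] < 0) "favourable" else "unfavourable",
       conflict = length(unique(signs)) > 1,
       models = paste0(pick$inheritance, ifelse(pick$adjusted, "_adj", ""),
                       "_", pick$term))
}

#' Classify one eGene-eQTL pair for prognostic-direction consistency
#'
#' The slope of the cis regression predicts the variant's survival direction
#' from its gene's: with favourable coded +1 and unfavourable -1, the
#' predicted variant direction is gene direction x sign(slope), and the pair
#' is consistent when the observed variant direction (from the significant
#' Cox model(s)) matches it. For codominant fits, the homozygous coefficient
#' defines the direction when present, else the heterozygous one.
#'
#' @param gene_direction `"favourable"` or `"unfavourable"` for the eGene.
#' @param slope The eQTL slope (per ALT allele); must be nonzero.
#' @param variant_records Variant-level survival records for the eQTL
#'   (at least one significant model), or a precomputed direction string.
#' @return A list with `gene_direction`, `slope_sign`,
#'   `predicted_direction`, `variant_direction`, `satisfied_models`,
#'   `direction_conflict` and logical `consistent`.
#' @export
classify_pair <- function(gene_direction, slope, variant_records) {
  stopifnot(gene_direction %in% c("favourable", "unfavourable"))
  if (slope == 0) stop("eQTL slope exactly zero: direction undefined")
  vd <- if (is.character(variant_records)) {
    list(direction = variant_records, conflict = FALSE, models = NA_character_)
  } else {
    variant_direction(variant_records)
  }
  if (is.null(vd)) stop("variant has no significant Cox model")
  pred <- direction_sign(gene_direction) * sign(slope)
  predicted <- if (pred > 0) "favourable" else "unfavourable"
  list(gene_direction = gene_direction, slope_sign = sign(slope),
       predicted_direction = predicted, variant_direction = vd$direction,
       satisfied_models = vd$models, direction_conflict = vd$conflict,
       consistent = predicted == vd$direction)
}

#' Enumerate prognostically consistent eGene-eQTL pairs
#'
#' Evaluates every significant cis pair whose gene is in the prognostic
#' union set and whose variant is significant (p < 0.05) in at least one Cox
#' model, classifying each for direction consistency and summarizing the
#' distinct genes, distinct eQTLs and pair counts.
#'
#' @param prognostic A `prognostic_sets` from [build_prognostic_sets()].
#' @param significant_pairs Significant pair `data.frame` (from
#'   [call_significant_pairs()] or [map_cis_eqtls()]) with `gene_id`,
#'   `variant_id`, `slope`.
#' @param variant_records Variant-level survival records covering the pairs'
#'   variants (all fitted models).
#' @return A list with `pairs` (per-pair verdicts), `consistent` (the
#'   consistent subset) and `summary` (`n_genes`, `n_eqtls`, `n_pairs` over
#'   the consistent subset).
#' @export
enumerate_consistent <- function(prognostic, significant_pairs,
                                 variant_records) {
  rows <- vector("list", 0)
  for (i in seq_len(nrow(significant_pairs))) {
    gene <- significant_pairs$gene_id[i]
    vid <- significant_pairs$variant_id[i]
    if (!(gene %in% prognostic$union_set)) next
    vrec <- variant_records[variant_records$entity == vid, , drop = FALSE]
    if (nrow(vrec) == 0) next
    if (!any(!is.na(vrec$wald_p) & vrec$wald_p < 0.05)) next
    cls <- classify_pair(prognostic$direction[[gene]],
                         significant_pairs$slope[i], vrec)
    rows[[length(rows) + 1]] <- data.frame(
      gene_id = gene, variant_id = vid,
      slope = significant_pairs$slope[i],
      gene_direction = cls$gene_direction,
      variant_direction = cls$variant_direction,
      satisfied_models = paste(cls$satisfied_models, collapse = ","),
      direction_conflict = cls$direction_conflict,
      consistent = cls$consistent, stringsAsFactors = FALSE)
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), variant_id = character(),
               slope = numeric(), gene_direction = character(),
               variant_direction = character(), satisfied_models = character(),
               direction_conflict = logical(), consistent = logical(),
               stringsAsFactors = FALSE)
  consistent <- pairs[pairs$consistent, , drop = FALSE]
  list(pairs = pairs, consistent = consistent,
       summary = c(n_genes = length(unique(consistent$gene_id)),
                   n_eqtls = length(unique(consistent$variant_id)),
                   n_pairs = nrow(consistent)))
}

#' Match discovery variants into a validation cohort
#'
#' Matches on (chrom, pos, ref, alt); an allele-swapped record (ref and alt
#' exchanged) is harmonized by flipping the validation dosage to `2 - d` and
#' flagged. Unmatched variants are reported with tier `"unmatched"`.
#'
#' @param variant_ids Character vector of discovery `chrom_pos_ref_alt` ids.
#' @param validation_genotypes The validation [genotype_matrix()].
#' @return A `data.frame` with `variant_id`, `matched`, `flipped` and
#'   `validation_id`; flipped dosages are returned in the attribute
#'   `dosage` (a matched-variants x samples matrix, harmonized to the
#'   discovery ALT allele).
#' @export
match_variants <- function(variant_ids, validation_genotypes) {
  v <- validation_genotypes$variants
  direct <- match(variant_ids, v$variant_id)
  swapped_id <- vapply(strsplit(variant_ids, "_"), function(p)
    paste(p[1], p[2], p[4], p[3], sep = "_"), character(1))
  swap <- match(swapped_id, v$variant_id)
  matched <- !is.na(direct) | !is.na(swap)
  flipped <- is.na(direct) & !is.na(swap)
  idx <- ifelse(flipped, swap, direct)
  dosage <- matrix(NA_real_, sum(matched), ncol(validation_genotypes$dosage),
                   dimnames = list(variant_ids[matched],
                                   validation_genotypes$samples))
  for (j in which(matched)) {
    d <- validation_genotypes$dosage[idx[j], ]
    dosage[variant_ids[j], ] <- if (flipped[j]) 2 - d else d
  }
  out <- data.frame(variant_id = variant_ids, matched = matched,
                    flipped = flipped,
                    validation_id = ifelse(matched, v$variant_id[idx], NA),
                    stringsAsFactors = FALSE)
  attr(out, "dosage") <- dosage
  out
}

#' Classify the replication tier of a matched pair
#'
#' Compared pairwise per model (same inheritance model and adjustment
#' status): strict replication requires a corresponding validation model
#' with p < 0.05 and agreeing coefficient sign; lenient replication requires
#' sign agreement in at least one corresponding model without any reaching
#' significance with agreement; otherwise the pair is discordant.
#'
#' @param discovery_records Variant-level survival records from the
#'   discovery cohort (the models in which the pair was significant).
#' @param validation_records Matching records from the validation cohort.
#' @return `"strict"`, `"lenient"` or `"discordant"`.
#' @export
classify_tier <- function(discovery_records, validation_records) {
  # direction-defining coefficient of one model's records: the homozygous
  # contrast when present, else the heterozygous one (codominant), else the
  # single coefficient
  pick <- function(r) {
    if (r$inheritance[1] == "codominant" && any(r$term == "hom"))
      r[r$term == "hom", , drop = FALSE][1, ] else r[1, ]
  }
  dk <- paste(discovery_records$inheritance, discovery_records$adjusted)
  vk <- paste(validation_records$inheritance, validation_records$adjusted)
  shared <- intersect(unique(dk), unique(vk))
  if (length(shared) == 0) return("discordant")
  agree <- logical(0); strict <- logical(0)
  for (kk in shared) {
    dd <- pick(discovery_records[dk == kk, , drop = FALSE])
    vv <- pick(validation_records[vk == kk, , drop = FALSE])
    a <- sign(dd$coef) == sign(vv$coef)
    agree <- c(agree, a)
    strict <- c(strict, a && !is.na(vv$wald_p) && vv$wald_p < 0.05)
  }
  if (any(strict)) "strict" else if (any(agree)) "lenient" else "discordant"
}

#' Linkage-disequilibrium r-squared from dosages
#'
#' Squared Pearson correlation of two dosage vectors over their jointly
#' non-missing samples (>= 5 required).
#'
#' @param dosages_a,dosages_b Dosage vectors over the same samples.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(dosages_a, dosages_b) {
  ok <- !is.na(dosages_a) & !is.na(dosages_b)
  if (sum(ok) < 5) stop("fewer than 5 jointly non-missing samples")
  a <- dosages_a[ok]; b <- dosages_b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero dosage variance; r-squared undefined")
  stats::cor(a, b)^2
}

#' Cluster variants into loci by LD
#'
#' Single-linkage clustering: variants are joined when pairwise r-squared is
#' at or above the threshold, and loci are the connected components; the
#' number of components is the count of unique genomic loci.
#'
#' @param dosage_matrix Variants x samples dosage matrix (rownames = ids).
#' @param threshold r-squared at/above which two variants share a locus
#'   (default 0.1).
#' @return Integer vector of locus memberships named by variant id.
#' @export
cluster_loci <- function(dosage_matrix, threshold = 0.1) {
  m <- nrow(dosage_matrix)
  ids <- rownames(dosage_matrix)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (m > 1) {
    for (i in seq_len(m - 1)) for (j in seq((i + 1), m)) {
      r2 <- tryCatch(ld_r2(dosage_matrix[i, ], dosage_matrix[j, ]),
                     error = function(e) NA_real_)
      if (!is.na(r2) && r2 >= threshold) parent[find(i)] <- find(j)
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  stats::setNames(match(roots, unique(roots)), ids)
}

#' Replicate consistent pairs in a validation cohort
#'
#' For each consistent discovery pair, matches the variant into the
#' validation cohort, refits the variant-level Cox models there (allelic and
#' codominant, unadjusted and adjusted by the supplied validation covariates)
#' on the harmonized dosages, applies the genotype-count filter in the
#' validation cohort, and assigns the replication tier.
#'
#' @param consistent_pairs Consistent pair `data.frame` from
#'   [enumerate_consistent()].
#' @param discovery_records Variant-level survival records from discovery.
#' @param validation A `cohort` used for validation.
#' @param adjust_vars Clinical adjustment columns available in the
#'   validation cohort (default `"t_stage"` only, the common case for
#'   validation registries lacking nodal/metastasis staging).
#' @return The pairs with `tier` (`"strict"`, `"lenient"`, `"discordant"`,
#'   `"unmatched"`) and matching metadata; validation records are attached
#'   as attribute `validation_records`.
#' @export
replicate_pairs <- function(consistent_pairs, discovery_records, validation,
                            adjust_vars = "t_stage") {
  vids <- unique(consistent_pairs$variant_id)
  mm <- match_variants(vids, validation$genotypes)
  dos <- attr(mm, "dosage")
  cl <- validation$clinical
  vrecs <- vector("list", 0)
  for (vid in vids[mm$matched[match(vids, mm$variant_id)]]) {
    for (inh in c("allelic", "codominant")) for (adj in c(FALSE, TRUE)) {
      r <- tryCatch(
        variant_survival(dos[vid, ], cl, inheritance = inh, adjusted = adj,
                         entity = vid, adjust_vars = adjust_vars),
        error = function(e) NULL)
      if (!is.null(r)) vrecs[[length(vrecs) + 1]] <- r
    }
  }
  validation_records <- if (length(vrecs)) do.call(rbind, vrecs) else NULL
  tier <- character(nrow(consistent_pairs))
  for (i in seq_len(nrow(consistent_pairs))) {
    vid <- consistent_pairs$variant_id[i]
    if (!mm$matched[mm$variant_id == vid]) { tier[i] <- "unmatched"; next }
    drec <- discovery_records[discovery_records$entity == vid &
                                !is.na(discovery_records$wald_p) &
                                discovery_records$wald_p < 0.05, , drop = FALSE]
    vrec <- if (is.null(validation_records)) NULL else
      validation_records[validation_records$entity == vid, , drop = FALSE]
    tier[i] <- if (is.null(vrec) || nrow(vrec) == 0) "unmatched" else
      classify_tier(drec, vrec)
  }
  out <- consistent_pairs
  out$tier <- tier
  out$flipped <- mm$flipped[match(out$variant_id, mm$variant_id)]
  attr(out, "validation_records") <- validation_records
  out
}
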