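#' Canonical variant identifier
#'
#' Concatenates chromosome, 1-based position, reference allele and alternative
#' allele into the `chrom_pos_ref_alt` identifier used throughout the package,
#' the same dialect GTEx uses for its variant tables.
#'
#' @param chrom Chromosome label (e.g. `"chr1"`).
#' @param pos 1-based position.
#' @param ref Reference allele string.
#' @param alt Alternative allele string.
#' @return Character vector of variant identifiers.
#' @export
variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = "_")
}

#' Construct a genotype matrix
#'
#' Container for biallelic ALT-allele dosages (variants x samples) with
#' per-variant metadata and optional per-genotype quality (GQ) and depth (DP)
#' matrices. Dosages are restricted to 0, 1, 2 or `NA` (missing).
#'
#' @param dosage Numeric matrix, variants in rows, samples in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param variants `data.frame` with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `rsid`; one row per dosage row.
#' @param samples Character vector of sample identifiers (dosage columns).
#' @param gq,dp Optional numeric matrices of the same shape as `dosage`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, variants, samples, gq = NULL, dp = NULL) {
  dosage <- as.matrix(dosage)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.character(samples)
  stopifnot(nrow(dosage) == nrow(variants), ncol(dosage) == length(samples))
  if (any(variants$ref == variants$alt))
    stop("ref and alt alleles must differ for every variant")
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad))
    stop("dosage values must be 0, 1, 2 or NA")
  if (!("rsid" %in% names(variants))) variants$rsid <- NA_character_
  variants$variant_id <- variant_id(variants$chrom, variants$pos,
                                    variants$ref, variants$alt)
  if (anyDuplicated(variants$variant_id))
    stop("duplicate variant identifiers")
  rownames(dosage) <- variants$variant_id
  colnames(dosage) <- samples
  for (nm in c("gq", "dp")) {
    m <- get(nm)
    if (!is.null(m)) {
      stopifnot(all(dim(m) == dim(dosage)))
      dimnames(m) <- dimnames(dosage)
      assign(nm, m)
    }
  }
  structure(list(dosage = dosage, variants = variants, samples = samples,
                 gq = gq, dp = dp),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d variants x %d samples (%.1f%% missing)\n",
              nrow(x$dosage), length(x$samples),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Construct an expression matrix
#'
#' Holds TPM and (optionally) read-count matrices, genes x samples, together
#' with per-gene annotation: chromosome, 1-based transcription start site
#' (TSS), strand and biotype.
#'
#' @param tpm Nonnegative numeric matrix, genes x samples.
#' @param genes `data.frame` with columns `gene_id`, `chrom`, `tss` and
#'   optionally `strand`, `biotype`.
#' @param samples Character vector of sample identifiers.
#' @param counts Optional nonnegative count matrix of the same shape.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(tpm, genes, samples, counts = NULL) {
  tpm <- as.matrix(tpm)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  samples <- as.character(samples)
  stopifnot(nrow(tpm) == nrow(genes), ncol(tpm) == length(samples))
  if (any(tpm < 0, na.rm = TRUE)) stop("tpm must be nonnegative")
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id")
  if (!("strand" %in% names(genes))) genes$strand <- rep("+", nrow(genes))
  if (!("biotype" %in% names(genes)))
    genes$biotype <- rep("protein_coding", nrow(genes))
  dimnames(tpm) <- list(genes$gene_id, samples)
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    stopifnot(all(dim(counts) == dim(tpm)))
    if (any(counts < 0)) stop("counts must be nonnegative")
    dimnames(counts) <- dimnames(tpm)
  }
  structure(list(tpm = tpm, counts = counts, genes = genes, samples = samples),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples%s\n",
              nrow(x$tpm), length(x$samples),
              if (is.null(x$counts)) " (TPM only)" else " (TPM + counts)"))
  invisible(x)
}

#' Construct a clinical table
#'
#' Per-sample clinical covariates and right-censored overall survival. Tumour
#' size `t_stage` is an integer 1-4, nodal spread `n_stage` 0-2, metastasis
#' `m_stage` 0-1; `time` is survival in days (> 0) and `event` is 1 for death,
#' 0 for censoring.
#'
#' @param x `data.frame` with columns `sample_id`, `sex` (`"male"`/`"female"`),
#'   `age` (years), `t_stage`, `n_stage`, `m_stage`, `time`, `event`.
#' @return A validated `data.frame` of class `clinical_table`.
#' @export
clinical_table <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("sample_id", "sex", "age", "t_stage", "n_stage", "m_stage",
            "time", "event")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("clinical table missing columns: ",
                         paste(miss, collapse = ", "))
  stopifnot(all(x$sex %in% c("male", "female")),
            all(x$t_stage %in% 1:4), all(x$n_stage %in% 0:2),
            all(x$m_stage %in% 0:1), all(x$event %in% 0:1))
  if (any(x$time <= 0)) stop("survival time must be positive")
  if (anyDuplicated(x$sample_id)) stop("duplicate sample_id")
  class(x) <- c("clinical_table", "data.frame")
  x
}

gt_string <- function(d) {
  out <- rep("./.", length(d))
  out[!is.na(d) & d == 0] <- "0/0"
  out[!is.na(d) & d == 1] <- "0/1"
  out[!is.na(d) & d == 2] <- "1/1"
  out
}

#' Read genotypes from a VCF file
#'
#' Parses a biallelic VCF and converts called genotypes to ALT-allele dosages
#' (0/0 -> 0, 0/1 -> 1, 1/1 -> 2, uncalled -> `NA`). GQ and DP are carried
#' along when the FORMAT declares them, so genotype-level masking can act on
#' them downstream.
#'
#' @param path Path to a VCF 4.x file (plain text or bgzipped).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi))
    stop("multi-allelic record(s) not supported: ",
         paste(head(paste0(fix$CHROM[multi], ":", fix$POS[multi]), 5),
               collapse = ", "))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # count ALT alleles irrespective of phasing separator
  dosage <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  called <- !is.na(gt) & !grepl("\\.", gt)
  alleles <- strsplit(gt[called], "[/|]")
  dosage[called] <- vapply(alleles, function(a) sum(a == "1"), numeric(1))
  fmt <- vcf@gt[, 1]
  gq <- if (any(grepl("GQ", fmt)))
    vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE) else NULL
  dp <- if (any(grepl("DP", fmt)))
    vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE) else NULL
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         rsid = ifelse(is.na(fix$ID) | fix$ID == ".",
                                       NA_character_, fix$ID),
                         stringsAsFactors = FALSE)
  genotype_matrix(dosage, variants, colnames(gt), gq = gq, dp = dp)
}

#' Write genotypes to a VCF file
#'
#' Emits a minimal VCF 4.2 file with GT (and GQ/DP when present) that
#' round-trips through [read_genotypes()]. Only hard-called dosages
#' (0, 1, 2, `NA`) can be written.
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  d <- g$dosage
  if (any(!(d %in% c(0, 1, 2)) & !is.na(d)))
    stop("write_genotypes requires hard-called dosages (0, 1, 2, NA)")
  has_gq <- !is.null(g$gq); has_dp <- !is.null(g$dp)
  fmt <- paste(c("GT", if (has_gq) "GQ", if (has_dp) "DP"), collapse = ":")
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              if (has_gq) '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
              if (has_dp) '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", g$samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(d)), function(i) {
    cells <- gt_string(d[i, ])
    if (has_gq) cells <- paste(cells, ifelse(is.na(g$gq[i, ]), ".", g$gq[i, ]), sep = ":")
    if (has_dp) cells <- paste(cells, ifelse(is.na(g$dp[i, ]), ".", g$dp[i, ]), sep = ":")
    v <- g$variants[i, ]
    paste(c(v$chrom, v$pos, ifelse(is.na(v$rsid), ".", v$rsid), v$ref, v$alt,
            ".", "PASS", ".", fmt, cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read expression from a BED-like TSV
#'
#' Reads the GTEx-style expression dialect: columns `chr`, `start`, `end`,
#' `gene_id` followed by one numeric column per sample. The TSS is the 0-based
#' `start` converted to 1-based (`start + 1`); strand is not used to recompute
#' it.
#'
#' @param path Path to a tab-separated file with a header line.
#' @param counts_path Optional companion file of identical layout holding read
#'   counts.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, counts_path = NULL) {
  parse_bed <- function(p) {
    x <- utils::read.delim(p, check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
    names(x)[1] <- sub("^#", "", names(x)[1])
    stopifnot(all(c("chr", "start", "end", "gene_id") %in% names(x)[1:4]))
    if (anyDuplicated(x$gene_id))
      stop("duplicate gene_id in ", p, ": ",
           x$gene_id[duplicated(x$gene_id)][1])
    vals <- x[, -(1:4), drop = FALSE]
    for (j in seq_along(vals)) {
      v <- suppressWarnings(as.numeric(vals[[j]]))
      if (any(is.na(v) & !is.na(vals[[j]])))
        stop(sprintf("non-numeric cell in %s: row %d, column %s", p,
                     which(is.na(v) & !is.na(vals[[j]]))[1], names(vals)[j]))
      vals[[j]] <- v
    }
    list(genes = data.frame(gene_id = x$gene_id, chrom = x$chr,
                            tss = as.integer(x$start) + 1L,
                            stringsAsFactors = FALSE),
         mat = as.matrix(vals), samples = names(vals))
  }
  tpm <- parse_bed(path)
  counts <- NULL
  if (!is.null(counts_path)) {
    cc <- parse_bed(counts_path)
    stopifnot(identical(cc$genes$gene_id, tpm$genes$gene_id),
              identical(cc$samples, tpm$samples))
    counts <- cc$mat
  }
  expression_matrix(tpm$mat, tpm$genes, tpm$samples, counts = counts)
}

#' Write expression to a BED-like TSV
#'
#' Inverse of [read_expression()]: writes `chr`, `start` (= TSS - 1), `end`
#' (= TSS), `gene_id` and one column per sample.
#'
#' @param e An [expression_matrix()].
#' @param path Output path for the TPM matrix.
#' @param counts_path Optional output path for the count matrix.
#' @return `path`, invisibly.
#' @export
write_expression <- function(e, path, counts_path = NULL) {
  emit <- function(mat, p) {
    df <- data.frame(chr = e$genes$chrom, start = e$genes$tss - 1L,
                     end = e$genes$tss, gene_id = e$genes$gene_id,
                     stringsAsFactors = FALSE, check.names = FALSE)
    df <- cbind(df, as.data.frame(mat, check.names = FALSE))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  emit(e$tpm, path)
  if (!is.null(counts_path)) {
    if (is.null(e$counts)) stop("expression matrix has no counts")
    emit(e$counts, counts_path)
  }
  invisible(path)
}

#' Read or write a clinical table as TSV
#'
#' @param path Path to a tab-separated clinical file with header.
#' @return [read_clinical()] returns a [clinical_table()].
#' @export
read_clinical <- function(path) {
  clinical_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_clinical
#' @param cl A [clinical_table()].
#' @export
write_clinical <- function(cl, path) {
  utils::write.table(cl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align genotypes, expression and clinical data on shared samples
#'
#' Restricts all three inputs to their sample intersection in a canonical
#' (lexicographic) order and reports what was dropped. Downstream stages
#' assume this alignment.
#'
#' @param g A [genotype_matrix()].
#' @param e An [expression_matrix()].
#' @param cl A [clinical_table()].
#' @return A list of class `cohort` with elements `genotypes`, `expression`,
#'   `clinical` and a `dropped` list naming samples absent from the
#'   intersection.
#' @export
align_cohort <- function(g, e, cl) {
  shared <- sort(Reduce(intersect, list(g$samples, e$samples, cl$sample_id)))
  if (length(shared) == 0) stop("no samples shared across genotypes, expression and clinical data")
  dropped <- list(genotypes = setdiff(g$samples, shared),
                  expression = setdiff(e$samples, shared),
                  clinical = setdiff(cl$sample_id, shared))
  gi <- match(shared, g$samples)
  g2 <- genotype_matrix(g$dosage[, gi, drop = FALSE], g$variants, shared,
                        gq = if (!is.null(g$gq)) g$gq[, gi, drop = FALSE],
                        dp = if (!is.null(g$dp)) g$dp[, gi, drop = FALSE])
  ei <- match(shared, e$samples)
  e2 <- expression_matrix(e$tpm[, ei, drop = FALSE], e$genes, shared,
                          counts = if (!is.null(e$counts)) e$counts[, ei, drop = FALSE])
  cl2 <- cl[match(shared, cl$sample_id), , drop = FALSE]
  rownames(cl2) <- NULL
  structure(list(genotypes = g2, expression = e2,
                 clinical = clinical_table(cl2), dropped = dropped),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d samples, %d variants, %d genes\n",
              length(x$genotypes$samples), nrow(x$genotypes$dosage),
              nrow(x$expression$tpm)))
  invisible(x)
}
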