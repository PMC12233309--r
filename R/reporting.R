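round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Set-overlap statistics with hypergeometric enrichment
#'
#' Counts the overlap of two sets inside a universe, reports it as a
#' percentage of set A (rounded half-up to one decimal), and computes the
#' upper-tail hypergeometric enrichment probability
#' `P(X >= overlap)` with population `|universe|`, successes `|B|` and
#' draws `|A|`.
#'
#' @param set_a,set_b Character vectors; both must lie inside `universe`.
#' @param universe Character vector defining the population.
#' @return A list of class `overlap_report`: `n_a`, `n_b`, `n_overlap`,
#'   `percent_of_a` (one decimal), `fraction_of_a` (unrounded),
#'   `n_universe`, `p_value`.
#' @export
overlap_stats <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (!all(set_a %in% universe)) stop("set A is not a subset of the universe")
  if (!all(set_b %in% universe)) stop("set B is not a subset of the universe")
  k <- length(intersect(set_a, set_b))
  n_a <- length(set_a); n_b <- length(set_b); n_u <- length(universe)
  p <- stats::phyper(k - 1, n_b, n_u - n_b, n_a, lower.tail = FALSE)
  structure(list(n_a = n_a, n_b = n_b, n_overlap = k,
                 percent_of_a = round_half_up(100 * k / n_a, 1),
                 fraction_of_a = k / n_a,
                 n_universe = n_u, p_value = p),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap: %d of %d (%.1f%%), universe %d, hypergeometric p = %.3g\n",
              x$n_overlap, x$n_a, x$percent_of_a, x$n_universe, x$p_value))
  invisible(x)
}

#' Union size by inclusion-exclusion
#'
#' `|A union B| = |A| + |B| - |A intersect B|`; the arithmetic behind
#' reported union-set sizes.
#'
#' @param n_a,n_b,n_both Set and intersection sizes.
#' @return The union size.
#' @export
set_union_size <- function(n_a, n_b, n_both) {
  stopifnot(n_both <= min(n_a, n_b))
  n_a + n_b - n_both
}

#' Count recurrently mutated genes
#'
#' Tallies mutation events per gene and keeps genes with at least
#' `min_count` events.
#'
#' @param gene_per_event Character vector, one gene per mutation event.
#' @param min_count Minimum recurrent events (default 5).
#' @return A `data.frame` of `gene_id` and `n_mutations`, most mutated
#'   first.
#' @export
count_recurrent_genes <- function(gene_per_event, min_count = 5) {
  if (length(gene_per_event) == 0) stop("empty mutation table")
  tab <- sort(table(gene_per_event), decreasing = TRUE)
  tab <- tab[tab >= min_count]
  data.frame(gene_id = names(tab), n_mutations = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flat key = value configuration file
#'
#' Lines of `key = value`; `#` starts a comment. Values are converted to
#' numeric where possible.
#'
#' @param path Configuration file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  out <- list()
  for (x in kv) {
    v <- suppressWarnings(as.numeric(x[2]))
    out[[x[1]]] <- if (is.na(v)) x[2] else v
  }
  out
}

#' Run the full discovery/validation pipeline
#'
#' Orchestrates the stages end to end on simulated twin cohorts: QC ->
#' covariates -> cis-eQTL mapping -> gene- and variant-level Cox ->
#' prognostic sets -> consistency classification -> cross-cohort
#' replication -> summary reports. Every stage table is written as TSV under
#' `outdir`; re-running with the same configuration reproduces identical
#' tables.
#'
#' @param config A [sim_config()], a named list of [sim_config()] arguments,
#'   or a path to a flat key = value file of them.
#' @param outdir Output directory (created if needed); `NULL` skips writing.
#' @param seed Seed controlling simulation and permutation (overrides the
#'   config's).
#' @param n_pcs,n_factors Covariate counts.
#' @param quiet Suppress stage messages.
#' @return A list with all stage results: `discovery`, `validation`,
#'   `covariates`, `eqtl`, `gene_survival_unadjusted`,
#'   `gene_survival_adjusted`, `prognostic`, `variant_records`,
#'   `consistency`, `replication`, `summary`.
#' @export
run_pipeline <- function(config = sim_config(), outdir = NULL, seed = NULL,
                         n_pcs = 5, n_factors = 15, quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  say <- function(...) if (!quiet) message(sprintf(...))

  say("stage simulate: twin cohorts (seed %d)", config$seed)
  tw <- make_paired_cohorts(config)

  run_cohort <- function(cohort, label, adjust_vars) {
    say("stage qc [%s]", label)
    filt <- filter_variants(cohort$genotypes, qc_thresholds())
    cohort$genotypes <- filt$genotypes
    say("stage prep [%s]", label)
    cohort$expression <- filter_genes(cohort$expression)
    cov <- cohort_covariates(cohort, n_pcs = n_pcs, n_factors = n_factors)
    say("stage eqtl [%s]: %d genes, %d variants", label,
        nrow(cohort$expression$tpm), nrow(cohort$genotypes$dosage))
    eqtl <- map_cis_eqtls(cohort, cov, seed = config$seed)
    say("stage survival [%s]", label)
    egenes <- eqtl$genes$gene_id[eqtl$genes$egene & eqtl$genes$passed]
    gs_u <- gene_survival(cohort, genes = egenes, adjusted = FALSE)
    gs_a <- gene_survival(cohort, genes = egenes, adjusted = TRUE,
                          adjust_vars = adjust_vars)
    prog <- build_prognostic_sets(gs_u, gs_a)
    sig <- eqtl$significant_pairs
    sig <- sig[sig$gene_id %in% egenes, , drop = FALSE]
    vrecs <- vector("list", 0)
    for (vid in unique(sig$variant_id)) {
      for (inh in c("allelic", "codominant")) for (adj in c(FALSE, TRUE)) {
        r <- tryCatch(
          variant_survival(cohort$genotypes$dosage[vid, ], cohort$clinical,
                           inheritance = inh, adjusted = adj, entity = vid,
                           adjust_vars = adjust_vars),
          error = function(e) NULL)
        if (!is.null(r)) vrecs[[length(vrecs) + 1]] <- r
      }
    }
    vrec <- if (length(vrecs)) sanitize_hr(do.call(rbind, vrecs)) else NULL
    if (!is.null(vrec)) vrec <- survival_multiple_testing(vrec)
    list(cohort = cohort, exclusions = filt$exclusions, covariates = cov,
         eqtl = eqtl, gs_u = survival_multiple_testing(gs_u),
         gs_a = survival_multiple_testing(gs_a),
         prognostic = prog, sig = sig, variant_records = vrec)
  }

  disc <- run_cohort(tw$discovery, "discovery",
                     c("t_stage", "n_stage", "m_stage"))
  say("stage consistency")
  cons <- enumerate_consistent(disc$prognostic, disc$sig,
                               disc$variant_records)
  say("stage replication")
  repl <- replicate_pairs(cons$consistent, disc$variant_records,
                          tw$validation, adjust_vars = "t_stage")
  summary <- list(
    n_egenes = sum(disc$eqtl$genes$egene),
    n_significant_pairs = nrow(disc$eqtl$significant_pairs),
    n_unique_eqtls = disc$eqtl$n_unique_eqtls,
    prognostic = c(n_unadjusted = length(disc$prognostic$unadjusted_set),
                   n_adjusted = length(disc$prognostic$adjusted_set),
                   n_union = length(disc$prognostic$union_set)),
    consistency = cons$summary,
    tiers = table(factor(repl$tier, levels = c("strict", "lenient",
                                               "discordant", "unmatched"))))
  out <- list(discovery = disc, validation = tw$validation, truth = tw$truth,
              consistency = cons, replication = repl, summary = summary)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(disc$exclusions, file.path(outdir, "qc_exclusions.tsv"))
    write_tsv(disc$eqtl$genes, file.path(outdir, "egenes.tsv"))
    write_tsv(disc$eqtl$pairs, file.path(outdir, "pairs.tsv"))
    write_tsv(disc$gs_u, file.path(outdir, "gene_survival_unadjusted.tsv"))
    write_tsv(disc$gs_a, file.path(outdir, "gene_survival_adjusted.tsv"))
    if (!is.null(disc$variant_records))
      write_tsv(disc$variant_records, file.path(outdir, "variant_survival.tsv"))
    write_tsv(cons$pairs, file.path(outdir, "consistency_pairs.tsv"))
    write_tsv(repl, file.path(outdir, "replication.tsv"))
  }
  out
}
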