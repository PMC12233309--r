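# Newton-Raphson maximization of the Cox partial likelihood with Efron's
# tie correction. Step-halving guards the ascent; a diverging coefficient
# (monotone likelihood, e.g. a genotype whose carriers all share one
# outcome) is flagged rather than reported as a finite hazard ratio.
cox_partial_fit <- function(time, event, x, max_iter = 100, tol = 1e-10,
                            coef_bound = 10) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  p <- ncol(x)
  if (sum(event) < 1) stop("no events in the data")
  if (any(apply(x, 2, stats::sd) == 0)) stop("constant covariate")
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord, , drop = FALSE]
  xc <- sweep(x, 2, colMeans(x))   # centering stabilizes exp() without
                                   # changing coefficients
  dtimes <- unique(time[event == 1])
  risk_idx <- lapply(dtimes, function(t) which(time >= t))
  death_idx <- lapply(dtimes, function(t) which(time == t & event == 1))
  beta <- rep(0, p)
  loglik_at <- function(beta) {
    eta <- drop(xc %*% beta); w <- exp(eta)
    ll <- 0
    for (j in seq_along(dtimes)) {
      D <- death_idx[[j]]; R <- risk_idx[[j]]; d <- length(D)
      wR <- sum(w[R]); wD <- sum(w[D])
      ll <- ll + sum(eta[D]) -
        sum(log(wR - (seq_len(d) - 1) / d * wD))
    }
    ll
  }
  ll_old <- loglik_at(beta)
  converged <- FALSE
  info <- NULL
  for (iter in seq_len(max_iter)) {
    eta <- drop(xc %*% beta); w <- exp(eta)
    U <- rep(0, p); info <- matrix(0, p, p)
    for (j in seq_along(dtimes)) {
      D <- death_idx[[j]]; R <- risk_idx[[j]]; d <- length(D)
      xR <- xc[R, , drop = FALSE]; xD <- xc[D, , drop = FALSE]
      wR <- sum(w[R]); wD <- sum(w[D])
      sR <- colSums(xR * w[R]); sD <- colSums(xD * w[D])
      x2R <- crossprod(xR, xR * w[R]); x2D <- crossprod(xD, xD * w[D])
      U <- U + colSums(xD)
      for (l in seq_len(d)) {
        a <- (l - 1) / d
        wj <- wR - a * wD
        sj <- sR - a * sD
        x2j <- x2R - a * x2D
        U <- U - sj / wj
        info <- info + x2j / wj - tcrossprod(sj) / wj^2
      }
    }
    step <- tryCatch(solve(info, U), error = function(e) NULL)
    if (is.null(step)) break
    halve <- 0
    repeat {
      beta_new <- beta + step
      ll_new <- loglik_at(beta_new)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
      step <- step / 2
      halve <- halve + 1
      if (halve > 30) break
    }
    done <- abs(ll_new - ll_old) < tol && max(abs(beta_new - beta)) < 1e-8
    beta <- beta_new; ll_old <- ll_new
    if (max(abs(beta)) > coef_bound) break
    if (done) { converged <- TRUE; break }
  }
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e) rep(NA_real_, p))
  flagged <- !converged || max(abs(beta)) > coef_bound || any(!is.finite(se))
  list(coef = beta, se = se, loglik = ll_old, converged = converged,
       flagged = flagged, iter = iter)
}

new_survival_record <- function(entity, level, inheritance, adjusted, term,
                                fit, j, het = NA_integer_, hom = NA_integer_) {
  coef <- fit$coef[j]; se <- fit$se[j]
  flagged <- fit$flagged
  hr <- if (flagged) NA_real_ else exp(coef)
  data.frame(entity = entity, level = level, inheritance = inheritance,
             adjusted = adjusted, term = term,
             coef = coef, se = se, hr = hr,
             ci_low = if (flagged) NA_real_ else exp(coef - 1.96 * se),
             ci_high = if (flagged) NA_real_ else exp(coef + 1.96 * se),
             wald_p = 2 * stats::pnorm(-abs(coef / se)),
             het_count = het, homalt_count = hom,
             flagged = flagged, sanitized = FALSE,
             stringsAsFactors = FALSE)
}

#' Fit a Cox proportional-hazards model for one entity
#'
#' Maximizes the partial likelihood (Efron tie handling) by Newton iteration
#' and reports the Wald test for the primary covariate(s); adjustment
#' covariates are included in the fit but not reported. Monotone likelihood
#' (a diverging coefficient) flags the record and suppresses the hazard
#' ratio and confidence interval while the coefficient and p-value are
#' retained.
#'
#' @param time Survival times (> 0).
#' @param event Event indicators (1 = death, 0 = censored).
#' @param primary Numeric vector or matrix of the covariate(s) under test.
#' @param adjust Optional matrix of adjustment covariates.
#' @param entity Label for the tested entity (gene or variant id).
#' @param level `"gene"` or `"variant"`.
#' @param inheritance `"allelic"`, `"codominant"` or `"none"`.
#' @return A `data.frame` with one row per primary covariate: `coef`, `se`,
#'   `hr`, `ci_low`, `ci_high`, `wald_p`, `flagged`, `sanitized`.
#' @export
fit_cox <- function(time, event, primary, adjust = NULL,
                    entity = "entity", level = "gene", inheritance = "none") {
  primary <- as.matrix(primary)
  if (is.null(colnames(primary)))
    colnames(primary) <- if (ncol(primary) == 1) "primary"
      else paste0("primary", seq_len(ncol(primary)))
  x <- if (is.null(adjust)) primary else cbind(primary, as.matrix(adjust))
  fit <- cox_partial_fit(time, event, x)
  out <- do.call(rbind, lapply(seq_len(ncol(primary)), function(j) {
    new_survival_record(entity, level, inheritance, !is.null(adjust),
                        colnames(primary)[j], fit, j)
  }))
  attr(out, "fit") <- fit
  out
}

#' Gene-level Cox tests for a cohort
#'
#' One Cox fit per gene with TPM expression as the covariate, unadjusted or
#' adjusted for T/N/M stage. TPM is log-transformed by default
#' (`log(TPM + 1)`): TPM distributions are approximately log-normal and a
#' raw-scale Cox covariate lets a handful of extreme values dominate the
#' partial likelihood; `transform = "identity"` reproduces the raw-scale
#' analysis. Genes whose fit degenerates are flagged.
#'
#' @param cohort An aligned `cohort`.
#' @param genes Gene ids to test (default: all genes in the cohort).
#' @param adjusted Include stage adjustment covariates.
#' @param adjust_vars Clinical columns used for adjustment.
#' @param transform Expression scale for the Cox covariate, `"log1p"`
#'   (default) or `"identity"`.
#' @return `data.frame` of survival records (one per gene).
#' @export
gene_survival <- function(cohort, genes = NULL,
                          adjusted = FALSE,
                          adjust_vars = c("t_stage", "n_stage", "m_stage"),
                          transform = c("log1p", "identity")) {
  transform <- match.arg(transform)
  cl <- cohort$clinical
  if (is.null(genes)) genes <- cohort$expression$genes$gene_id
  adj <- if (adjusted) as.matrix(cl[, adjust_vars, drop = FALSE]) else NULL
  do.call(rbind, lapply(genes, function(gene) {
    y <- cohort$expression$tpm[gene, ]
    if (transform == "log1p") y <- log1p(y)
    rec <- tryCatch(
      fit_cox(cl$time, cl$event, matrix(y, ncol = 1,
                                        dimnames = list(NULL, "expression")),
              adjust = adj, entity = gene, level = "gene"),
      error = function(e) NULL)
    rec
  }))
}

#' Variant-level Cox tests under an inheritance model
#'
#' Hard-called genotypes (imputed dosages rounded to 0/1/2) are tested under
#' the allelic model (dosage as a single numeric covariate) or the codominant
#' model (heterozygous and homozygous-ALT indicators against the
#' homozygous-reference category, one record each). Variants with fewer than
#' three heterozygous AND fewer than three homozygous-ALT carriers are
#' excluded; in the codominant model an absent category simply drops its
#' indicator.
#'
#' @param dosages Dosage vector for the variant.
#' @param clinical A [clinical_table()] in the same sample order.
#' @param inheritance `"allelic"` or `"codominant"`.
#' @param adjusted Include stage adjustment covariates.
#' @param entity Variant identifier for the records.
#' @param adjust_vars Clinical columns used for adjustment (for validation
#'   cohorts lacking N/M, pass `"t_stage"` only).
#' @return `data.frame` of survival records, or `NULL` when the variant is
#'   excluded by the genotype-count filter.
#' @export
variant_survival <- function(dosages, clinical,
                             inheritance = c("allelic", "codominant"),
                             adjusted = FALSE, entity = "variant",
                             adjust_vars = c("t_stage", "n_stage", "m_stage")) {
  inheritance <- match.arg(inheritance)
  hard <- pmin(pmax(round(mean_impute_dosage(dosages)), 0), 2)
  het <- sum(hard == 1); hom <- sum(hard == 2)
  if (het < 3 && hom < 3) return(NULL)   # count-filter exclusion
  adj <- if (adjusted) as.matrix(clinical[, adjust_vars, drop = FALSE]) else NULL
  primary <- if (inheritance == "allelic") {
    matrix(hard, ncol = 1, dimnames = list(NULL, "dosage"))
  } else {
    m <- cbind(het = as.numeric(hard == 1), hom = as.numeric(hard == 2))
    m[, colSums(m) > 0, drop = FALSE]   # drop empty categories
  }
  rec <- fit_cox(clinical$time, clinical$event, primary, adjust = adj,
                 entity = entity, level = "variant",
                 inheritance = inheritance)
  rec$het_count <- het
  rec$homalt_count <- hom
  rec
}

#' Sanitize extreme hazard ratios
#'
#' Converts the hazard ratio and confidence interval to `NA` when the HR
#' exceeds 50 (or, symmetrically, falls below 1/50) or when the CI ratio
#' `ci_high / ci_low` exceeds 100; such estimates arise from tiny genotype
#' groups and are unstable. Coefficients and p-values are retained.
#' Idempotent.
#'
#' @param records `data.frame` of survival records.
#' @param hr_max HR bound (default 50).
#' @param ci_ratio_max CI ratio bound (default 100).
#' @param symmetric Also sanitize HR below `1 / hr_max` (default TRUE).
#' @return The records with `hr`, `ci_low`, `ci_high` set `NA` and
#'   `sanitized = TRUE` where triggered.
#' @export
sanitize_hr <- function(records, hr_max = 50, ci_ratio_max = 100,
                        symmetric = TRUE) {
  bad <- !is.na(records$hr) &
    (records$hr > hr_max |
       (symmetric & records$hr < 1 / hr_max) |
       (!is.na(records$ci_low) & records$ci_high / records$ci_low > ci_ratio_max))
  records$hr[bad] <- NA_real_
  records$ci_low[bad] <- NA_real_
  records$ci_high[bad] <- NA_real_
  records$sanitized <- records$sanitized | bad
  records
}

#' Benjamini-Hochberg correction within a testing family
#'
#' Adds an `fdr` column by applying the BH step-up procedure to `wald_p`
#' within each family defined by `level`, `inheritance` and `adjusted`
#' (gene-level and variant-level results are corrected separately, per
#' model).
#'
#' @param records `data.frame` of survival records.
#' @return The records with an `fdr` column.
#' @export
survival_multiple_testing <- function(records) {
  fam <- interaction(records$level, records$inheritance, records$adjusted,
                     drop = TRUE)
  records$fdr <- NA_real_
  for (f in levels(fam)) {
    i <- fam == f
    records$fdr[i] <- stats::p.adjust(records$wald_p[i], "BH")
  }
  records
}

#' Build the prognostic eGene sets
#'
#' Genes significant (p below `p_threshold`) in the unadjusted model, in the
#' adjusted model, and their union; each union member is labelled favourable
#' (coefficient < 0: higher expression, better survival) or unfavourable
#' (coefficient > 0) using the model(s) in which it was significant.
#' Direction conflicts between the two models are flagged, not resolved.
#'
#' @param unadjusted,adjusted Gene-level survival record `data.frame`s from
#'   [gene_survival()].
#' @param p_threshold Significance threshold (default 0.05).
#' @return A list of class `prognostic_sets` with `unadjusted_set`,
#'   `adjusted_set`, `union_set`, `direction` (named vector over the union,
#'   `"favourable"`/`"unfavourable"`), `conflicts` and a `table` of per-gene
#'   detail.
#' @export
build_prognostic_sets <- function(unadjusted, adjusted, p_threshold = 0.05) {
  ua <- unadjusted[!is.na(unadjusted$wald_p) & unadjusted$wald_p < p_threshold, ]
  ad <- adjusted[!is.na(adjusted$wald_p) & adjusted$wald_p < p_threshold, ]
  union_set <- union(ua$entity, ad$entity)
  direction <- character(0)
  conflicts <- character(0)
  for (gene in union_set) {
    signs <- c(if (gene %in% ua$entity) sign(ua$coef[ua$entity == gene]),
               if (gene %in% ad$entity) sign(ad$coef[ad$entity == gene]))
    if (any(signs == 0)) stop("coefficient exactly zero for ", gene,
                              ": direction undefined")
    if (length(unique(signs)) > 1) conflicts <- c(conflicts, gene)
    direction[gene] <- if (signs[1] < 0) "favourable" else "unfavourable"
  }
  tab <- data.frame(gene_id = union_set,
                    in_unadjusted = union_set %in% ua$entity,
                    in_adjusted = union_set %in% ad$entity,
                    direction = unname(direction[union_set]),
                    conflict = union_set %in% conflicts,
                    stringsAsFactors = FALSE)
  structure(list(unadjusted_set = ua$entity, adjusted_set = ad$entity,
                 union_set = union_set, direction = direction,
                 conflicts = conflicts, table = tab),
            class = "prognostic_sets")
}

#' @export
print.prognostic_sets <- function(x, ...) {
  cat(sprintf(paste0("prognostic_sets: %d unadjusted, %d adjusted, ",
                     "%d union (%d favourable / %d unfavourable)\n"),
              length(x$unadjusted_set), length(x$adjusted_set),
              length(x$union_set), sum(x$direction == "favourable"),
              sum(x$direction == "unfavourable")))
  invisible(x)
}
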