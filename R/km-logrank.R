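#' Kaplan-Meier product-limit estimate per group
#'
#' @param time Survival times.
#' @param event Event indicators (1 = death).
#' @param group Group labels (a single group if omitted).
#' @return A `data.frame` of class `km_curve` with one row per distinct
#'   event/censoring time per group: `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`.
#' @export
km_estimate <- function(time, event, group = NULL) {
  if (is.null(group)) group <- rep("all", length(time))
  stopifnot(length(time) == length(event), length(group) == length(time))
  out <- lapply(split(seq_along(time), group), function(i) {
    if (length(i) == 0) stop("empty group")
    tt <- time[i]; ee <- event[i]
    ut <- sort(unique(tt))
    n_risk <- vapply(ut, function(t) sum(tt >= t), numeric(1))
    n_event <- vapply(ut, function(t) sum(tt == t & ee == 1), numeric(1))
    n_censor <- vapply(ut, function(t) sum(tt == t & ee == 0), numeric(1))
    surv <- cumprod(1 - n_event / n_risk)
    data.frame(group = group[i[1]], time = ut, n_risk = n_risk,
               n_event = n_event, n_censor = n_censor, survival = surv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Unweighted log-rank test
#'
#' Standard k-sample log-rank chi-square with k - 1 degrees of freedom,
#' using the hypergeometric variance of the observed-minus-expected event
#' counts at each distinct event time.
#'
#' @param time Survival times.
#' @param event Event indicators.
#' @param group Group labels (>= 2 non-empty groups).
#' @return A list with `statistic`, `df`, `p_value`, `observed` and
#'   `expected` per group.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  k <- nlevels(group)
  if (k < 2) stop("log-rank test needs at least two non-empty groups")
  if (any(table(group) == 0)) stop("empty group")
  dtimes <- sort(unique(time[event == 1]))
  O <- E <- rep(0, k)
  V <- matrix(0, k, k)
  for (t in dtimes) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(time == t & event == 1)
    n_g <- vapply(levels(group), function(g) sum(at_risk & group == g),
                  numeric(1))
    d_g <- vapply(levels(group), function(g)
      sum(time == t & event == 1 & group == g), numeric(1))
    O <- O + d_g
    E <- E + d * n_g / n
    if (n > 1) {
      c1 <- d * (n - d) / (n - 1)
      V <- V + c1 * (diag(n_g / n, k) - tcrossprod(n_g / n))
    }
  }
  i <- seq_len(k - 1)
  oe <- (O - E)[i]
  stat <- tryCatch(drop(t(oe) %*% solve(V[i, i, drop = FALSE], oe)),
                   error = function(e) NA_real_)
  p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  list(statistic = stat, df = k - 1, p_value = p,
       observed = stats::setNames(O, levels(group)),
       expected = stats::setNames(E, levels(group)))
}

#' Optimal expression-cutoff scan
#'
#' Tests every distinct observed TPM value between the 20th and 80th
#' percentiles (linear-interpolation percentiles) as a high/low cutoff
#' (high = value > cutoff) and selects the cutoff with the lowest log-rank
#' p-value; ties resolve to the smallest cutoff. The selected p is an
#' optimized statistic and is reported as descriptive, never corrected
#' alongside Cox p-values.
#'
#' @param tpm Expression values.
#' @param time,event Survival data.
#' @param lower,upper Percentile band (defaults 0.2 and 0.8).
#' @param min_per_stratum Minimum subjects per stratum (default 3).
#' @return A list of class `cutoff_scan` with `candidates`, `p_values`,
#'   `cutoff` (selected) and `p_value` (selected).
#' @export
optimal_cutoff_scan <- function(tpm, time, event, lower = 0.2, upper = 0.8,
                                min_per_stratum = 3) {
  if (length(tpm) < 10) stop("cutoff scan needs at least 10 subjects")
  if (stats::sd(tpm) == 0) stop("expression is constant; no cutoff exists")
  band <- stats::quantile(tpm, c(lower, upper), type = 7)
  cand <- sort(unique(tpm[tpm >= band[1] & tpm <= band[2]]))
  pvals <- vapply(cand, function(cut) {
    grp <- tpm > cut
    if (sum(grp) < min_per_stratum || sum(!grp) < min_per_stratum)
      return(NA_real_)
    logrank_test(time, event, grp)$p_value
  }, numeric(1))
  ok <- !is.na(pvals)
  if (!any(ok)) stop("no candidate cutoff leaves both strata populated")
  best <- which(ok)[which.min(pvals[ok])]
  structure(list(candidates = cand, p_values = pvals,
                 cutoff = cand[best], p_value = pvals[best]),
            class = "cutoff_scan")
}

#' Genotype-stratified Kaplan-Meier analysis
#'
#' Stratifies subjects by hard-called genotype (0 = homozygous reference,
#' 1 = heterozygous, 2 = homozygous ALT), drops absent categories, and runs
#' the log-rank test over the present strata.
#'
#' @param dosages Dosage vector (hard-called after rounding).
#' @param time,event Survival data.
#' @return A list with `curves` (a `km_curve`), `p_value` and `strata`
#'   (counts per present genotype).
#' @export
genotype_km <- function(dosages, time, event) {
  hard <- pmin(pmax(round(mean_impute_dosage(dosages)), 0), 2)
  present <- sort(unique(hard))
  if (length(present) < 2)
    stop("only one genotype category present; no strata to compare")
  lab <- c("ref", "het", "homalt")[hard + 1]
  curves <- km_estimate(time, event, lab)
  lr <- logrank_test(time, event, lab)
  list(curves = curves, p_value = lr$p_value, statistic = lr$statistic,
       strata = table(lab))
}
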