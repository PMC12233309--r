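test_that("the Cox fitter matches the reference fitter on toy data", {
  time <- 1:6
  event <- rep(1, 6)
  x <- c(0, 1, 0, 1, 0, 1)
  rec <- fit_cox(time, event, x)
  ref <- survival::coxph(survival::Surv(time, event) ~ x, ties = "efron")
  expect_equal(rec$coef, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(rec$se, sqrt(unname(diag(vcov(ref)))), tolerance = 1e-6)
  # a covariate that perfectly orders the deaths is monotone-degenerate:
  # the fitter must flag it rather than report a finite hazard ratio
  mono <- fit_cox(time, event, c(0, 0, 0, 1, 1, 1))
  expect_true(mono$flagged)
})

test_that("the Cox fitter agrees with the reference on random tied data", {
  set.seed(14)
  worst <- 0
  for (i in 1:25) {
    n <- sample(25:60, 1)
    p <- sample(1:3, 1)
    x <- matrix(rnorm(n * p), n, p)
    time <- round(rexp(n, exp(0.4 * x[, 1])) * 30) + 1   # rounding -> ties
    event <- rbinom(n, 1, 0.7)
    if (sum(event) < 3) next
    ours <- eqtlsurv:::cox_partial_fit(time, event, x)
    ref <- survival::coxph(survival::Surv(time, event) ~ x, ties = "efron")
    worst <- max(worst, max(abs(ours$coef - unname(coef(ref)))))
  }
  expect_lt(worst, 1e-6)
})

test_that("a covariate unrelated to hazard has coefficient near zero", {
  set.seed(15)
  n <- 800
  time <- rexp(n); event <- rbinom(n, 1, 0.8); x <- rnorm(n)
  rec <- fit_cox(time, event, x)
  expect_lt(abs(rec$coef), 0.15)
  expect_equal(rec$hr, exp(rec$coef))
})

test_that("rescaling the covariate rescales the coefficient, not the p-value", {
  set.seed(16)
  n <- 80
  x <- rnorm(n)
  time <- rexp(n, exp(0.5 * x)); event <- rbinom(n, 1, 0.8)
  a <- fit_cox(time, event, x)
  b <- fit_cox(time, event, 10 * x)
  expect_equal(b$coef, a$coef / 10, tolerance = 1e-6)
  expect_equal(b$wald_p, a$wald_p, tolerance = 1e-8)
})

test_that("monotone likelihood is flagged and the HR suppressed", {
  # all carriers die first: the coefficient diverges
  time <- c(1, 2, 3, 10, 11, 12, 13)
  event <- rep(1, 7)
  x <- c(1, 1, 1, 0, 0, 0, 0)
  rec <- fit_cox(time, event, x)
  expect_true(rec$flagged)
  expect_true(is.na(rec$hr))
  expect_error(fit_cox(time, rep(0, 7), x), "no events")
  expect_error(fit_cox(time, event, rep(1, 7)), "constant")
})

test_that("variant-level Cox applies the genotype-count exclusion rule", {
  cl <- tiny_clinical(sprintf("S%02d", 1:40), seed = 21)
  d_few <- c(rep(0, 36), 1, 1, 2, 2)        # het = 2 and homalt = 2
  expect_null(variant_survival(d_few, cl))
  d_het3 <- c(rep(0, 37), 1, 1, 1)          # het = 3, homalt = 0
  rec <- variant_survival(d_het3, cl)
  expect_equal(rec$het_count, 3L)
  # codominant with no homalt carriers yields only the het contrast
  rec2 <- variant_survival(d_het3, cl, inheritance = "codominant")
  expect_equal(rec2$term, "het")
})

test_that("allelic and codominant models report the expected records", {
  set.seed(22)
  cl <- tiny_clinical(sprintf("S%02d", 1:60), seed = 23)
  d <- rbinom(60, 2, 0.4)
  al <- variant_survival(d, cl, "allelic", adjusted = TRUE)
  expect_equal(nrow(al), 1L)
  expect_true(al$adjusted)
  co <- variant_survival(d, cl, "codominant")
  expect_setequal(co$term, c("het", "hom"))
  ref <- survival::coxph(survival::Surv(cl$time, cl$event) ~ d)
  expect_equal(al0 <- variant_survival(d, cl)$coef, unname(coef(ref)),
               tolerance = 1e-6)
})

test_that("extreme hazard ratios are sanitized without touching p-values", {
  rec <- data.frame(entity = c("a", "b", "c", "d"),
                    hr = c(60, 2, 0.01, 2),
                    ci_low = c(10, 1, 0.001, 0.01),
                    ci_high = c(300, 4, 0.1, 2.5),
                    wald_p = c(0.01, 0.2, 0.03, 0.04),
                    sanitized = FALSE)
  out <- sanitize_hr(rec)
  expect_true(is.na(out$hr[1]))                    # HR > 50
  expect_false(out$sanitized[2])                   # untouched
  expect_true(out$sanitized[3])                    # HR < 1/50
  expect_true(out$sanitized[4])                    # CI ratio 250 > 100
  expect_equal(out$wald_p, rec$wald_p)
  expect_identical(sanitize_hr(out), out)          # idempotent
  # the symmetric low-HR rule can be switched off
  out2 <- sanitize_hr(rec, symmetric = FALSE)
  expect_false(out2$sanitized[3])
})

test_that("multiple-testing families are corrected separately", {
  rec <- data.frame(entity = c(paste0("g", 1:4), paste0("v", 1:2)),
                    level = rep(c("gene", "variant"), c(4, 2)),
                    inheritance = rep(c("none", "allelic"), c(4, 2)),
                    adjusted = FALSE,
                    wald_p = c(0.01, 0.02, 0.03, 0.04, 0.001, 0.5))
  out <- survival_multiple_testing(rec)
  expect_equal(out$fdr[1:4], rep(0.04, 4))        # gene family untouched by
  expect_equal(out$fdr[5], 0.002)                  # the variant family
  set.seed(10)
  p <- runif(200)
  rec2 <- data.frame(entity = paste0("e", 1:200), level = "gene",
                     inheritance = "none", adjusted = FALSE, wald_p = p)
  expect_equal(survival_multiple_testing(rec2)$fdr, bh_brute_force(p))
})

test_that("prognostic sets form the union with direction labels", {
  mk <- function(ids, coef, p) data.frame(entity = ids, coef = coef,
                                          wald_p = p)
  ua <- mk(c("g1", "g2", "g3"), c(-0.5, 0.3, 0.2), c(0.01, 0.02, 0.5))
  ad <- mk(c("g1", "g2", "g4"), c(-0.4, 0.2, -1), c(0.03, 0.3, 0.01))
  ps <- build_prognostic_sets(ua, ad)
  expect_setequal(ps$union_set, c("g1", "g2", "g4"))
  expect_equal(unname(ps$direction["g1"]), "favourable")
  expect_equal(unname(ps$direction["g2"]), "unfavourable")
  expect_equal(unname(ps$direction["g4"]), "favourable")
  expect_length(ps$conflicts, 0)
  # identical sets collapse to themselves
  ps2 <- build_prognostic_sets(ua, ua)
  expect_setequal(ps2$union_set, c("g1", "g2"))
  # conflicting directions between models are flagged, not resolved
  ad3 <- mk("g1", 0.4, 0.01)
  ps3 <- build_prognostic_sets(ua, ad3)
  expect_equal(ps3$conflicts, "g1")
})

test_that("gene-level detection holds under the null at the nominal rate", {
  set.seed(30)
  n <- 100
  time <- rexp(n); event <- rbinom(n, 1, 0.7)
  p <- replicate(200, fit_cox(time, event, rnorm(n))$wald_p)
  frac <- mean(p < 0.05)
  expect_lt(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})
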