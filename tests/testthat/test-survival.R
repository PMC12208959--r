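# Kaplan-Meier / log-rank and the Cox partial-likelihood fitter, validated
# against closed-form hand calculations and the survival package.

test_that("product-limit estimate matches the hand calculation", {
  km <- km_estimate(c(1, 2), c(1L, 1L))
  expect_equal(km$curves$surv, c(0.5, 0))
  expect_equal(km$curves$n_risk, c(2L, 1L))
  # censoring between events reduces the risk set, not the product
  km2 <- km_estimate(c(1, 1.5, 2), c(1L, 0L, 1L))
  expect_equal(km2$curves$surv, c(2 / 3, 0))
})

test_that("all-censored data is flagged and the log-rank is undefined", {
  km <- km_estimate(c(3, 4, 5, 6), rep(0L, 4), rep(c("a", "b"), 2))
  expect_true(km$all_censored)
  expect_true(is.na(km$logrank_stat))
  expect_equal(nrow(km$curves), 0L)
  expect_error(km_estimate(c(1, 2), c(1L, 1L), factor(c("a", "a"),
                                                      levels = c("a", "b"))),
               "invalid-split")
})

test_that("log-rank detects a hazard ratio of 3 and matches survdiff", {
  skip_if_not_installed("survival")
  set.seed(40)
  hits <- 0L
  for (r in 1:20) {
    t1 <- rexp(100, 1); t2 <- rexp(100, 3)
    tt <- c(t1, t2); ev <- rep(1L, 200)
    gr <- rep(c("lo", "hi"), each = 100)
    km <- km_estimate(tt, ev, gr)
    ref <- survival::survdiff(survival::Surv(tt, ev) ~ gr)
    expect_equal(km$logrank_stat, ref$chisq, tolerance = 1e-8)
    if (km$logrank_p < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("cox fit reproduces coxph (Efron ties) on tied data", {
  skip_if_not_installed("survival")
  set.seed(41)
  n <- 150
  x <- cbind(a = rbinom(n, 1, 0.5), b = rnorm(n))
  tt <- round(rexp(n, 0.08 * exp(0.6 * x[, 1] - 0.25 * x[, 2])), 1) + 0.1
  ev <- rbinom(n, 1, 0.8)
  ours <- cox_fit(x, tt, ev)
  ref <- survival::coxph(survival::Surv(tt, ev) ~ x, ties = "efron")
  expect_equal(ours$coef, unname(coef(ref)), tolerance = 1e-7)
  expect_equal(ours$se, unname(sqrt(diag(vcov(ref)))), tolerance = 1e-7)
  expect_equal(ours$lrt_stat, 2 * diff(ref$loglik), tolerance = 1e-7)
})

test_that("degenerate covariates are rejected", {
  expect_error(cox_fit(cbind(rep(1, 10)), 1:10, rep(1L, 10)), "invalid-input")
  expect_error(cox_fit(cbind(rnorm(3), rnorm(3), rnorm(3), rnorm(3)),
                       1:3, rep(1L, 3)), "invalid-input")
})

test_that("score test at the null equals the log-rank statistic without ties", {
  set.seed(42)
  for (r in 1:5) {
    n <- 80
    x <- rbinom(n, 1, 0.5)
    tt <- rexp(n, 0.1 * exp(0.4 * x))       # continuous: no ties
    fit <- cox_fit(cbind(x), tt, rep(1L, n))
    km <- km_estimate(tt, rep(1L, n), ifelse(x == 1, "hi", "lo"))
    expect_equal(fit$score_stat, km$logrank_stat, tolerance = 1e-6)
  }
})

test_that("null covariates give approximately uniform Wald p-values", {
  set.seed(43)
  ps <- replicate(200, {
    n <- 60
    x <- rnorm(n)
    tt <- rexp(n, 0.1)
    cox_fit(cbind(x), tt, rbinom(n, 1, 0.9))$p_coef[1]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the screen recovers hazard-linked features and keeps nulls near 5%", {
  sim <- simulate_cohort(design = list(
    n_control = 0L, n_patient = 120L, n_features = 250L,
    n_longitudinal = 0L, n_hazard = 30L, n_enriched = 0L,
    frac_de = 0, drift_mode = "none"), seed = 44)
  tr <- sim$truth$features
  scr <- survival_screen(sim$counts, sim$meta,
                         settings = list(endpoints = "from-enrollment",
                                         strata = "both",
                                         covariate_sets = "univariate"),
                         classes = tr$class)
  hz <- tr$feature[tr$hazard_linked]
  kept <- scr$feature[scr$kept]
  expect_gte(mean(hz %in% kept), 0.8)
  expect_lte(mean(setdiff(unique(scr$feature), hz) %in% kept), 0.12)
  # kept rule is exactly reproducible from the stored p-values
  re <- scr$p_coef <= 0.05 & (scr$p_lrt <= 0.05 | scr$p_wald <= 0.05)
  expect_equal(re, scr$kept)
})

test_that("a one-sided Riluzole cohort skips the empty stratum with a warning", {
  sim <- simulate_cohort(design = list(
    n_control = 0L, n_patient = 25L, n_features = 40L,
    n_longitudinal = 0L), seed = 45)
  meta <- sim$meta
  meta$riluzole <- "+"
  expect_warning(
    scr <- survival_screen(sim$counts, meta,
                           settings = list(endpoints = "from-enrollment",
                                           strata = c("+", "-"),
                                           covariate_sets = "univariate")),
    "skipped")
  expect_true(all(scr$stratum == "+"))
  expect_error(survival_screen(sim$counts, meta[, -3]), "schema error")
})
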