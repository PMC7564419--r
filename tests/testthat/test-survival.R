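test_that("fit_cox matches brute-force partial-likelihood maximization", {
  # many small datasets; separable draws (flagged non-converged, oracle
  # pinned at its search boundary) are excluded from the comparison
  compared <- 0
  for (seed in 101:115) {
    for (n in 5:8) {
      d <- make_small_cox_data(n, seed = seed)
      # separable draws legitimately warn inside the fitter before being
      # flagged non-converged below
      fit <- suppressWarnings(fit_cox(d$times, d$events, matrix(d$x, ncol = 1)))
      if (!fit$converged) next
      oracle <- cox_oracle_beta(d$times, d$events, d$x)
      if (abs(oracle) > 7.9) next
      expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-4)
      expect_equal(fit$loglik,
                   cox_partial_loglik(oracle, d$times, d$events, d$x),
                   tolerance = 1e-6)
      compared <- compared + 1
    }
  }
  expect_gte(compared, 20)
})

test_that("exchangeable groups give beta near zero and HR near one", {
  times <- rep(c(1.1, 2.3, 3.7, 4.2), 2)
  events <- rep(c(1, 1, 0, 1), 2)
  x <- rep(c(0, 1), each = 4)
  fit <- fit_cox(times, events, matrix(x, ncol = 1), ties = "breslow")
  expect_equal(unname(fit$coefficients), 0, tolerance = 1e-6)
  expect_equal(unname(fit$hazard_ratio), 1, tolerance = 1e-6)
})

test_that("planted log-hazard is recovered within sampling error", {
  planted <- data.frame(symbol = "RISK1", cnv_gain_prevalence = 0.4,
                        ge_cnv_slope = 1.0,
                        log_hazard_per_unit_expression = 0.7)
  cfg <- synthetic_config(n_patients = 300, n_genes = 5,
                          planted_genes = planted, seed = 21L)
  co <- generate_cohort(cfg)
  clin <- co$clinical
  fit <- fit_cox(clin$survival_years, clin$event,
                 data.frame(expr = co$expression["RISK1", ],
                            met = clin$metastasis_at_diagnosis))
  expect_lt(abs(fit$coefficients["expr"] - 0.7), 3 * fit$se["expr"])
})

test_that("constant covariates and perfect separation are not silently fit", {
  times <- c(1, 2, 3, 4, 5, 6)
  events <- c(1, 1, 1, 1, 1, 1)
  expect_error(fit_cox(times, events, matrix(1, 6, 1)), "constant")
  # all early deaths in one group: monotone likelihood (the fitter warns,
  # and the wrapper must flag the fit as non-converged)
  fit <- suppressWarnings(
    fit_cox(times, events, matrix(c(1, 1, 1, 0, 0, 0), ncol = 1)))
  expect_false(fit$converged)
})

test_that("genewise screen flags inestimable genes and honours alpha", {
  cfg <- synthetic_config(n_patients = 80, n_genes = 30, seed = 13L)
  co <- generate_cohort(cfg)
  feats <- co$expression
  feats["G0001", ] <- 1  # constant feature
  tab <- genewise_screen(feats, co$clinical, alpha = 0.05)
  expect_false(tab$converged[tab$gene == "G0001"])
  expect_false(tab$significant[tab$gene == "G0001"])
  tab0 <- genewise_screen(co$expression, co$clinical, alpha = 0)
  expect_equal(sum(tab0$significant), 0)
  expect_error(genewise_screen(co$expression[, 1:5],
                               co$clinical[6:10, ], alpha = 0.05),
               "no samples shared")
})

test_that("log-rank statistic matches the hand-computed O-E table", {
  # group A dies at 1 and 2, group B at 3 and 4; by hand:
  # O_A = 2, E_A = 1/2 + 1/3 = 5/6, V = 1/4 + 2/9 = 17/36
  # chi-square = (7/6)^2 / (17/36) = 49/17
  lr <- logrank(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
  expect_equal(lr$statistic, 49 / 17, tolerance = 1e-10)
  expect_equal(lr$p, stats::pchisq(49 / 17, 1, lower.tail = FALSE))

  # identical groups: statistic 0, p = 1
  lr0 <- logrank(c(1, 2, 3), c(1, 0, 1), c(1, 2, 3), c(1, 0, 1))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)

  # invariant under swapping group labels
  set.seed(5)
  ta <- rexp(20); tb <- rexp(25); ea <- rbinom(20, 1, 0.7)
  eb <- rbinom(25, 1, 0.7)
  expect_equal(logrank(ta, ea, tb, eb)$statistic,
               logrank(tb, eb, ta, ea)$statistic)

  expect_error(logrank(numeric(0), numeric(0), c(1), c(1)), "non-empty")
})

test_that("log-rank p-values are approximately uniform under the null", {
  set.seed(99)
  times <- rexp(40, 0.3); events <- rbinom(40, 1, 0.8)
  ps <- replicate(1000, {
    g <- sample(rep(c(TRUE, FALSE), each = 20))
    logrank(times[g], events[g], times[!g], events[!g])$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("Kaplan-Meier estimate equals the hand product-limit table", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_true(km$median_defined)
  expect_equal(km$median, 2.5)  # curve sits at 0.5 between times 2 and 3

  flat <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(flat$surv == 1))
  expect_false(flat$median_defined)

  # heavy censoring: events at 2 (d=2, n=5) and 4 (d=1, n=2)
  km2 <- km_estimate(c(1, 2, 2, 3, 4, 5), c(0, 1, 1, 0, 1, 0))
  at_events <- km2$surv[km2$n_event > 0]
  expect_equal(at_events, c(3 / 5, 3 / 10))
  # non-increasing always
  expect_true(all(diff(km2$surv) <= 0))
})

test_that("CNV dichotomization implements both grouping rules", {
  m <- matrix(c(1L, 0L, -1L, 1L), 1, 4,
              dimnames = list("MYC", paste0("P", 1:4)))
  g1 <- dichotomize_by_cnv(m, "MYC", "gain_vs_rest")
  expect_equal(as.character(g1), c("gain", "no_gain", "no_gain", "gain"))
  g2 <- dichotomize_by_cnv(m, "MYC", "gain_or_normal_vs_deletion")
  expect_equal(as.character(g2),
               c("gain_or_normal", "gain_or_normal", "deletion",
                 "gain_or_normal"))
  expect_error(dichotomize_by_cnv(m, "RAD21"), "absent")
})
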