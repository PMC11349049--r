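test_that("response and disease-control classification follow the endpoint definitions", {
  expect_true(classify_responder(patient_row(bor = "PR")))
  expect_true(classify_responder(patient_row(bor = "CR")))
  expect_false(classify_responder(patient_row(bor = "SD", sd_weeks = 40)))
  expect_false(classify_responder(patient_row(bor = "NE")))

  cfg <- endpoint_config()
  expect_true(classify_disease_control(patient_row(bor = "SD", sd_weeks = 24), cfg))
  expect_false(classify_disease_control(patient_row(bor = "SD", sd_weeks = 23), cfg))
  expect_true(classify_disease_control(patient_row(bor = "PR"), cfg))
  expect_error(classify_disease_control(patient_row(bor = "SD", sd_weeks = NA), cfg),
               "sd_duration_weeks")

  # responders are a subset of the disease-control set
  sim <- simulate_cohort(seed = 11)
  expect_true(all(classify_disease_control(sim$patients, cfg)[
    classify_responder(sim$patients)]))
})

test_that("CD8 conversion uses the maximum on-treatment biopsy and the 15% cutoff", {
  cfg <- endpoint_config()
  p <- validate_patients(rbind(
    patient_row("a", baseline = 4, on_tx = "6|16"),
    patient_row("b", baseline = 14, on_tx = "14.9"),
    patient_row("c", baseline = 10, on_tx = "15"),
    patient_row("d", baseline = 10, on_tx = "")), cfg)
  expect_equal(classify_converter(p, cfg),
               c("CONVERTER", "NON_CONVERTER", "CONVERTER", "NOT_EVALUABLE"))
  high <- validate_patients(patient_row(group = "CD8_HIGH", baseline = 40), cfg)
  expect_error(classify_converter(high, cfg), "CD8_LOW")
})

test_that("patient validation enforces record invariants", {
  expect_error(validate_patients(patient_row(baseline = 120)), "\\[0, 100\\]")
  expect_error(validate_patients(patient_row(group = "CD8_HIGH", baseline = 5)),
               "inconsistent")
  expect_error(validate_patients(patient_row(bor = "SD", sd_weeks = NA)),
               "sd_duration_weeks")
  expect_error(validate_patients(rbind(patient_row("x"), patient_row("x"))),
               "duplicated")
})

test_that("beta-binomial intervals reproduce printed trial values and the MC oracle", {
  dcr <- beta_binomial_interval(18, 72)
  expect_equal(c(dcr$lower_pct, dcr$upper_pct), c(15.8, 35.2))
  expect_equal(dcr$point_estimate_pct, 25.0)
  expect_equal(c(dcr$posterior_alpha, dcr$posterior_beta), c(18.4, 55.6))

  orr <- beta_binomial_interval(14, 72)
  expect_equal(c(orr$lower_pct, orr$upper_pct), c(11.3, 29.1))
  expect_equal(orr$point_estimate_pct, 19.4)

  high <- beta_binomial_interval(1, 7)
  expect_equal(c(high$lower_pct, high$upper_pct), c(1.1, 43.8))
  expect_equal(high$point_estimate_pct, 14.3)

  # Beta(6,6) posterior is symmetric about 50%
  sym <- beta_binomial_interval(5, 10, prior = c(1, 1))
  expect_equal(sym$lower_pct + sym$upper_pct, 100, tolerance = 0.11)

  # quantiles agree with a million-draw Monte-Carlo oracle to < 0.1 pp
  set.seed(401)
  for (case in list(c(3, 9), c(18, 72), c(1, 7))) {
    iv <- beta_binomial_interval(case[1], case[2])
    mc <- beta_mc_quantiles(0.4 + case[1], 1.6 + case[2] - case[1])
    expect_lt(abs(100 * iv$lower - 100 * mc[1]), 0.1)
    expect_lt(abs(100 * iv$upper - 100 * mc[2]), 0.1)
  }

  expect_error(beta_binomial_interval(5, 4), "s <= n")
  expect_error(beta_binomial_interval(2, 10, prior = c(-1, 1)), "positive")
})

test_that("interval width shrinks with n and the lower bound rises with s", {
  widths <- sapply(c(20, 40, 80, 160), function(n) {
    iv <- beta_binomial_interval(round(n / 4), n)
    iv$upper_pct - iv$lower_pct
  })
  expect_true(all(diff(widths) < 0))
  lowers <- sapply(0:20, function(s) beta_binomial_interval(s, 20)$lower_pct)
  expect_true(all(diff(lowers) >= 0))
})

test_that("level-0.95 intervals are calibrated under the prior", {
  set.seed(402)
  n <- 72
  p <- rbeta(10000, 0.4, 1.6)
  s <- rbinom(10000, n, p)
  lo <- qbeta(0.025, 0.4 + s, 1.6 + n - s)
  hi <- qbeta(0.975, 0.4 + s, 1.6 + n - s)
  # same posterior the package reports, checked on unrounded quantiles
  iv <- beta_binomial_interval(s[1], n)
  expect_equal(c(iv$posterior_alpha, iv$posterior_beta),
               c(0.4 + s[1], 1.6 + n - s[1]))
  coverage <- mean(p >= lo & p <= hi)
  expect_gte(coverage, 0.94)
  expect_lte(coverage, 0.96)
})

test_that("the no-prior conversion interval supports both readings", {
  both <- conversion_interval_both(14, 39)
  expect_equal(c(both$improper_zero$lower_pct, both$improper_zero$upper_pct),
               c(21.8, 51.4))
  expect_equal(both$improper_zero$point_estimate_pct, 35.9)
  expect_false(isTRUE(all.equal(
    c(both$uniform$lower_pct, both$uniform$upper_pct), c(21.8, 51.4))))

  unif <- conversion_interval(10, 20, "uniform")
  expect_equal(unif$lower_pct + unif$upper_pct, 100, tolerance = 0.11)
  expect_error(conversion_interval(0, 20, "improper_zero"), "uniform")
  expect_error(conversion_interval(20, 20, "improper_zero"), "uniform")
})

test_that("logistic Wald fit matches a likelihood grid-search oracle and known symmetries", {
  # balanced independent design: slope 0, p = 1
  fit <- fit_logistic_wald(c(1, 0, 1, 0), c(1, 1, 0, 0))
  expect_equal(unname(fit$coefficients[2]), 0, tolerance = 1e-8)
  expect_equal(unname(fit$p_values[2]), 1, tolerance = 1e-6)

  set.seed(403)
  for (rep in 1:5) {
    x <- rnorm(16)
    y <- rbinom(16, 1, plogis(0.3 + 0.8 * x))
    if (length(unique(y)) < 2) next
    fit <- fit_logistic_wald(y, x)
    if (!fit$converged) next
    orc <- logistic_grid_oracle(y, x)
    expect_equal(unname(fit$coefficients), orc$coef, tolerance = 1e-4)
    expect_equal(unname(fit$p_values[2]), orc$p[2], tolerance = 1e-4)
  }

  # slope sign equals the responder-vs-non-responder mean difference sign
  set.seed(404)
  for (rep in 1:20) {
    x <- rbinom(40, 1, 0.5)
    y <- rbinom(40, 1, 0.3 + 0.3 * x)
    if (var(x) == 0 || length(unique(y)) < 2) next
    fit <- suppressWarnings(fit_logistic_wald(y, x))
    d <- mean(x[y == 1]) - mean(x[y == 0])
    if (abs(d) > 1e-12 && fit$converged)
      expect_equal(sign(unname(fit$coefficients[2])), sign(d))
  }

  expect_error(fit_logistic_wald(c(1, 0, 1), c(2, 2, 2)), "constant")
  expect_warning(fit_logistic_wald(c(0, 0, 0, 1, 1, 1),
                                   c(1, 2, 3, 10, 11, 12)), "separation")
})

test_that("logistic slope is recovered inside its Wald CI in most seeded replicates", {
  hits <- 0
  for (s in 1:200) {
    set.seed(s)
    x <- rnorm(200)
    y <- rbinom(200, 1, plogis(-1 + 1.5 * x))
    fit <- suppressWarnings(fit_logistic_wald(y, x))
    ci <- fit$coefficients[2] + c(-1.96, 1.96) * fit$standard_errors[2]
    if (ci[1] <= 1.5 && 1.5 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 180)
})

test_that("Fisher exact p equals full enumeration and respects table symmetries", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 1 / 126,
               tolerance = 1e-12)
  set.seed(405)
  for (rep in 1:30) {
    tab <- matrix(rpois(4, 3), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_exact_2x2(tab)
    expect_equal(p, fisher_enum_oracle(tab), tolerance = 1e-12)
    expect_equal(p, fisher_exact_2x2(t(tab)), tolerance = 1e-12)
    expect_equal(p, fisher_exact_2x2(tab[2:1, ]), tolerance = 1e-12)
    expect_equal(p, fisher_exact_2x2(tab[, 2:1]), tolerance = 1e-12)
  }
  expect_warning(p0 <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2,
                                               byrow = TRUE)), "margin")
  expect_equal(p0, 1)
})

test_that("cohort endpoint summary assembles counts, intervals and conversion analysis", {
  pats <- build_counts_cohort()
  res <- summarize_endpoints(pats)
  expect_equal(res$cd8_low$n, 72)
  expect_equal(res$cd8_low$orr$point_estimate_pct, 19.4)
  expect_equal(res$cd8_low$dcr$point_estimate_pct, 25.0)
  expect_equal(res$cd8_high$orr$point_estimate_pct, 14.3)
  expect_equal(res$conversion$evaluable, 39)
  expect_equal(res$conversion$converters, 14)
  expect_equal(res$conversion$rate_pct, 35.9)
  expect_named(res$conversion$intervals, c("improper_zero", "uniform"))
})
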