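test_that("precision ANOVA handles degenerate and truncated panels", {
  const <- matrix(2.88, nrow = 5, ncol = 5)
  res <- precision_anova(const)
  expect_equal(res$cv_intraday, 0)
  expect_equal(res$cv_interday, 0)
  expect_equal(res$cv_total, 0)

  # MS_between < MS_within forces the truncation branch
  panel <- rbind(c(1, 3), c(2.01, 1.99), c(2.2, 1.8))
  res2 <- precision_anova(panel)
  expect_equal(res2$variance_components[["between"]], 0)
  expect_equal(res2$cv_total, res2$cv_intraday, tolerance = 1e-12)

  expect_error(precision_anova(matrix(1, nrow = 1, ncol = 5)),
               class = "mrmquant_invalid_input")
  expect_error(precision_anova(matrix(0, nrow = 3, ncol = 3)),
               class = "mrmquant_undefined_cv")
  df <- data.frame(day = c(1, 1, 2), replicate = c(1, 2, 1),
                   concentration_nmol_L = c(1, 2, 3))
  expect_error(precision_anova(df), class = "mrmquant_invalid_input")
})

test_that("precision ANOVA equals the brute-force oracle on random panels", {
  set.seed(11)
  for (rep in 1:100) {
    d <- sample(2:6, 1); n <- sample(2:6, 1)
    panel <- matrix(abs(rnorm(d * n, 2, 0.5)) + 0.1, nrow = d)
    got <- precision_anova(panel)
    want <- oracle_precision(panel)
    expect_equal(got$grand_mean, want$grand, tolerance = 1e-10)
    expect_equal(got$cv_intraday, want$cv_intra, tolerance = 1e-10)
    expect_equal(got$cv_interday, want$cv_inter, tolerance = 1e-10)
    expect_equal(got$cv_total, want$cv_total, tolerance = 1e-10)
    # decomposition and scale invariance
    expect_equal(got$cv_total^2, got$cv_intraday^2 + got$cv_interday^2,
                 tolerance = 1e-8)
    scaled <- precision_anova(panel * 37.5)
    expect_equal(scaled$cv_total, got$cv_total, tolerance = 1e-10)
  }
})

test_that("simulated precision panels recover the designed CVs", {
  ests <- vapply(1:200, function(s) {
    panel <- simulate_precision_panel(truth = 2.88, cv_within = 0.08,
                                      cv_between = 0.05, seed = s)
    res <- precision_anova(panel)
    c(res$cv_intraday, res$cv_interday)
  }, numeric(2))
  expect_lt(abs(median(ests[1, ]) - 8), 2)
  expect_lt(abs(median(ests[2, ]) - 5), 2)
})

test_that("LLOQ rule follows the monotone-run definition", {
  prof <- data.frame(nominal_nmol_L = c(0.05, 0.08, 0.10, 0.15, 0.20),
                     cv_pct = c(30, 25, 18, 12, 8))
  expect_equal(lloq_from_profile(prof)$lloq, 0.10)

  all_bad <- data.frame(nominal_nmol_L = c(0.1, 0.2), cv_pct = c(25, 22))
  res <- lloq_from_profile(all_bad)
  expect_false(res$determinable)
  expect_true(is.na(res$lloq))

  # a clean level below a noisy one does not qualify
  broken <- data.frame(nominal_nmol_L = c(0.05, 0.08, 0.10, 0.15),
                       cv_pct = c(18, 25, 10, 9))
  expect_equal(lloq_from_profile(broken)$lloq, 0.10)
})

test_that("LLOQ rule equals a brute-force scan on random profiles", {
  set.seed(23)
  for (rep in 1:100) {
    k <- sample(3:10, 1)
    levels <- sort(runif(k, 0.02, 1))
    cvs <- runif(k, 5, 35)
    got <- lloq_from_profile(data.frame(nominal_nmol_L = levels,
                                        cv_pct = cvs))$lloq
    expect_identical(got, oracle_lloq(levels, cvs, 20))
  }
})

test_that("LLOQ is computed from replicate values, not just CVs", {
  prof <- simulate_cv_profile(seed = 3)
  res <- lloq_from_profile(prof)
  # the per-level CVs must match direct computation
  for (i in seq_len(nrow(res$profile))) {
    x <- prof$measured_nmol_L[prof$nominal_nmol_L ==
                                res$profile$nominal_nmol_L[i]]
    expect_equal(res$profile$cv_pct[i], 100 * sd(x) / mean(x),
                 tolerance = 1e-12)
  }
  expect_error(
    lloq_from_profile(data.frame(nominal_nmol_L = c(0.1, 0.1),
                                 measured_nmol_L = c(0.1, 0.11))),
    class = "mrmquant_invalid_input")
})

test_that("linearity fits measured on nominal", {
  exact <- data.frame(nominal = 1:10, measured = 1:10)
  fit <- linearity(exact)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$range, c(1, 10))
  expect_error(linearity(data.frame(nominal = c(1, 1, 1),
                                    measured = c(1, 2, 3))),
               class = "mrmquant_invalid_input")
})

test_that("interference recovery reproduces the triglyceride case", {
  r <- interference_recovery(1.58, 1.2166, interferent = "triglycerides",
                             level = 617)
  expect_equal(r$recovery_pct, 77.0, tolerance = 1e-10)
  expect_false(r$within_limits)

  expect_true(interference_recovery(1.58, 1.58)$within_limits)
  expect_equal(interference_recovery(1.58, 1.58)$recovery_pct, 100)
  # just above the upper limit is flagged
  high <- interference_recovery(1.58, 1.90)
  expect_equal(high$recovery_pct, 120.3, tolerance = 0.05)
  expect_false(high$within_limits)
  expect_error(interference_recovery(0, 1),
               class = "mrmquant_invalid_input")
})

test_that("stability change is unsigned percent change", {
  expect_equal(stability_change(2.88, 2.88), 0)
  expect_equal(stability_change(1.00, 0.94), 6.0, tolerance = 1e-12)
  expect_equal(stability_change(0.53, 0.541), 2.1, tolerance = 0.05)
  expect_equal(stability_change(1.00, 1.06), 6.0, tolerance = 1e-12)
  expect_error(stability_change(0, 1), class = "mrmquant_invalid_input")
})

test_that("method comparison: OLS and Deming on exact lines", {
  ident <- data.frame(reference = c(1, 3, 5, 8), candidate = c(1, 3, 5, 8))
  for (m in c("ols", "deming")) {
    fit <- method_comparison(ident, m)
    expect_equal(fit$slope, 1, tolerance = 1e-10)
    expect_equal(fit$intercept, 0, tolerance = 1e-10)
    expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  }
  dbl <- data.frame(reference = c(1, 3, 5, 8), candidate = 2 * c(1, 3, 5, 8))
  fit2 <- method_comparison(dbl)
  expect_equal(fit2$slope, 2, tolerance = 1e-10)
  expect_equal(fit2$intercept, 0, tolerance = 1e-10)
  expect_error(method_comparison(data.frame(reference = c(2, 2, 2),
                                            candidate = c(1, 2, 3))),
               class = "mrmquant_invalid_input")
})

test_that("Deming resists attenuation where OLS does not", {
  # average slopes over replicate errors-in-variables simulations so the
  # check targets bias, not single-draw sampling noise
  slopes <- vapply(1:20, function(s) {
    pairs <- simulate_method_comparison(n = 200, error_sd = 1.0, seed = s)
    c(method_comparison(pairs, "deming")$slope,
      method_comparison(pairs, "ols")$slope)
  }, numeric(2))
  expect_lt(abs(mean(slopes[1, ]) - 1), 0.05)
  expect_lt(mean(slopes[2, ]), mean(slopes[1, ]))
  expect_lt(mean(slopes[2, ]), 0.95)   # attenuation 6.75/7.75 ~ 0.87
})

test_that("Deming slope is scale-equivariant in y", {
  pairs <- simulate_method_comparison(n = 60, error_sd = 0.3, seed = 29)
  base <- method_comparison(pairs, "deming")$slope
  for (c_scale in c(0.5, 3)) {
    scaled <- pairs
    scaled$candidate <- scaled$candidate * c_scale
    # scaling y by c scales the error variance on y by c^2
    got <- method_comparison(scaled, "deming", lambda = c_scale^2)$slope
    expect_equal(got, c_scale * base, tolerance = 1e-10)
  }
})
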