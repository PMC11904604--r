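test_that("response ratio arithmetic and internal-standard guard", {
  expect_equal(response_ratio(100, 100), 1.0)
  expect_equal(response_ratio(0, 100), 0.0)
  expect_equal(response_ratio(250, 100), 2.5)
  expect_error(response_ratio(100, 0), class = "mrmquant_is_failure")
  expect_error(response_ratio(-1, 100), class = "mrmquant_invalid_input")
})

test_that("two-point calibration passes through both points", {
  c1 <- fit_calibration(data.frame(molar_ratio = c(1, 6),
                                   response_ratio = c(1, 6)))
  expect_equal(c1$slope, 1, tolerance = 1e-12)
  expect_equal(c1$intercept, 0, tolerance = 1e-12)
  expect_equal(c1$r_squared, 1)

  c2 <- fit_calibration(data.frame(molar_ratio = c(1, 6),
                                   response_ratio = c(0.9, 5.9)))
  expect_equal(c2$slope, 1, tolerance = 1e-12)
  expect_equal(c2$intercept, -0.1, tolerance = 1e-12)

  # seven collinear points
  c7 <- fit_calibration(data.frame(molar_ratio = 1:7,
                                   response_ratio = 0.2 + 0.95 * (1:7)))
  expect_equal(c7$r_squared, 1, tolerance = 1e-12)
  expect_equal(c7$n_points, 7L)

  expect_error(fit_calibration(data.frame(molar_ratio = c(2, 2),
                                          response_ratio = c(1, 2))),
               class = "mrmquant_invalid_input")
})

test_that("quantify converts molar ratio to nmol/L through the IS amount", {
  curve <- two_point_curve()
  # molar ratio 1 with the default 2 ng spike in 0.2 mL -> ~3.30 nmol/L
  q <- quantify(1.0, curve)
  expect_equal(q$concentration_nmol_L, 3.30, tolerance = 0.002)
  expect_equal(quantify(0, curve)$concentration_nmol_L, 0)
  # doubling the sample volume halves the concentration at fixed rr
  p2 <- assay_parameters(sample_volume_mL = 0.400)
  expect_equal(quantify(1.0, curve, p2)$concentration_nmol_L,
               q$concentration_nmol_L / 2, tolerance = 1e-12)
  # negative back-calculated ratios floored and flagged
  c_off <- fit_calibration(data.frame(molar_ratio = c(1, 6),
                                      response_ratio = c(1.1, 6.1)))
  qn <- quantify(0.05, c_off)
  expect_equal(qn$concentration_nmol_L, 0)
  expect_true(qn$flag_negative_ratio)
})

test_that("calibration round-trips its own points", {
  pts <- data.frame(molar_ratio = c(1, 6), response_ratio = c(0.93, 5.87))
  curve <- fit_calibration(pts)
  for (i in 1:2) {
    q <- quantify(pts$response_ratio[i], curve)
    expect_equal(q$molar_ratio, pts$molar_ratio[i], tolerance = 1e-10)
  }
})

test_that("concentration is invariant under common scaling of both areas", {
  curve <- two_point_curve()
  base <- quantify(response_ratio(480, 960), curve)$concentration_nmol_L
  for (c_scale in c(1e-3, 0.5, 7, 1e4)) {
    scaled <- quantify(response_ratio(480 * c_scale, 960 * c_scale),
                       curve)$concentration_nmol_L
    expect_equal(scaled, base, tolerance = 1e-12)
  }
})

test_that("noise-free end-to-end quantitation recovers truth within 2%", {
  params <- assay_parameters()
  is_equiv <- labeled_equiv_concentration(params)
  measure_rr <- function(conc) {
    spec <- simulation_spec(native_concentration = conc,
                            labeled_equiv_nmol_L = is_equiv,
                            noise_cv = 0, baseline_sd = 0, seed = 1)
    ar <- integrate_chromatograms(simulate_chromatograms(spec),
                                  c(11.4, 11.7))
    response_ratio(ar$area[ar$transition_id == "native_b11"],
                   ar$area[ar$transition_id == "labeled_b11"])
  }
  cal <- data.frame(molar_ratio = c(1, 6),
                    response_ratio = vapply(c(1, 6) * is_equiv, measure_rr,
                                            numeric(1)))
  curve <- fit_calibration(cal)
  truths <- seq(0.5, 9.5, by = 1)
  measured <- vapply(truths, function(cc)
    quantify(measure_rr(cc), curve, params)$concentration_nmol_L,
    numeric(1))
  expect_true(all(abs(measured - truths) / truths < 0.02))
})

test_that("noisy replicate quantitation lands within 10% at n = 5 (median)", {
  params <- assay_parameters()
  is_equiv <- labeled_equiv_concentration(params)
  curve <- two_point_curve()
  truth <- 2.88
  meds <- vapply(1:20, function(batch) {
    reps <- vapply(1:5, function(r) {
      spec <- simulation_spec(native_concentration = truth,
                              labeled_equiv_nmol_L = is_equiv,
                              noise_cv = 0.05, seed = batch * 100 + r)
      ar <- integrate_chromatograms(simulate_chromatograms(spec),
                                    c(11.4, 11.7))
      rr <- response_ratio(ar$area[ar$transition_id == "native_b11"],
                           ar$area[ar$transition_id == "labeled_b11"])
      quantify(rr, curve, params)$concentration_nmol_L
    }, numeric(1))
    median(reps)
  }, numeric(1))
  expect_true(all(abs(meds - truth) / truth < 0.10))
})

test_that("internal-standard failure flags a sample without killing the batch", {
  curve <- two_point_curve()
  areas <- data.frame(sample_id = c("good", "dead"),
                      native_area = c(500, 400),
                      labeled_area = c(1000, 0))
  out <- quantify_batch(areas, curve)
  expect_true(out$qc_pass[1])
  expect_false(out$qc_pass[2])
  expect_true(is.na(out$concentration_nmol_L[2]))
  expect_match(out$flags[2], "internal-standard-failure")
})
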