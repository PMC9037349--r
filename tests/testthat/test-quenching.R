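test_that("inner-filter correction matches its closed form in both bases", {
  expect_identical(inner_filter_correct(100, 0, 0), 100)
  expect_equal(inner_filter_correct(100, 0.1, 0.1, "e"), 100 * exp(0.1))
  expect_equal(inner_filter_correct(100, 0.1, 0.1, "ten"), 100 * 10^0.1)
  expect_error(inner_filter_correct(100, -0.1, 0), "non-negative")
})

test_that("inner-filter correction is multiplicative and monotone in total absorbance", {
  a_grid <- seq(0, 0.5, by = 0.05)
  for (F0 in c(1, 42, 1e4)) {
    expect_equal(inner_filter_correct(F0, a_grid, a_grid),
                 F0 * inner_filter_correct(1, a_grid, a_grid))
  }
  vals <- inner_filter_correct(1, a_grid, rev(a_grid) * 0.3 + a_grid)
  expect_true(all(diff(vals) > 0))
})

test_that("peak_intensity reads fixed-wavelength and global-max intensities", {
  grid <- seq(290, 450, by = 1)
  g <- spectrum(grid, 100 * exp(-((grid - 335)^2) / (2 * 15^2)), "emission")
  expect_equal(peak_intensity(g, "at_fixed_nm", wavelength_nm = 335), 100)
  expect_equal(peak_intensity(g, "global_max"), 100)

  flat <- spectrum(c(300, 400), c(5, 5), "emission")
  expect_equal(peak_intensity(flat, "at_fixed_nm", wavelength_nm = 350), 5)

  bimodal <- spectrum(c(300, 320, 340, 360), c(8, 1, 1, 10), "emission")
  expect_equal(peak_intensity(bimodal, "global_max"), 10)
  expect_error(peak_intensity(g, "at_fixed_nm", wavelength_nm = 600),
               "outside")
})

test_that("Stern-Volmer fit recovers the generating constant on noise-free data", {
  for (Ksv in c(7.16e4, 5.54e4, 4.06e4)) {
    res <- fit_stern_volmer(make_sv_series(Ksv))
    expect_equal(res$Ksv_per_M, Ksv, tolerance = 1e-9)
    expect_equal(res$intercept, 1, tolerance = 1e-9)
    expect_equal(res$kq_per_M_s, res$Ksv_per_M / res$tau0_s)
    expect_equal(res$mode, "inconclusive")
  }
  # fixed-intercept variant gives the same slope on exact data
  resf <- fit_stern_volmer(make_sv_series(7.16e4),
                           pipeline_config(sv_intercept = "fixed"))
  expect_equal(resf$Ksv_per_M, 7.16e4, tolerance = 1e-9)
  expect_identical(resf$intercept, 1)
})

test_that("k_q follows K_SV / tau0: doubling tau0 halves k_q", {
  s <- make_sv_series(7.16e4)
  r1 <- fit_stern_volmer(s, pipeline_config(tau0_s = 5.78e-9))
  r2 <- fit_stern_volmer(s, pipeline_config(tau0_s = 2 * 5.78e-9))
  expect_equal(r1$kq_per_M_s, 7.16e4 / 5.78e-9, tolerance = 1e-9)
  expect_equal(r1$kq_per_M_s / r2$kq_per_M_s, 2, tolerance = 1e-12)
})

test_that("constant intensities give a flagged zero-slope result", {
  s <- make_series(c(0, 5e-6, 10e-6, 15e-6), rep(100, 4))
  expect_message(res <- fit_stern_volmer(s), "flagged")
  expect_equal(res$Ksv_per_M, 0, tolerance = 1e-12)
  expect_true(res$flagged)
})

test_that("inner-filter correction recovers the true K_SV from attenuated data", {
  Ksv <- 7.16e4
  concs <- seq(0, 15e-6, length.out = 7)
  a_ex <- 2000 * concs   # absorbance ramp proportional to [Q]
  a_em <- 1000 * concs
  true_F <- 100 / (1 + Ksv * concs)
  measured <- true_F * exp(-(a_ex + a_em) / 2)
  s <- make_series(concs, measured, a_ex = a_ex, a_em = a_em)
  corrected <- fit_stern_volmer(s, pipeline_config(inner_filter_base = "e"))
  expect_equal(corrected$Ksv_per_M, Ksv, tolerance = 1e-9)
  # without correction the apparent quenching is biased upward
  raw <- fit_stern_volmer(s, pipeline_config(inner_filter_base = "off"))
  expect_gt(raw$Ksv_per_M, Ksv)
})

test_that("quench-mode classifier applies both magnitude and trend criteria", {
  # reported-style multi-temperature results: kq >> diffusion limit, Ksv falling
  static_set <- list(make_qr(298, 7.16e4, 1.25e13),
                     make_qr(303, 5.54e4, 0.97e13),
                     make_qr(308, 4.06e4, 0.71e13))
  expect_equal(classify_quench_mode(static_set)$mode, "static")

  dynamic_set <- list(make_qr(298, 1e3, 1e9), make_qr(308, 2e3, 1e9))
  expect_equal(classify_quench_mode(dynamic_set)$mode, "dynamic")

  # conflicting criteria: kq above threshold but Ksv increasing
  conflict <- list(make_qr(298, 1e4, 1e13), make_qr(308, 2e4, 1e13))
  expect_equal(classify_quench_mode(conflict)$mode, "inconclusive")

  # single temperature: trend unavailable, verdict inconclusive
  expect_equal(classify_quench_mode(list(make_qr(298, 7e4, 1e13)))$mode,
               "inconclusive")
})

test_that("quench-mode classifier is invariant to input order", {
  set <- list(make_qr(303, 5.54e4, 0.97e13),
              make_qr(308, 4.06e4, 0.71e13),
              make_qr(298, 7.16e4, 1.25e13))
  for (perm in list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1), c(3, 2, 1))) {
    expect_equal(classify_quench_mode(set[perm])$mode, "static")
  }
})

test_that("ANS summary finds the saturation concentration and normalizes to F_o", {
  concs <- c(0, 5, 10, 15, 20) * 1e-6
  s <- make_series(concs, c(100, 60, 40, 39.5, 39.4))
  res <- summarize_ans(s, tolerance = 0.01)
  expect_equal(res$relative_intensity[1], 1)
  expect_equal(res$saturation_conc_M, 15e-6)

  # strictly linear decrease never saturates
  lin <- make_series(concs, 100 - seq(0, 40, length.out = 5))
  expect_true(is.na(summarize_ans(lin, tolerance = 0.01)$saturation_conc_M))

  expect_error(summarize_ans(make_series(c(0, 1e-6), c(100, 90))),
               "distinct concentrations")
})
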