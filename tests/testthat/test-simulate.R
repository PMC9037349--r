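test_that("generators are bit-reproducible under a fixed seed", {
  gs <- generator_spec(seed = 7, noise_cv = 0.02)
  s1 <- generate_titration(gs, 298)
  s2 <- generate_titration(gs, 298)
  expect_identical(s1, s2)
  expect_identical(generate_cd(gs), generate_cd(gs))
  # different seeds give different noise realizations
  s3 <- generate_titration(generator_spec(seed = 8, noise_cv = 0.02), 298)
  expect_false(identical(s1$points[[2]]$spectrum$value,
                         s3$points[[2]]$spectrum$value))
})

test_that("noise-free static-binding generation round-trips through the binding fit", {
  gs <- generator_spec(noise_cv = 0, thermo = NULL, Ka_ref_per_M = 4.28e4,
                       n_sites = 0.9538)
  res <- fit_modified_stern_volmer(generate_titration(gs, 298))
  expect_equal(res$Ka_per_M, 4.28e4, tolerance = 1e-6)
  expect_equal(res$n_sites, 0.9538, tolerance = 1e-6)
})

test_that("noise-free linear-SV generation round-trips through the quenching fit", {
  gs <- generator_spec(noise_cv = 0, quench_model = "linear_sv",
                       Ksv_per_M = 7.16e4)
  res <- fit_stern_volmer(generate_titration(gs, 298))
  expect_equal(res$Ksv_per_M, 7.16e4, tolerance = 1e-9)
  expect_equal(res$intercept, 1, tolerance = 1e-9)
})

test_that("van't Hoff family generation round-trips (dH, dS) exactly", {
  gs <- generator_spec(noise_cv = 0,
                       thermo = list(dH_kcal_mol = 20.25,
                                     dS_cal_mol_K = 89.13))
  fam <- generate_thermo_family(gs)
  expect_length(fam, 3)
  binding <- lapply(fam, fit_modified_stern_volmer)
  th <- vant_hoff(binding)
  expect_equal(th$dH_kcal_mol, 20.25, tolerance = 1e-9)
  expect_equal(th$dS_cal_mol_K, 89.13, tolerance = 1e-9)
  # degenerate thermodynamics: dH = 0 makes Ka flat across temperature
  flat <- generator_spec(noise_cv = 0,
                         thermo = list(dH_kcal_mol = 0, dS_cal_mol_K = 21))
  kas <- vapply(generate_thermo_family(flat), function(s) {
    fit_modified_stern_volmer(s)$Ka_per_M
  }, numeric(1))
  expect_equal(diff(range(kas)) / kas[1], 0, tolerance = 1e-9)
  # dS = 0, dH < 0: Ka decreases with temperature
  falling <- generator_spec(noise_cv = 0,
                            thermo = list(dH_kcal_mol = -8, dS_cal_mol_K = 0))
  kas2 <- vapply(generate_thermo_family(falling), function(s) {
    fit_modified_stern_volmer(s)$Ka_per_M
  }, numeric(1))
  expect_true(all(diff(kas2) < 0))
  expect_error(generate_thermo_family(generator_spec(thermo = NULL)),
               "thermo")
})

test_that("generated inner-filter attenuation is undone by the correction stage", {
  gs <- generator_spec(noise_cv = 0, quench_model = "linear_sv",
                       Ksv_per_M = 7.16e4,
                       inner_filter = list(a_ex_per_M = 2000,
                                           a_em_per_M = 1000, base = "e"))
  s <- generate_titration(gs, 298)
  on_cfg <- pipeline_config(inner_filter_base = "e")
  off_cfg <- pipeline_config(inner_filter_base = "off")
  expect_equal(fit_stern_volmer(s, on_cfg)$Ksv_per_M, 7.16e4,
               tolerance = 1e-9)
  expect_gt(fit_stern_volmer(s, off_cfg)$Ksv_per_M, 7.16e4)
})

test_that("with 1% multiplicative noise the median recovered Ka error stays small", {
  errs <- vapply(1:60, function(seed) {
    gs <- generator_spec(seed = seed, noise_cv = 0.01, thermo = NULL,
                         Ka_ref_per_M = 4.28e4, n_sites = 0.9538)
    fit <- fit_modified_stern_volmer(generate_titration(gs, 298))
    abs(fit$Ka_per_M - 4.28e4) / 4.28e4
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("FRET pair generator calibrates to a target overlap integral", {
  gs <- generator_spec()
  pair <- generate_fret_pair(gs, target_J = 1.2e-14)
  expect_equal(overlap_integral(pair$donor, pair$acceptor), 1.2e-14,
               tolerance = 1e-9)
  expect_equal(forster_radius(overlap_integral(pair$donor, pair$acceptor)),
               2.527, tolerance = 1e-3)
  # rectangular option matches the closed form
  rect <- generate_fret_pair(gs, shape = "rectangular",
                             grid_nm = seq(400, 500, length.out = 1001),
                             rect_range_nm = c(400, 500))
  a <- 400e-7; b <- 500e-7
  J_closed <- gs$acceptor_band$peak_molar_absorptivity *
    (b^5 - a^5) / (5 * (b - a))
  expect_equal(overlap_integral(rect$donor, rect$acceptor), J_closed,
               tolerance = 1e-6)
})

test_that("CD generator hits the helix-estimator anchors", {
  gs <- generator_spec(noise_cv = 0)
  res100 <- analyze_cd(generate_cd(gs, 100), 5e-6, 689, 0.1)
  expect_equal(res100$mre_208, -33000, tolerance = 1e-6)
  res0 <- analyze_cd(generate_cd(gs, 0), 5e-6, 689, 0.1)
  expect_equal(res0$mre_208, -4000, tolerance = 1e-6)
  expect_error(generate_cd(gs, 120), "\\[0, 100\\]")
})
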