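test_that("modified Stern-Volmer fit recovers (Ka, n) from the static-binding law", {
  cases <- list(c(Ka = 4.28e4, n = 0.9538),
                c(Ka = 7.58e4, n = 1.0279),
                c(Ka = 12.97e4, n = 1.1010))
  for (p in cases) {
    res <- fit_modified_stern_volmer(make_binding_series(p["Ka"], p["n"]))
    expect_equal(res$Ka_per_M, unname(p["Ka"]), tolerance = 1e-6)
    expect_equal(res$n_sites, unname(p["n"]), tolerance = 1e-6)
  }
  # exact log-linear case: n = 1, Ka = 1e5 -> slope 1, intercept 5
  res1 <- fit_modified_stern_volmer(make_binding_series(1e5, 1))
  expect_equal(res1$n_sites, 1, tolerance = 1e-9)
  expect_equal(log10(res1$Ka_per_M), 5, tolerance = 1e-9)
})

test_that("points with F >= F_o are excluded with a warning", {
  concs <- seq(0, 15e-6, length.out = 7)
  F <- 100 / (1 + 4.28e4 * concs)
  F[2] <- 100  # no quenching at the smallest [Q]
  s <- make_series(concs, F)
  expect_warning(res <- fit_modified_stern_volmer(s), "excluded")
  expect_equal(res$n_points, 5)
  expect_equal(res$Ka_per_M, 4.28e4, tolerance = 1e-6)
})

test_that("binding fit is invariant to a global intensity scale", {
  concs <- seq(0, 15e-6, length.out = 7)
  base <- make_series(concs, 100 / (1 + 4.28e4 * concs^0.9538))
  for (scale in c(0.01, 3.7, 1e4)) {
    scaled <- make_series(concs, scale * 100 / (1 + 4.28e4 * concs^0.9538))
    a <- fit_modified_stern_volmer(base)
    b <- fit_modified_stern_volmer(scaled)
    expect_equal(b$Ka_per_M, a$Ka_per_M, tolerance = 1e-9)
    expect_equal(b$n_sites, a$n_sites, tolerance = 1e-9)
  }
})

test_that("van't Hoff fit matches an independent closed-form OLS oracle", {
  # oracle: explicit normal-equations OLS of ln K on 1/T, computed once from
  # the reported association constants; frozen values below
  binding <- list(binding_result(298, 4.28e4), binding_result(303, 7.58e4),
                  binding_result(308, 12.97e4))
  th <- vant_hoff(binding, R_cal = 1.987)
  expect_equal(th$dH_kcal_mol, 20.221258313, tolerance = 1e-8)
  expect_equal(th$dS_cal_mol_K, 89.0517785738, tolerance = 1e-8)
  expect_equal(th$force_type, "hydrophobic")
  expect_gt(th$fit_r_squared, 0.999)
})

test_that("van't Hoff round trip: constants generated from (dH, dS) are recovered", {
  R <- 1.987
  dH <- 10; dS <- 50
  temps <- c(288, 298, 308, 318)
  binding <- lapply(temps, function(tk) {
    binding_result(tk, exp(-dH * 1000 / (R * tk) + dS / R))
  })
  th <- vant_hoff(binding, R_cal = R)
  expect_equal(th$dH_kcal_mol, dH, tolerance = 1e-9)
  expect_equal(th$dS_cal_mol_K, dS, tolerance = 1e-9)
  # thermodynamic consistency: -RT ln Ka == dH - T dS at each T
  for (b in binding) {
    lhs <- -R * b$temperature_K * log(b$Ka_per_M) / 1000
    rhs <- gibbs(th$dH_kcal_mol, th$dS_cal_mol_K, b$temperature_K)$dG_kcal_mol
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("flat van't Hoff line yields zero enthalpy and dS = R ln Ka", {
  binding <- lapply(c(298, 303, 308), binding_result, Ka_per_M = 5e4)
  th <- vant_hoff(binding)
  expect_equal(th$dH_kcal_mol, 0, tolerance = 1e-9)
  expect_equal(th$dS_cal_mol_K, 1.987 * log(5e4), tolerance = 1e-9)
  expect_error(vant_hoff(binding[c(1, 1, 2)]), "distinct temperatures")
})

test_that("gibbs satisfies dG = dH - T dS exactly across the reported range", {
  g298 <- gibbs(20.25, 89.13, 298)
  expect_equal(round(g298$TdS_kcal_mol, 2), 26.56)
  expect_equal(round(g298$dG_kcal_mol, 2), -6.31)
  expect_equal(round(gibbs(20.25, 89.13, 303)$dG_kcal_mol, 2), -6.76)
  expect_equal(round(gibbs(20.25, 89.13, 308)$dG_kcal_mol, 2), -7.20)
  expect_equal(gibbs(0, 0, 298), list(TdS_kcal_mol = 0, dG_kcal_mol = 0))
  # identity holds exactly, not just to rounding
  for (tk in seq(280, 320, by = 5)) {
    g <- gibbs(20.25, 89.13, tk)
    expect_identical(g$dG_kcal_mol, 20.25 - g$TdS_kcal_mol)
  }
})

test_that("force classification follows the thermodynamic sign rules", {
  expect_equal(classify_force(20.25, 89.13), "hydrophobic")
  expect_equal(classify_force(-5, 10), "electrostatic")
  expect_equal(classify_force(-5, -10), "hbond_vdw")
  expect_error(classify_force(5, -10), "unclassified")
  expect_message(z <- classify_force(0, 10), "treated as positive")
  expect_equal(z, "hydrophobic")
})

test_that("energy_to_affinity inverts dG = -RT ln K", {
  expect_equal(energy_to_affinity(-9.7, 298), exp(9.7 / (1.987e-3 * 298)))
  expect_equal(energy_to_affinity(-9.7, 298) / 1.30e7, 1, tolerance = 0.01)
  expect_identical(energy_to_affinity(0, 298), 1)
  RT <- 1.987e-3 * 298
  expect_equal(energy_to_affinity(-RT * log(1e6), 298), 1e6,
               tolerance = 1e-12)
  # exact inverse round trip at arbitrary energies and temperatures
  for (dG in c(-12, -3.3, 0.5)) {
    K <- energy_to_affinity(dG, 310)
    expect_equal(-1.987e-3 * 310 * log(K), dG, tolerance = 1e-12)
  }
})
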