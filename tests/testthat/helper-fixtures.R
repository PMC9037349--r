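# Shared fixtures: all synthetic, built in code at test time.

# Emission band (Gaussian, peak at `center`) scaled per point so the scalar
# intensity read at the reference peak equals `intensities[i]`.
make_series <- function(concs_M, intensities, temperature_K = 298,
                        a_ex = rep(NA_real_, length(concs_M)),
                        a_em = rep(NA_real_, length(concs_M)),
                        center = 335) {
  grid <- seq(290, 450, by = 5)
  band <- exp(-((grid - center)^2) / (2 * 20^2))
  pts <- lapply(seq_along(concs_M), function(i) {
    titration_point(concs_M[i],
                    spectrum(grid, band * intensities[i], kind = "emission"),
                    a_ex = a_ex[i], a_em = a_em[i])
  })
  titration_series(pts, temperature_K = temperature_K, excitation_nm = 280,
                   protein_conc_M = 5e-6)
}

# Series whose intensities follow the linear Stern-Volmer law F_o/F = 1+Ksv[Q]
make_sv_series <- function(Ksv, concs_M = seq(0, 15e-6, length.out = 7),
                           F0 = 100, temperature_K = 298) {
  make_series(concs_M, F0 / (1 + Ksv * concs_M), temperature_K)
}

# Series following the n-site static-binding law F = F_o/(1 + Ka [Q]^n)
make_binding_series <- function(Ka, n, concs_M = seq(0, 15e-6, length.out = 7),
                                F0 = 100, temperature_K = 298) {
  make_series(concs_M, F0 / (1 + Ka * concs_M^n), temperature_K)
}

# quenching_result literals (for classifier tests fed with reported values)
make_qr <- function(temperature_K, Ksv, kq) {
  structure(list(temperature_K = temperature_K, Ksv_per_M = Ksv,
                 intercept = 1, r_squared = NA_real_, kq_per_M_s = kq,
                 tau0_s = Ksv / kq, mode = "inconclusive",
                 mode_evidence = "", flagged = FALSE),
            class = "quenching_result")
}
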