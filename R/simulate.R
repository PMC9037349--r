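#' Specification for the synthetic-data generator
#'
#' Collects every knob of the forward model that the analysis stages assume:
#' a Gaussian protein emission band quenched according to a static-binding or
#' linear Stern-Volmer model, an association constant following the van't
#' Hoff temperature dependence, a Gaussian ligand absorption band overlapping
#' the emission band, a far-UV CD trace anchored at a target alpha-helix
#' fraction, optional inner-filter attenuation proportional to quencher
#' concentration, and multiplicative Gaussian instrument noise.
#'
#' Defaults reproduce the study design the analysis was built around:
#' 5 uM protein excited at 280 nm, emission 290-450 nm peaking at 335 nm,
#' a 7-point 0-15 uM quencher titration at 298/303/308 K, binding parameters
#' K_a = 4.28e4 M^-1 and n = 0.9538 at 298 K with van't Hoff coefficients
#' dH = 20.25 kcal mol^-1 and dS = 89.13 cal mol^-1 K^-1, and 1%
#' multiplicative noise.
#'
#' @param seed Integer RNG seed; a fixed seed makes every generator
#'   bit-reproducible.
#' @param temperatures_K Series temperatures.
#' @param quencher_concs_M Titration concentrations (must include 0).
#' @param quench_model `"static_binding"` (F = F_o / (1 + K_a [Q]^n)) or
#'   `"linear_sv"` (F_o/F = 1 + K_SV [Q]).
#' @param Ka_ref_per_M,n_sites Binding parameters; `Ka_ref_per_M` applies at
#'   `ref_temperature_K` when `thermo` is NULL, otherwise K_a(T) comes from
#'   the van't Hoff relation.
#' @param ref_temperature_K Temperature at which `Ka_ref_per_M` applies.
#' @param Ksv_per_M Stern-Volmer constant(s) for `"linear_sv"`; scalar or one
#'   value per temperature.
#' @param thermo NULL or `list(dH_kcal_mol=, dS_cal_mol_K=)`; when set,
#'   ln K_a(T) = -dH/(R T) + dS/R exactly (before noise).
#' @param emission_band `list(center_nm, width_nm, amplitude)` for the
#'   Gaussian donor emission (width is the Gaussian sigma).
#' @param acceptor_band `list(center_nm, width_nm, peak_molar_absorptivity)`
#'   for the Gaussian acceptor absorptivity.
#' @param emission_grid_nm Wavelength grid for emission spectra.
#' @param inner_filter NULL, or `list(a_ex_per_M, a_em_per_M, base)`: the
#'   per-point absorbances ramp linearly with quencher concentration and the
#'   emitted spectra are attenuated by base^-((a_ex+a_em)/2), so the
#'   correction stage must undo it.
#' @param alpha_helix_percent Target helix content for CD traces.
#' @param protein_conc_M,n_residues,path_cm CD conversion parameters.
#' @param excitation_nm Excitation wavelength recorded in the series.
#' @param noise_cv Coefficient of variation of multiplicative Gaussian noise
#'   (0 disables noise).
#' @param R_cal Gas constant (cal mol^-1 K^-1) for the van't Hoff relation.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1L,
                           temperatures_K = c(298, 303, 308),
                           quencher_concs_M = seq(0, 15e-6, length.out = 7),
                           quench_model = c("static_binding", "linear_sv"),
                           Ka_ref_per_M = 4.28e4,
                           n_sites = 0.9538,
                           ref_temperature_K = 298,
                           Ksv_per_M = 7.16e4,
                           thermo = list(dH_kcal_mol = 20.25,
                                         dS_cal_mol_K = 89.13),
                           emission_band = list(center_nm = 335,
                                                width_nm = 20,
                                                amplitude = 100),
                           acceptor_band = list(center_nm = 370,
                                                width_nm = 40,
                                                peak_molar_absorptivity = 1e4),
                           emission_grid_nm = seq(290, 450, by = 1),
                           inner_filter = NULL,
                           alpha_helix_percent = 32.04,
                           protein_conc_M = 5e-6,
                           n_residues = 689,
                           path_cm = 0.1,
                           excitation_nm = 280,
                           noise_cv = 0.01,
                           R_cal = 1.987) {
  quench_model <- match.arg(quench_model)
  if (!any(quencher_concs_M == 0)) {
    stop("quencher_concs_M must include 0 (the F_o reference)", call. = FALSE)
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (alpha_helix_percent < 0 || alpha_helix_percent > 100) {
    stop("alpha_helix_percent must lie in [0, 100]", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), temperatures_K = temperatures_K,
         quencher_concs_M = quencher_concs_M, quench_model = quench_model,
         Ka_ref_per_M = Ka_ref_per_M, n_sites = n_sites,
         ref_temperature_K = ref_temperature_K, Ksv_per_M = Ksv_per_M,
         thermo = thermo, emission_band = emission_band,
         acceptor_band = acceptor_band, emission_grid_nm = emission_grid_nm,
         inner_filter = inner_filter,
         alpha_helix_percent = alpha_helix_percent,
         protein_conc_M = protein_conc_M, n_residues = n_residues,
         path_cm = path_cm, excitation_nm = excitation_nm,
         noise_cv = noise_cv, R_cal = R_cal),
    class = "generator_spec"
  )
}

# K_a at temperature T: van't Hoff when thermo is set, else the reference
# constant (used at any T).
generator_ka <- function(spec, temperature_K) {
  if (!is.null(spec$thermo)) {
    dH_cal <- spec$thermo$dH_kcal_mol * 1000
    exp(-dH_cal / (spec$R_cal * temperature_K) +
          spec$thermo$dS_cal_mol_K / spec$R_cal)
  } else {
    spec$Ka_ref_per_M
  }
}

gaussian_band <- function(grid_nm, center_nm, width_nm, amplitude) {
  amplitude * exp(-((grid_nm - center_nm)^2) / (2 * width_nm^2))
}

apply_noise <- function(values, cv, floor_zero = TRUE) {
  if (cv <= 0) return(values)
  out <- values * (1 + stats::rnorm(length(values), sd = cv))
  if (floor_zero) out <- pmax(out, 0)
  out
}

#' Generate one synthetic titration series
#'
#' Scales a Gaussian emission band per titration point by the chosen quench
#' model, optionally attenuates the "measured" output by the inner-filter
#' factor (so the correction stage must undo it), applies multiplicative
#' noise, and packs the result as a [titration_series()]. Deterministic under
#' a fixed seed; each temperature gets its own RNG stream.
#'
#' @param spec A [generator_spec()].
#' @param temperature_K One of `spec$temperatures_K`.
#' @return A [titration_series()].
#' @export
generate_titration <- function(spec, temperature_K = spec$temperatures_K[1]) {
  ti <- match(temperature_K, spec$temperatures_K)
  if (is.na(ti)) {
    stop("temperature not listed in spec$temperatures_K", call. = FALSE)
  }
  set.seed(spec$seed + ti - 1L)
  grid <- spec$emission_grid_nm
  band <- gaussian_band(grid, spec$emission_band$center_nm,
                        spec$emission_band$width_nm,
                        spec$emission_band$amplitude)
  concs <- sort(spec$quencher_concs_M)
  pts <- vector("list", length(concs))
  for (i in seq_along(concs)) {
    q <- concs[i]
    frac <- switch(spec$quench_model,
      static_binding = 1 / (1 + generator_ka(spec, temperature_K) *
                              q^spec$n_sites),
      linear_sv = {
        ksv <- if (length(spec$Ksv_per_M) > 1) spec$Ksv_per_M[ti]
               else spec$Ksv_per_M
        1 / (1 + ksv * q)
      },
      stop("unknown quench model: ", spec$quench_model, call. = FALSE))
    if (q == 0) frac <- 1
    vals <- band * frac
    a_ex <- a_em <- NA_real_
    if (!is.null(spec$inner_filter)) {
      a_ex <- spec$inner_filter$a_ex_per_M * q
      a_em <- spec$inner_filter$a_em_per_M * q
      base <- spec$inner_filter$base %||% "e"
      att <- (a_ex + a_em) / 2
      vals <- vals / (if (base == "e") exp(att) else 10^att)
    }
    vals <- apply_noise(vals, spec$noise_cv)
    pts[[i]] <- titration_point(
      quencher_conc_M = q,
      spectrum = spectrum(grid, vals, kind = "emission",
                          label = sprintf("sim_%gK_%g", temperature_K, q)),
      a_ex = a_ex, a_em = a_em
    )
  }
  titration_series(pts, temperature_K = temperature_K,
                   excitation_nm = spec$excitation_nm,
                   protein_conc_M = spec$protein_conc_M)
}

#' Generate a family of titration series across temperatures
#'
#' One series per temperature in `spec$temperatures_K`, with K_a(T) following
#' the van't Hoff relation of `spec$thermo`, so the downstream binding and
#' van't Hoff stages can recover (dH, dS).
#'
#' @param spec A [generator_spec()] with `thermo` set and >= 3 temperatures.
#' @return List of [titration_series()], one per temperature.
#' @export
generate_thermo_family <- function(spec) {
  if (is.null(spec$thermo)) {
    stop("generate_thermo_family requires spec$thermo (dH, dS)", call. = FALSE)
  }
  if (length(spec$temperatures_K) < 3L) {
    stop("need >= 3 temperatures for a van't Hoff family", call. = FALSE)
  }
  lapply(spec$temperatures_K, function(tk) generate_titration(spec, tk))
}

#' Generate a matched donor-emission / acceptor-absorptivity pair
#'
#' Gaussian donor emission and Gaussian acceptor molar-absorptivity spectra
#' on a shared grid (or rectangular bands, for closed-form oracle checks).
#' When `target_J` is given, the acceptor amplitude is rescaled so the
#' numerical overlap integral equals the target exactly (J is linear in the
#' acceptor amplitude).
#'
#' @param spec A [generator_spec()].
#' @param shape `"gaussian"` or `"rectangular"`.
#' @param target_J Optional overlap integral (M^-1 cm^3) to calibrate the
#'   acceptor amplitude against.
#' @param grid_nm Shared wavelength grid.
#' @param rect_range_nm Support of the rectangular bands.
#' @return List with `donor` and `acceptor` [spectrum()] objects.
#' @export
generate_fret_pair <- function(spec, shape = c("gaussian", "rectangular"),
                               target_J = NULL,
                               grid_nm = seq(290, 500, by = 0.5),
                               rect_range_nm = c(400, 500)) {
  shape <- match.arg(shape)
  if (shape == "rectangular") {
    donor_vals <- as.numeric(grid_nm >= rect_range_nm[1] &
                               grid_nm <= rect_range_nm[2])
    acc_vals <- donor_vals * spec$acceptor_band$peak_molar_absorptivity
  } else {
    donor_vals <- gaussian_band(grid_nm, spec$emission_band$center_nm,
                                spec$emission_band$width_nm,
                                spec$emission_band$amplitude)
    acc_vals <- gaussian_band(grid_nm, spec$acceptor_band$center_nm,
                              spec$acceptor_band$width_nm,
                              spec$acceptor_band$peak_molar_absorptivity)
  }
  donor <- spectrum(grid_nm, donor_vals, kind = "emission", label = "sim donor")
  acceptor <- spectrum(grid_nm, acc_vals, kind = "absorbance",
                       label = "sim acceptor")
  if (!is.null(target_J)) {
    j0 <- overlap_integral(donor, acceptor)
    acceptor <- spectrum(grid_nm, acc_vals * target_J / j0,
                         kind = "absorbance", label = "sim acceptor")
  }
  list(donor = donor, acceptor = acceptor)
}

#' Generate a synthetic far-UV CD trace
#'
#' Two negative Gaussian bands at 208 and 222 nm, scaled so that the 208-nm
#' mean residue ellipticity equals the inverse of the helix estimator at the
#' target alpha-helix percentage, then converted to observed millidegrees
#' with the spec's concentration, residue count, and path length.
#'
#' @param spec A [generator_spec()].
#' @param alpha_helix_percent Target helix content; defaults to the spec's.
#' @param grid_nm Wavelength grid (must cover 208 nm).
#' @return An ellipticity [spectrum()] in mdeg.
#' @export
generate_cd <- function(spec, alpha_helix_percent = spec$alpha_helix_percent,
                        grid_nm = seq(200, 250, by = 0.5)) {
  mre208 <- helix_percent_to_mre208(alpha_helix_percent)
  shape <- gaussian_band(grid_nm, 208, 6, 1) +
    0.95 * gaussian_band(grid_nm, 222, 7, 1)
  shape_208 <- gaussian_band(208, 208, 6, 1) + 0.95 * gaussian_band(208, 222, 7, 1)
  theta208 <- mre_to_ellipticity(mre208, spec$protein_conc_M,
                                 spec$n_residues, spec$path_cm)
  set.seed(spec$seed)
  vals <- apply_noise(theta208 * shape / shape_208, spec$noise_cv,
                      floor_zero = FALSE)
  spectrum(grid_nm, vals, kind = "ellipticity",
           label = sprintf("sim CD %.2f%% helix", alpha_helix_percent))
}
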