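#' Spectral overlap integral between donor emission and acceptor absorption
#'
#' J = int F(lambda) eps(lambda) lambda^4 dlambda / int F(lambda) dlambda,
#' the donor-emission-weighted average of eps(lambda) lambda^4. The acceptor
#' molar absorptivity (M^-1 cm^-1) is linearly interpolated onto the donor
#' grid, integration is restricted to the overlapping wavelength support
#' (no extrapolation), the wavelength enters the lambda^4 term in cm, and the
#' integrals are evaluated by the trapezoidal rule, so J carries M^-1 cm^3.
#'
#' @param donor_emission Donor emission [spectrum()] (arbitrary intensity
#'   units; J is invariant to its scale).
#' @param acceptor_absorption Acceptor molar absorptivity [spectrum()]
#'   (`kind = "absorbance"`, values in M^-1 cm^-1, all >= 0).
#' @return Overlap integral J in M^-1 cm^3.
#' @export
overlap_integral <- function(donor_emission, acceptor_absorption) {
  validate_spectrum(donor_emission)
  validate_spectrum(acceptor_absorption)
  if (any(acceptor_absorption$value < 0)) {
    stop("acceptor molar absorptivity must be non-negative", call. = FALSE)
  }
  lo <- max(min(donor_emission$wavelength_nm),
            min(acceptor_absorption$wavelength_nm))
  hi <- min(max(donor_emission$wavelength_nm),
            max(acceptor_absorption$wavelength_nm))
  if (lo >= hi) stop("disjoint wavelength ranges", call. = FALSE)
  keep <- donor_emission$wavelength_nm >= lo & donor_emission$wavelength_nm <= hi
  lam_nm <- donor_emission$wavelength_nm[keep]
  if (length(lam_nm) < 2L) {
    stop("fewer than 2 donor grid points on the overlap range", call. = FALSE)
  }
  f <- donor_emission$value[keep]
  if (all(f == 0)) {
    stop("donor intensity is zero everywhere on the overlap range", call. = FALSE)
  }
  eps <- stats::approx(acceptor_absorption$wavelength_nm,
                       acceptor_absorption$value, xout = lam_nm)$y
  lam_cm <- lam_nm * 1e-7
  num <- pracma::trapz(lam_cm, f * eps * lam_cm^4)
  den <- pracma::trapz(lam_cm, f)
  num / den
}

#' Forster critical distance from the overlap integral
#'
#' R0^6 = 8.79e-25 K^2 n^-4 phi J (in cm^6, with J in M^-1 cm^3), the
#' donor-acceptor separation at which transfer efficiency is 50%. Returned
#' in nm.
#'
#' @param J_M_cm3 Overlap integral, M^-1 cm^3, > 0.
#' @param kappa2 Orientation factor (2/3 for isotropic averaging).
#' @param refractive_index Medium refractive index.
#' @param quantum_yield Donor quantum yield.
#' @return Forster radius R0 in nm.
#' @examples
#' forster_radius(1.20e-14, 2/3, 1.336, 0.118)
#' @export
forster_radius <- function(J_M_cm3, kappa2 = 2 / 3, refractive_index = 1.336,
                           quantum_yield = 0.118) {
  if (any(c(J_M_cm3, kappa2, refractive_index, quantum_yield) <= 0)) {
    stop("all Forster radius inputs must be > 0", call. = FALSE)
  }
  r0_cm <- (8.79e-25 * kappa2 * refractive_index^-4 * quantum_yield *
              J_M_cm3)^(1 / 6)
  r0_cm * 1e7
}

#' Energy transfer efficiency from donor intensities
#'
#' E = 1 - F/F_o, the fraction of donor excitation transferred to the
#' acceptor, from the donor intensity without (F_o) and with (F) acceptor.
#'
#' @param F_o Donor intensity alone, > 0.
#' @param F_da Donor intensity in the presence of acceptor, 0 <= F_da <= F_o.
#' @return Efficiency E in [0, 1].
#' @export
fret_efficiency <- function(F_o, F_da) {
  if (F_o <= 0) stop("F_o must be > 0", call. = FALSE)
  if (F_da < 0 || F_da > F_o) {
    stop("F must satisfy 0 <= F <= F_o (negative efficiency otherwise)",
         call. = FALSE)
  }
  1 - F_da / F_o
}

#' Donor-acceptor distance from transfer efficiency
#'
#' Inverts E = R0^6 / (R0^6 + r^6): r = R0 ((1 - E)/E)^(1/6). Undefined at
#' E = 0 (infinite separation) and E = 1 (zero separation).
#'
#' @param E Transfer efficiency, strictly between 0 and 1.
#' @param R0_nm Forster radius in nm, > 0.
#' @return Distance r in nm.
#' @export
donor_acceptor_distance <- function(E, R0_nm) {
  if (E <= 0 || E >= 1) {
    stop("efficiency must lie strictly between 0 and 1", call. = FALSE)
  }
  if (R0_nm <= 0) stop("R0 must be > 0", call. = FALSE)
  R0_nm * ((1 - E) / E)^(1 / 6)
}

#' Full FRET analysis from spectra and donor intensities
#'
#' Computes the overlap integral, Forster radius, transfer efficiency, and
#' donor-acceptor distance in one pass, recording the physical constants
#' used. The returned triple (E, R0, r) satisfies E = R0^6/(R0^6 + r^6) by
#' construction.
#'
#' @param donor_emission Donor emission [spectrum()].
#' @param acceptor_absorption Acceptor molar absorptivity [spectrum()]
#'   (M^-1 cm^-1). Supply raw absorbance via [absorbance_to_molar()] first if
#'   needed.
#' @param F_o,F_da Donor scalar intensities without/with acceptor.
#' @param config A [pipeline_config()] carrying kappa2, refractive index, and
#'   quantum yield.
#' @return An object of class `fret_result`.
#' @export
analyze_fret <- function(donor_emission, acceptor_absorption, F_o, F_da,
                         config = pipeline_config()) {
  J <- overlap_integral(donor_emission, acceptor_absorption)
  R0 <- forster_radius(J, config$kappa2, config$refractive_index,
                       config$quantum_yield)
  E <- fret_efficiency(F_o, F_da)
  r <- if (E > 0 && E < 1) donor_acceptor_distance(E, R0) else NA_real_
  structure(
    list(J_M_cm3 = J, R0_nm = R0, E = E, r_nm = r,
         kappa2 = config$kappa2,
         refractive_index = config$refractive_index,
         quantum_yield = config$quantum_yield),
    class = "fret_result"
  )
}

#' @export
print.fret_result <- function(x, ...) {
  cat(sprintf("<fret_result>  J = %.4g /M cm3, R0 = %.3f nm, E = %.1f%%, r = %.3f nm\n",
              x$J_M_cm3, x$R0_nm, 100 * x$E, x$r_nm))
  invisible(x)
}

#' Convert an absorbance spectrum to molar absorptivity
#'
#' Beer-Lambert: eps(lambda) = A(lambda) / (c l), for an acceptor absorption
#' spectrum recorded at a known molar concentration and path length.
#'
#' @param absorbance An absorbance [spectrum()] (dimensionless A).
#' @param conc_M Chromophore concentration, mol/L, > 0.
#' @param path_cm Path length in cm, > 0.
#' @return A [spectrum()] of molar absorptivity (M^-1 cm^-1).
#' @export
absorbance_to_molar <- function(absorbance, conc_M, path_cm = 1) {
  validate_spectrum(absorbance)
  if (conc_M <= 0 || path_cm <= 0) {
    stop("concentration and path length must be > 0", call. = FALSE)
  }
  spectrum(absorbance$wavelength_nm, absorbance$value / (conc_M * path_cm),
           kind = "absorbance",
           label = paste0(absorbance$label, " (molar)"))
}
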