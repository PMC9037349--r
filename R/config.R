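#' Pipeline configuration
#'
#' Physical constants and fitting options shared across the pipeline stages.
#'
#' @param tau0_s Unquenched donor fluorescence lifetime in seconds. Default
#'   5.78e-9 s, the tryptophan lifetime used to convert the Stern-Volmer
#'   constant to a bimolecular quenching rate constant.
#' @param R_cal Gas constant in cal mol^-1 K^-1 (1.987) used by the van't
#'   Hoff stage.
#' @param kappa2 Dipole orientation factor K^2; 2/3 for freely rotating
#'   dipoles. Must lie in (0, 4].
#' @param refractive_index Refractive index of the medium (default 1.336,
#'   aqueous buffer).
#' @param quantum_yield Donor fluorescence quantum yield (default 0.118).
#' @param n_residues Protein residue count used for mean residue ellipticity
#'   (default 689, the mature camel lactoferrin chain).
#' @param path_length_cm Cuvette path length in cm (default 0.1, a standard
#'   far-UV CD cell).
#' @param inner_filter_base Base of the inner-filter correction factor:
#'   `"e"` (F_c = F e^((A_ex+A_em)/2)) or `"ten"` (the common base-10
#'   variant), or `"off"` to disable correction.
#' @param intensity_metric How the scalar intensity F of each titration point
#'   is read from its spectrum: `"band_integral"` (default; trapezoidal
#'   integral of the whole emission band) or `"peak"` (value at the
#'   wavelength of the unquenched spectrum's maximum). Quenching scales the
#'   band uniformly, so the two give identical F ratios on noise-free data;
#'   the integral pools the independent per-wavelength noise of real spectra
#'   and is therefore far less variable.
#' @param sv_intercept `"free"` (default; intercept reported for QC) or
#'   `"fixed"` (constrained to 1) for the Stern-Volmer fit.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(tau0_s = 5.78e-9,
                            R_cal = 1.987,
                            kappa2 = 2 / 3,
                            refractive_index = 1.336,
                            quantum_yield = 0.118,
                            n_residues = 689,
                            path_length_cm = 0.1,
                            inner_filter_base = c("e", "ten", "off"),
                            intensity_metric = c("band_integral", "peak"),
                            sv_intercept = c("free", "fixed")) {
  inner_filter_base <- match.arg(inner_filter_base)
  intensity_metric <- match.arg(intensity_metric)
  sv_intercept <- match.arg(sv_intercept)
  num <- c(tau0_s = tau0_s, R_cal = R_cal, kappa2 = kappa2,
           refractive_index = refractive_index, quantum_yield = quantum_yield,
           n_residues = n_residues, path_length_cm = path_length_cm)
  if (any(num <= 0)) {
    stop("all physical constants must be > 0: ",
         paste(names(num)[num <= 0], collapse = ", "), call. = FALSE)
  }
  if (kappa2 > 4) stop("kappa2 must lie in (0, 4]", call. = FALSE)
  structure(
    list(tau0_s = tau0_s, R_cal = R_cal, kappa2 = kappa2,
         refractive_index = refractive_index, quantum_yield = quantum_yield,
         n_residues = n_residues, path_length_cm = path_length_cm,
         inner_filter_base = inner_filter_base,
         intensity_metric = intensity_metric, sv_intercept = sv_intercept),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  tau0 = %.3g s, R = %.4g cal/mol/K\n", x$tau0_s, x$R_cal))
  cat(sprintf("  FRET: kappa2 = %.4g, n = %.4g, phi = %.4g\n",
              x$kappa2, x$refractive_index, x$quantum_yield))
  cat(sprintf("  CD: %d residues, path %.3g cm\n", x$n_residues,
              x$path_length_cm))
  cat(sprintf("  inner filter base '%s', SV intercept '%s'\n",
              x$inner_filter_base, x$sv_intercept))
  invisible(x)
}
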