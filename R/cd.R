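#' Convert observed ellipticity to mean residue ellipticity
#'
#' MRE = theta / (10 * C_p * n * l), where theta is the observed ellipticity
#' in mdeg, C_p the molar protein concentration (mol/L), n the number of
#' amino-acid residues, and l the path length in cm. The result carries units
#' of deg cm^2 dmol^-1.
#'
#' @param theta_mdeg Observed ellipticity in millidegrees (scalar or vector).
#' @param protein_conc_M Molar protein concentration, > 0.
#' @param n_residues Residue count, > 0.
#' @param path_cm Cuvette path length in cm, > 0.
#' @return Mean residue ellipticity (deg cm^2 dmol^-1).
#' @examples
#' ellipticity_to_mre(-20, 5e-6, 689, 0.1)
#' @export
ellipticity_to_mre <- function(theta_mdeg, protein_conc_M, n_residues,
                               path_cm) {
  if (protein_conc_M <= 0) stop("protein concentration must be > 0", call. = FALSE)
  if (n_residues <= 0) stop("residue count must be > 0", call. = FALSE)
  if (path_cm <= 0) stop("path length must be > 0", call. = FALSE)
  theta_mdeg / (10 * protein_conc_M * n_residues * path_cm)
}

# algebraic inverse (used by the synthetic generator)
mre_to_ellipticity <- function(mre, protein_conc_M, n_residues, path_cm) {
  mre * 10 * protein_conc_M * n_residues * path_cm
}

#' Alpha-helix content from the 208 nm mean residue ellipticity
#'
#' Linear single-wavelength estimator between the random-coil/beta anchor
#' (MRE_208 = -4000 deg cm^2 dmol^-1) and the pure alpha-helix anchor
#' (MRE_208 = -33000): percent = 100 (-MRE_208 - 4000) / 29000, clipped to
#' [0, 100] with a warning when noise pushes the estimate out of range.
#'
#' @param mre_208 Mean residue ellipticity at 208 nm (deg cm^2 dmol^-1).
#' @return Percentage of alpha-helix in [0, 100].
#' @examples
#' alpha_helix_percent(-33000)  # 100
#' alpha_helix_percent(-4000)   # 0
#' @export
alpha_helix_percent <- function(mre_208) {
  if (!is.finite(mre_208)) stop("MRE_208 must be finite", call. = FALSE)
  pct <- 100 * (-mre_208 - 4000) / (33000 - 4000)
  if (pct < -1e-8 || pct > 100 + 1e-8) {
    warning(sprintf("helix estimate %.2f%% outside [0, 100]; clipped", pct),
            call. = FALSE)
  }
  min(max(pct, 0), 100)
}

# inverse of the helix estimator (generator side)
helix_percent_to_mre208 <- function(percent) {
  if (percent < 0 || percent > 100) {
    stop("alpha-helix percentage must lie in [0, 100]", call. = FALSE)
  }
  -(4000 + percent / 100 * (33000 - 4000))
}

#' Analyze a far-UV CD spectrum
#'
#' Converts an ellipticity spectrum (mdeg vs nm) to mean residue ellipticity,
#' reads MRE at 208 nm by linear interpolation, and estimates the alpha-helix
#' percentage.
#'
#' @param cd_spectrum An ellipticity [spectrum()] in mdeg covering 208 nm.
#' @param protein_conc_M,n_residues,path_cm Conversion parameters; see
#'   [ellipticity_to_mre()].
#' @return An object of class `cd_result` with `mre` (a [spectrum()]-like MRE
#'   trace), `mre_208`, and `alpha_helix_percent`.
#' @export
analyze_cd <- function(cd_spectrum, protein_conc_M, n_residues, path_cm) {
  validate_spectrum(cd_spectrum)
  if (cd_spectrum$kind != "ellipticity") {
    stop("analyze_cd expects an ellipticity spectrum", call. = FALSE)
  }
  mre_vals <- ellipticity_to_mre(cd_spectrum$value, protein_conc_M,
                                 n_residues, path_cm)
  mre <- spectrum(cd_spectrum$wavelength_nm, mre_vals, kind = "ellipticity",
                  label = paste0(cd_spectrum$label, " (MRE)"))
  mre_208 <- spectrum_value_at(mre, 208)
  structure(
    list(mre = mre, mre_208 = mre_208,
         alpha_helix_percent = alpha_helix_percent(mre_208),
         label = cd_spectrum$label),
    class = "cd_result"
  )
}

#' @export
print.cd_result <- function(x, ...) {
  cat(sprintf("<cd_result>  MRE_208 = %.1f deg cm2/dmol, alpha-helix = %.2f%%\n",
              x$mre_208, x$alpha_helix_percent))
  invisible(x)
}

#' Compare helix content of complexed samples against the native protein
#'
#' @param native A `cd_result` for the free protein.
#' @param complexed List of `cd_result` objects (e.g. different
#'   protein:ligand molar ratios), in presentation order.
#' @return A data.frame with columns `label`, `alpha_helix_percent`, and
#'   `delta_vs_native` (percentage points).
#' @export
compare_helix <- function(native, complexed) {
  if (inherits(complexed, "cd_result")) complexed <- list(complexed)
  if (!length(complexed)) stop("need at least one complexed result", call. = FALSE)
  rows <- lapply(seq_along(complexed), function(i) {
    x <- complexed[[i]]
    data.frame(label = if (nzchar(x$label)) x$label else sprintf("complex_%d", i),
               alpha_helix_percent = x$alpha_helix_percent,
               delta_vs_native = x$alpha_helix_percent - native$alpha_helix_percent)
  })
  out <- do.call(rbind, rows)
  attr(out, "native_alpha_helix_percent") <- native$alpha_helix_percent
  out
}
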