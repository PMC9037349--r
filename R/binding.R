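#' Modified Stern-Volmer binding fit
#'
#' For static quenching through an n-site binding equilibrium, the double
#' logarithmic form log10((F_o - F)/F) = log10(K_a) + n log10([Q]) is linear
#' in log10 of the quencher concentration. Ordinary least squares on the
#' nonzero-concentration points yields the association constant K_a
#' (intercept, as 10^intercept) and the number of binding sites n (slope).
#' Points with F >= F_o (no quenching; log undefined) are excluded with a
#' warning.
#'
#' @param series A [titration_series()].
#' @param config A [pipeline_config()]; controls inner-filter correction of
#'   the intensities, as in [fit_stern_volmer()].
#' @return An object of class `binding_result` with `temperature_K`,
#'   `Ka_per_M`, `n_sites`, `r_squared`.
#' @export
fit_modified_stern_volmer <- function(series, config = pipeline_config()) {
  si <- series_intensities(series, config)
  F0 <- si$F[si$conc == 0]
  nz <- si$conc > 0
  usable <- nz & si$F < F0
  if (any(nz & !usable)) {
    warning(sprintf("%d point(s) with F >= F_o excluded from the double-log fit",
                    sum(nz & !usable)), call. = FALSE)
  }
  if (sum(usable) < 3L) {
    stop("modified Stern-Volmer fit needs >= 3 usable nonzero points with F < F_o",
         call. = FALSE)
  }
  x <- log10(si$conc[usable])
  y <- log10((F0 - si$F[usable]) / si$F[usable])
  if (length(unique(x)) < 2L) {
    stop("all usable points at a single concentration", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  structure(
    list(temperature_K = series$temperature_K,
         Ka_per_M = 10^unname(co[1]),
         n_sites = unname(co[2]),
         r_squared = r_squared_of(fit, y),
         n_points = sum(usable)),
    class = "binding_result"
  )
}

#' Construct a binding result directly
#'
#' For feeding literature or externally fitted (K_a, n) values into the
#' thermodynamic stage.
#'
#' @param temperature_K Temperature in kelvin.
#' @param Ka_per_M Association constant, M^-1, > 0.
#' @param n_sites Number of binding sites, > 0.
#' @param r_squared Optional goodness of fit.
#' @return A `binding_result`.
#' @export
binding_result <- function(temperature_K, Ka_per_M, n_sites = 1,
                           r_squared = NA_real_) {
  if (Ka_per_M <= 0) stop("Ka must be > 0", call. = FALSE)
  if (n_sites <= 0) stop("n_sites must be > 0", call. = FALSE)
  structure(
    list(temperature_K = as.numeric(temperature_K),
         Ka_per_M = as.numeric(Ka_per_M),
         n_sites = as.numeric(n_sites),
         r_squared = r_squared, n_points = NA_integer_),
    class = "binding_result"
  )
}

#' @export
print.binding_result <- function(x, ...) {
  cat(sprintf("<binding_result>  T = %.0f K: Ka = %.4g /M, n = %.4f, R2 = %s\n",
              x$temperature_K, x$Ka_per_M, x$n_sites,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared))))
  invisible(x)
}

#' van't Hoff analysis of temperature-dependent binding constants
#'
#' Fits ln K_a = -dH/(R T) + dS/R by ordinary least squares of ln K_a on 1/T
#' over at least three distinct temperatures. The slope gives the binding
#' enthalpy dH = -slope * R and the intercept the entropy dS = intercept * R
#' (R in cal mol^-1 K^-1; dH reported in kcal mol^-1, dS in cal mol^-1 K^-1).
#' The Gibbs energy at each input temperature follows from
#' dG = dH - T dS, and the sign pattern of (dH, dS) classifies the dominant
#' interaction force via [classify_force()].
#'
#' @param binding List of `binding_result` objects at >= 3 distinct
#'   temperatures.
#' @param R_cal Gas constant in cal mol^-1 K^-1.
#' @return An object of class `thermo_result` with `dH_kcal_mol`,
#'   `dS_cal_mol_K`, `fit_r_squared`, `per_T` (data.frame of temperature_K,
#'   TdS_kcal_mol, dG_kcal_mol), and `force_type`.
#' @export
vant_hoff <- function(binding, R_cal = 1.987) {
  if (inherits(binding, "binding_result")) binding <- list(binding)
  tempK <- vapply(binding, `[[`, numeric(1), "temperature_K")
  Ka <- vapply(binding, `[[`, numeric(1), "Ka_per_M")
  if (length(unique(tempK)) < 3L) {
    stop("van't Hoff analysis needs >= 3 distinct temperatures", call. = FALSE)
  }
  ord <- order(tempK)
  tempK <- tempK[ord]; Ka <- Ka[ord]
  x <- 1 / tempK
  y <- log(Ka)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  dH_cal <- -unname(co[2]) * R_cal
  dS_cal <- unname(co[1]) * R_cal
  r2 <- r_squared_of(fit, y)
  dH_kcal <- dH_cal / 1000
  per_T <- do.call(rbind, lapply(tempK, function(tk) {
    g <- gibbs(dH_kcal, dS_cal, tk)
    data.frame(temperature_K = tk, TdS_kcal_mol = g$TdS_kcal_mol,
               dG_kcal_mol = g$dG_kcal_mol)
  }))
  force <- classify_force(dH_kcal, dS_cal)
  structure(
    list(dH_kcal_mol = dH_kcal, dS_cal_mol_K = dS_cal,
         fit_r_squared = r2, per_T = per_T, force_type = force,
         R_cal = R_cal),
    class = "thermo_result"
  )
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("<thermo_result>  dH = %.4g kcal/mol, dS = %.4g cal/mol/K, force: %s\n",
              x$dH_kcal_mol, x$dS_cal_mol_K, x$force_type))
  print(x$per_T, row.names = FALSE)
  invisible(x)
}

#' Gibbs free energy from enthalpy and entropy
#'
#' dG = dH - T dS, with dH in kcal mol^-1 and dS in cal mol^-1 K^-1; the TdS
#' product is converted to kcal so the identity holds in kcal throughout.
#'
#' @param dH_kcal_mol Enthalpy change, kcal mol^-1.
#' @param dS_cal_mol_K Entropy change, cal mol^-1 K^-1.
#' @param temperature_K Temperature in kelvin, > 0.
#' @return List with `TdS_kcal_mol` and `dG_kcal_mol`.
#' @examples
#' gibbs(20.25, 89.13, 298)
#' @export
gibbs <- function(dH_kcal_mol, dS_cal_mol_K, temperature_K) {
  if (temperature_K <= 0) stop("temperature must be > 0 K", call. = FALSE)
  TdS <- temperature_K * dS_cal_mol_K / 1000
  list(TdS_kcal_mol = TdS, dG_kcal_mol = dH_kcal_mol - TdS)
}

#' Classify the dominant interaction force from thermodynamic signs
#'
#' The sign pattern of the binding enthalpy and entropy indicates the force
#' driving complex formation: both positive, hydrophobic interactions
#' (entropy-driven desolvation); negative enthalpy with positive entropy,
#' electrostatic; both negative, hydrogen bonding and van der Waals contacts.
#' Zero values are treated as positive (with a message). The remaining
#' pattern (dH > 0, dS < 0) is outside the rule set and raises an error.
#'
#' @param dH_kcal_mol Enthalpy change (sign used).
#' @param dS_cal_mol_K Entropy change (sign used).
#' @return `"hydrophobic"`, `"electrostatic"`, or `"hbond_vdw"`.
#' @export
classify_force <- function(dH_kcal_mol, dS_cal_mol_K) {
  if (dH_kcal_mol == 0 || dS_cal_mol_K == 0) {
    message("zero dH or dS treated as positive for force classification")
  }
  h_pos <- dH_kcal_mol >= 0
  s_pos <- dS_cal_mol_K >= 0
  if (h_pos && s_pos) return("hydrophobic")
  if (!h_pos && s_pos) return("electrostatic")
  if (!h_pos && !s_pos) return("hbond_vdw")
  stop("dH > 0 with dS < 0: combination unclassified by the sign rules",
       call. = FALSE)
}

#' Convert a binding free energy to an affinity constant
#'
#' Inverts dG = -R T ln K: K = exp(-dG / (R T)), with R = 1.987e-3
#' kcal mol^-1 K^-1. Used to translate docking energies into affinities.
#'
#' @param dG_kcal_mol Binding free energy, kcal mol^-1 (negative for
#'   favourable binding).
#' @param temperature_K Temperature in kelvin (default 298).
#' @param R_kcal Gas constant in kcal mol^-1 K^-1.
#' @return Affinity constant (M^-1 scale as conventionally reported).
#' @examples
#' energy_to_affinity(-9.7)          # ~1.3e7
#' @export
energy_to_affinity <- function(dG_kcal_mol, temperature_K = 298,
                               R_kcal = 1.987e-3) {
  if (temperature_K <= 0) stop("temperature must be > 0 K", call. = FALSE)
  exp(-dG_kcal_mol / (R_kcal * temperature_K))
}
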