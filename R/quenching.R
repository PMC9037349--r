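#' Inner-filter correction of fluorescence intensity
#'
#' Attenuation of the excitation beam and reabsorption of emitted light by an
#' absorbing sample bias measured intensities downward. The correction
#' multiplies the observed intensity by base^((A_ex + A_em)/2), where A_ex and
#' A_em are the absorbances at the excitation and emission wavelengths. The
#' default base is e; the base-10 variant common in the literature is
#' available.
#'
#' @param F_obs Measured intensity (scalar or vector).
#' @param a_ex,a_em Absorbances at the excitation and emission wavelengths,
#'   both >= 0.
#' @param base `"e"` or `"ten"`.
#' @return Corrected intensity.
#' @examples
#' inner_filter_correct(100, 0.1, 0.1)            # 100 * exp(0.1)
#' inner_filter_correct(100, 0.1, 0.1, "ten")     # 100 * 10^0.1
#' @export
inner_filter_correct <- function(F_obs, a_ex, a_em, base = c("e", "ten")) {
  base <- match.arg(base)
  if (any(a_ex < 0) || any(a_em < 0)) {
    stop("absorbances must be non-negative", call. = FALSE)
  }
  fac <- (a_ex + a_em) / 2
  F_obs * if (base == "e") exp(fac) else 10^fac
}

# R^2 without summary.lm (which warns on exact synthetic fits)
r_squared_of <- function(fit, y) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum(stats::resid(fit)^2) / ss_tot
}

#' Scalar intensity read from an emission spectrum
#'
#' Returns the single intensity used as F in the quenching fits. The default
#' reads at a fixed wavelength (linear interpolation), so that every point of
#' a titration is sampled at the same wavelength; `"global_max"` returns the
#' spectrum maximum.
#'
#' @param spectrum An emission [spectrum()].
#' @param mode `"at_fixed_nm"` or `"global_max"`.
#' @param wavelength_nm Wavelength for `"at_fixed_nm"`; must lie inside the
#'   grid.
#' @return Intensity value.
#' @export
peak_intensity <- function(spectrum, mode = c("global_max", "at_fixed_nm"),
                           wavelength_nm = NULL) {
  mode <- match.arg(mode)
  validate_spectrum(spectrum)
  if (spectrum$kind != "emission") {
    stop("peak_intensity expects an emission spectrum", call. = FALSE)
  }
  if (mode == "global_max") return(max(spectrum$value))
  if (is.null(wavelength_nm)) {
    stop("wavelength_nm required for mode 'at_fixed_nm'", call. = FALSE)
  }
  spectrum_value_at(spectrum, wavelength_nm)
}

# Scalar F per titration point. Quenching in this pipeline scales the whole
# emission band (the model assumes no shape change), so any shape-invariant
# functional of the spectrum yields the same F ratios; the default integrates
# the band (trapezoid), which pools the independent per-wavelength noise of a
# measured spectrum, while "peak" reads at lambda_max of the [Q]=0 spectrum.
# Inner-filter correction is applied per point when absorbances are present
# and correction is enabled.
series_intensities <- function(series, config) {
  concs <- titration_concs(series)
  ref <- series$points[[which(concs == 0)]]$spectrum
  lambda_ref <- ref$wavelength_nm[which.max(ref$value)]
  f <- vapply(series$points, function(p) {
    val <- if (config$intensity_metric == "band_integral") {
      pracma::trapz(p$spectrum$wavelength_nm, p$spectrum$value)
    } else {
      spectrum_value_at(p$spectrum, lambda_ref)
    }
    if (config$inner_filter_base != "off" && !is.na(p$a_ex) && !is.na(p$a_em)) {
      val <- inner_filter_correct(val, p$a_ex, p$a_em,
                                  base = config$inner_filter_base)
    }
    val
  }, numeric(1))
  list(conc = concs, F = f, lambda_ref = lambda_ref)
}

#' Stern-Volmer quenching fit
#'
#' Fits F_o/F = 1 + K_SV [Q] by ordinary least squares of F_o/F on the
#' quencher concentration, after inner-filter correction of each point when
#' absorbances are available. The slope is the Stern-Volmer constant K_SV
#' (M^-1); the bimolecular quenching rate constant is k_q = K_SV / tau0. With
#' a single temperature the quenching mode is left `"inconclusive"`; use
#' [classify_quench_mode()] on results from several temperatures.
#'
#' @param series A [titration_series()].
#' @param config A [pipeline_config()].
#' @return An object of class `quenching_result` with fields `temperature_K`,
#'   `Ksv_per_M`, `intercept`, `r_squared`, `kq_per_M_s`, `tau0_s`, `mode`,
#'   `mode_evidence`, `flagged`.
#' @export
fit_stern_volmer <- function(series, config = pipeline_config()) {
  si <- series_intensities(series, config)
  i0 <- which(si$conc == 0)
  F0 <- si$F[i0]
  if (F0 <= 0) stop("reference intensity F_o must be positive", call. = FALSE)
  nz <- si$conc > 0
  if (sum(nz) < 2L) {
    stop("Stern-Volmer fit needs >= 2 nonzero-concentration points",
         call. = FALSE)
  }
  y <- F0 / si$F
  x <- si$conc
  if (config$sv_intercept == "fixed") {
    fit <- stats::lm(I(y - 1) ~ 0 + x)
    slope <- unname(stats::coef(fit)[1])
    intercept <- 1
  } else {
    fit <- stats::lm(y ~ x)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
  }
  r2 <- r_squared_of(fit, if (config$sv_intercept == "fixed") y - 1 else y)
  flagged <- slope <= 0
  if (flagged) {
    message(sprintf("Stern-Volmer slope %.4g <= 0 at %.0f K: no measurable quenching; result flagged",
                    slope, series$temperature_K))
  }
  structure(
    list(temperature_K = series$temperature_K,
         Ksv_per_M = slope,
         intercept = intercept,
         r_squared = r2,
         kq_per_M_s = slope / config$tau0_s,
         tau0_s = config$tau0_s,
         mode = "inconclusive",
         mode_evidence = "single-temperature fit; run classify_quench_mode on >= 2 temperatures",
         flagged = flagged,
         lambda_ref_nm = si$lambda_ref),
    class = "quenching_result"
  )
}

#' @export
print.quenching_result <- function(x, ...) {
  cat(sprintf("<quenching_result>  T = %.0f K: Ksv = %.4g /M, kq = %.4g /M/s (tau0 = %.3g s), R2 = %.4f%s\n",
              x$temperature_K, x$Ksv_per_M, x$kq_per_M_s, x$tau0_s,
              x$r_squared, if (isTRUE(x$flagged)) " [flagged]" else ""))
  invisible(x)
}

#' Classify the quenching mechanism from multi-temperature results
#'
#' Two criteria distinguish static (ground-state complex) from dynamic
#' (collisional) quenching: (i) the magnitude of k_q relative to the
#' diffusion-limited maximum collisional quenching constant, 2e10 M^-1 s^-1 -
#' k_q far above it cannot arise from diffusive encounters; and (ii) the
#' temperature trend of K_SV - static quenching weakens on heating (complex
#' dissociation) while dynamic quenching strengthens (faster diffusion). The
#' verdict is `"static"` if every k_q exceeds the threshold and K_SV is
#' strictly decreasing with temperature, `"dynamic"` if every k_q is at or
#' below the threshold and K_SV is strictly increasing, `"inconclusive"`
#' otherwise (including whenever fewer than two temperatures are supplied).
#'
#' @param results List of `quenching_result` objects (any order).
#' @param kq_threshold Diffusion-limit threshold in M^-1 s^-1.
#' @return List with `mode` and `evidence`.
#' @export
classify_quench_mode <- function(results, kq_threshold = 2e10) {
  if (inherits(results, "quenching_result")) results <- list(results)
  if (!length(results)) stop("need at least one quenching result", call. = FALSE)
  tmp <- vapply(results, `[[`, numeric(1), "temperature_K")
  ord <- order(tmp)
  tmp <- tmp[ord]
  ksv <- vapply(results, `[[`, numeric(1), "Ksv_per_M")[ord]
  kq <- vapply(results, `[[`, numeric(1), "kq_per_M_s")[ord]
  all_above <- all(kq > kq_threshold)
  all_below <- all(kq <= kq_threshold)
  trend <- if (length(tmp) >= 2L) {
    if (all(diff(ksv) < 0)) "decreasing"
    else if (all(diff(ksv) > 0)) "increasing"
    else "mixed"
  } else "unavailable"
  mode <- if (all_above && trend %in% c("decreasing")) "static"
    else if (all_below && trend == "increasing") "dynamic"
    else "inconclusive"
  evidence <- sprintf(
    "k_q in [%.3g, %.3g] /M/s vs threshold %.3g (%s); K_SV %s with temperature over %d temperature(s)",
    min(kq), max(kq), kq_threshold,
    if (all_above) "all above" else if (all_below) "all at/below" else "mixed",
    trend, length(tmp))
  list(mode = mode, evidence = evidence)
}

#' Summarize an ANS displacement titration
#'
#' For a titration followed by extrinsic ANS fluorescence, computes the
#' relative intensity F/F_o at each quencher concentration and locates the
#' saturation concentration: the first concentration at which the step change
#' from the previous point, relative to F_o, falls below `tolerance`.
#' Saturation marks the ligand concentration at which ANS displacement from
#' hydrophobic surface is complete.
#'
#' @param series A [titration_series()] (ANS-excited).
#' @param tolerance Relative step-change threshold (default 0.01, i.e. 1% of
#'   F_o per titration step).
#' @param config A [pipeline_config()].
#' @return An object of class `ans_result` with `quencher_conc_M`,
#'   `relative_intensity`, and `saturation_conc_M` (NA when never reached).
#' @export
summarize_ans <- function(series, tolerance = 0.01,
                          config = pipeline_config()) {
  if (length(series$points) < 3L) {
    stop("ANS summary needs at least 3 titration points", call. = FALSE)
  }
  si <- series_intensities(series, config)
  F0 <- si$F[si$conc == 0]
  rel <- si$F / F0
  steps <- abs(diff(si$F)) / F0
  sat_idx <- which(steps < tolerance)
  saturation <- if (length(sat_idx)) si$conc[min(sat_idx) + 1L] else NA_real_
  structure(
    list(quencher_conc_M = si$conc,
         relative_intensity = rel,
         saturation_conc_M = saturation,
         tolerance = tolerance),
    class = "ans_result"
  )
}

#' @export
print.ans_result <- function(x, ...) {
  cat(sprintf("<ans_result>  %d points; saturation at %s\n",
              length(x$quencher_conc_M),
              if (is.na(x$saturation_conc_M)) "none"
              else sprintf("%.3g M", x$saturation_conc_M)))
  invisible(x)
}
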