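#' Construct a spectrum
#'
#' A spectrum is a single wavelength-indexed trace: fluorescence emission
#' intensity (arbitrary units), absorbance (dimensionless), or circular
#' dichroism ellipticity (mdeg), sampled on a strictly increasing wavelength
#' grid in nanometres.
#'
#' @param wavelength_nm Numeric vector of wavelengths in nm, strictly
#'   increasing, at least two points.
#' @param value Numeric vector of the same length. Emission intensities must
#'   be non-negative.
#' @param kind One of `"emission"`, `"absorbance"`, `"ellipticity"`.
#' @param label Free-text label carried through reports.
#' @return An object of class `spectrum`.
#' @examples
#' s <- spectrum(c(290, 335, 450), c(0, 100, 0), kind = "emission")
#' peak_intensity(s)
#' @export
spectrum <- function(wavelength_nm, value,
                     kind = c("emission", "absorbance", "ellipticity"),
                     label = "") {
  kind <- match.arg(kind)
  wavelength_nm <- as.numeric(wavelength_nm)
  value <- as.numeric(value)
  if (length(wavelength_nm) != length(value)) {
    stop("wavelength and value vectors must have equal length", call. = FALSE)
  }
  if (is.unsorted(wavelength_nm, strictly = FALSE)) {
    warning("wavelengths not monotone increasing; sorting", call. = FALSE)
    ord <- order(wavelength_nm)
    wavelength_nm <- wavelength_nm[ord]
    value <- value[ord]
  }
  out <- structure(
    list(wavelength_nm = wavelength_nm, value = value,
         kind = kind, label = as.character(label)[1]),
    class = "spectrum"
  )
  validate_spectrum(out)
}

validate_spectrum <- function(x) {
  stopifnot(inherits(x, "spectrum"))
  if (length(x$wavelength_nm) < 2L) {
    stop("a spectrum needs at least 2 points", call. = FALSE)
  }
  if (anyNA(x$wavelength_nm) || anyNA(x$value)) {
    stop("spectrum contains missing values", call. = FALSE)
  }
  if (any(diff(x$wavelength_nm) == 0)) {
    stop("duplicate wavelength in spectrum", call. = FALSE)
  }
  if (any(diff(x$wavelength_nm) < 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (x$kind == "emission" && any(x$value < 0)) {
    stop("emission intensities must be non-negative", call. = FALSE)
  }
  x
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s%s>  %d points, %.1f-%.1f nm\n",
              x$kind,
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$wavelength_nm),
              min(x$wavelength_nm), max(x$wavelength_nm)))
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelength_nm, value = x$value)
}

#' Interpolate a spectrum value at a wavelength
#'
#' Linear interpolation on the stored grid; no extrapolation.
#'
#' @param x A [spectrum()].
#' @param wavelength_nm Wavelength (nm) inside the grid range.
#' @return Interpolated value.
#' @export
spectrum_value_at <- function(x, wavelength_nm) {
  validate_spectrum(x)
  rng <- range(x$wavelength_nm)
  if (wavelength_nm < rng[1] || wavelength_nm > rng[2]) {
    stop(sprintf("wavelength %.6g nm outside spectrum range [%.6g, %.6g]",
                 wavelength_nm, rng[1], rng[2]), call. = FALSE)
  }
  stats::approx(x$wavelength_nm, x$value, xout = wavelength_nm)$y
}

#' Read a two-column spectrum file
#'
#' Reads plain delimited text (comma or tab, auto-detected) with columns
#' wavelength (nm) and value; an optional single header line is skipped.
#' Non-monotone rows are sorted with a warning; duplicated wavelengths are an
#' error.
#'
#' @param path File path.
#' @param kind Spectrum kind; see [spectrum()].
#' @param label Label; defaults to the file name.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path, kind = c("emission", "absorbance", "ellipticity"),
                          label = basename(path)) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  header <- is.na(suppressWarnings(as.numeric(strsplit(first, sep)[[1]][1])))
  tab <- utils::read.table(path, sep = sep, header = header,
                           strip.white = TRUE, blank.lines.skip = TRUE)
  if (ncol(tab) < 2L) stop("expected two columns in ", path, call. = FALSE)
  wl <- suppressWarnings(as.numeric(tab[[1]]))
  val <- suppressWarnings(as.numeric(tab[[2]]))
  keep <- !is.na(wl) & !is.na(val)
  if (any(!keep)) {
    stop(sprintf("non-numeric rows in %s (%d bad rows)", path, sum(!keep)),
         call. = FALSE)
  }
  if (sum(keep) < 2L) stop("fewer than 2 usable rows in ", path, call. = FALSE)
  if (anyDuplicated(wl)) stop("duplicate wavelength in ", path, call. = FALSE)
  spectrum(wl, val, kind = kind, label = label)
}

#' Write a spectrum to delimited text
#'
#' Writes `wavelength_nm,value` with full double precision so that a
#' write/read round trip is exact.
#'
#' @param x A [spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path) {
  validate_spectrum(x)
  lines <- c("wavelength_nm,value",
             paste(format_full(x$wavelength_nm), format_full(x$value), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

# full round-trip precision for doubles
format_full <- function(x) formatC(x, digits = 17, format = "g")

#' Construct a titration point
#'
#' One measurement in a quencher titration: the quencher concentration, the
#' emission spectrum recorded at that concentration, and (optionally) the
#' absorbances at the excitation and emission wavelengths used for
#' inner-filter correction.
#'
#' @param quencher_conc_M Quencher (ligand) concentration in mol/L, >= 0.
#' @param spectrum An emission [spectrum()].
#' @param a_ex,a_em Optional absorbances (>= 0) at the excitation and emission
#'   wavelengths.
#' @return An object of class `titration_point`.
#' @export
titration_point <- function(quencher_conc_M, spectrum, a_ex = NA_real_,
                            a_em = NA_real_) {
  if (!inherits(spectrum, "spectrum") || spectrum$kind != "emission") {
    stop("spectrum must be an emission spectrum", call. = FALSE)
  }
  if (quencher_conc_M < 0) stop("quencher concentration must be >= 0", call. = FALSE)
  if (!is.na(a_ex) && a_ex < 0) stop("a_ex must be >= 0", call. = FALSE)
  if (!is.na(a_em) && a_em < 0) stop("a_em must be >= 0", call. = FALSE)
  structure(
    list(quencher_conc_M = as.numeric(quencher_conc_M), spectrum = spectrum,
         a_ex = as.numeric(a_ex), a_em = as.numeric(a_em)),
    class = "titration_point"
  )
}

#' Construct a titration series
#'
#' An ordered set of titration points at one temperature. Exactly one point
#' must be at zero quencher concentration (the unquenched reference F_o), and
#' all spectra must share one wavelength grid.
#'
#' @param points List of [titration_point()] objects; sorted by concentration
#'   on construction.
#' @param temperature_K Temperature in kelvin.
#' @param excitation_nm Excitation wavelength in nm.
#' @param protein_conc_M Protein concentration in mol/L.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(points, temperature_K, excitation_nm,
                             protein_conc_M) {
  if (!is.list(points) || !all(vapply(points, inherits, logical(1),
                                      "titration_point"))) {
    stop("points must be a list of titration_point objects", call. = FALSE)
  }
  concs <- vapply(points, `[[`, numeric(1), "quencher_conc_M")
  points <- points[order(concs)]
  out <- structure(
    list(points = points, temperature_K = as.numeric(temperature_K),
         excitation_nm = as.numeric(excitation_nm),
         protein_conc_M = as.numeric(protein_conc_M)),
    class = "titration_series"
  )
  validate_titration_series(out)
}

validate_titration_series <- function(x, point_names = NULL) {
  concs <- titration_concs(x)
  if (length(unique(concs)) < 3L) {
    stop("a titration series needs at least 3 distinct concentrations",
         call. = FALSE)
  }
  if (sum(concs == 0) != 1L) {
    stop("exactly one point must have zero quencher concentration (the F_o reference)",
         call. = FALSE)
  }
  if (x$temperature_K <= 0) stop("temperature must be positive kelvin", call. = FALSE)
  grid0 <- x$points[[1]]$spectrum$wavelength_nm
  for (i in seq_along(x$points)) {
    gi <- x$points[[i]]$spectrum$wavelength_nm
    if (length(gi) != length(grid0) || any(gi != grid0)) {
      nm <- if (!is.null(point_names)) point_names[i] else
        x$points[[i]]$spectrum$label
      stop(sprintf("wavelength grid of point %d (%s) differs from the series grid",
                   i, nm), call. = FALSE)
    }
  }
  x
}

titration_concs <- function(series) {
  vapply(series$points, `[[`, numeric(1), "quencher_conc_M")
}

#' @export
print.titration_series <- function(x, ...) {
  concs <- titration_concs(x)
  cat(sprintf("<titration_series>  %d points, [Q] %.3g-%.3g M, T = %.1f K, ex %.0f nm\n",
              length(concs), min(concs), max(concs), x$temperature_K,
              x$excitation_nm))
  invisible(x)
}

#' Read a titration series from a manifest
#'
#' The manifest is a YAML file with keys `temperature_K`, `excitation_nm`,
#' `protein_conc_M`, optional `concentration_unit` (`"M"` or `"uM"`), and
#' `points`, a list of `{conc, file, a_ex, a_em}` entries. Spectrum file paths
#' are resolved relative to the manifest location. If `path` is a directory,
#' `manifest.yaml` (or `.yml`) inside it is read.
#'
#' @param path Manifest file or directory containing one.
#' @return A [titration_series()].
#' @export
read_titration <- function(path) {
  if (dir.exists(path)) {
    cand <- file.path(path, c("manifest.yaml", "manifest.yml"))
    cand <- cand[file.exists(cand)]
    if (!length(cand)) stop("no manifest.yaml in directory ", path, call. = FALSE)
    path <- cand[1]
  }
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  man <- yaml::read_yaml(path)
  need <- c("temperature_K", "excitation_nm", "protein_conc_M", "points")
  miss <- setdiff(need, names(man))
  if (length(miss)) {
    stop("manifest missing keys: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  unit <- man$concentration_unit %||% "M"
  scale <- switch(unit, M = 1, uM = 1e-6, "µM" = 1e-6,
                  stop("unknown concentration_unit: ", unit, call. = FALSE))
  base <- dirname(path)
  files <- character(length(man$points))
  pts <- vector("list", length(man$points))
  for (i in seq_along(man$points)) {
    p <- man$points[[i]]
    f <- p$file
    fp <- if (file.exists(f)) f else file.path(base, f)
    files[i] <- f
    sp <- read_spectrum(fp, kind = "emission", label = f)
    pts[[i]] <- titration_point(
      quencher_conc_M = as.numeric(p$conc) * scale,
      spectrum = sp,
      a_ex = as.numeric(p$a_ex %||% NA_real_),
      a_em = as.numeric(p$a_em %||% NA_real_)
    )
  }
  ord <- order(vapply(pts, `[[`, numeric(1), "quencher_conc_M"))
  out <- structure(
    list(points = pts[ord],
         temperature_K = as.numeric(man$temperature_K),
         excitation_nm = as.numeric(man$excitation_nm),
         protein_conc_M = as.numeric(man$protein_conc_M) *
           if (!is.null(man$protein_conc_unit) && man$protein_conc_unit %in%
               c("uM", "µM")) 1e-6 else 1),
    class = "titration_series"
  )
  validate_titration_series(out, point_names = files[ord])
}

#' Write a titration series as manifest plus spectrum files
#'
#' Inverse of [read_titration()]: writes each point's spectrum as a delimited
#' file and a `manifest.yaml` referring to them, all inside `dir`.
#'
#' @param series A [titration_series()].
#' @param dir Output directory; created if needed.
#' @return The manifest path, invisibly.
#' @export
write_titration <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pts <- list()
  for (i in seq_along(series$points)) {
    p <- series$points[[i]]
    f <- sprintf("point_%02d.csv", i)
    write_spectrum(p$spectrum, file.path(dir, f))
    entry <- list(conc = p$quencher_conc_M, file = f)
    if (!is.na(p$a_ex)) entry$a_ex <- p$a_ex
    if (!is.na(p$a_em)) entry$a_em <- p$a_em
    pts[[i]] <- entry
  }
  man <- list(temperature_K = series$temperature_K,
              excitation_nm = series$excitation_nm,
              protein_conc_M = series$protein_conc_M,
              concentration_unit = "M",
              points = pts)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(man, path, precision = 17)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
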