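#' Spectrum objects
#'
#' A `spectrum` is the universal currency of the package: a strictly
#' increasing wavelength grid (nm) with one value per wavelength and a unit
#' tag. Irradiance is in mW m-2 nm-1, radiance in mW m-2 nm-1 sr-1;
#' reflectance and transmittance are dimensionless and constrained to
#' [0, 1 + 1e-9].
#'
#' @param wavelengths_nm strictly increasing numeric vector of wavelengths
#'   in nanometres.
#' @param values numeric vector of the same length; must be finite.
#' @param unit one of `"irradiance"`, `"radiance"`, `"reflectance"`,
#'   `"transmittance"`, `"dimensionless"`.
#' @return An object of class `spectrum`: a list with elements
#'   `wavelengths_nm`, `values`, `unit`.
#' @examples
#' s <- spectrum(seq(650, 815, by = 1), rep(0.2, 166), "reflectance")
#' spectrum_value(s, 719)
#' @export
spectrum <- function(wavelengths_nm, values, unit = "dimensionless") {
  unit <- match.arg(unit, c("irradiance", "radiance", "reflectance",
                            "transmittance", "dimensionless"))
  wavelengths_nm <- as.numeric(wavelengths_nm)
  values <- as.numeric(values)
  if (length(wavelengths_nm) != length(values))
    stop("wavelengths and values must have the same length")
  if (length(wavelengths_nm) < 1L)
    stop("empty spectrum")
  if (any(diff(wavelengths_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  if (!all(is.finite(values)))
    stop("spectrum values must be finite")
  if (unit %in% c("reflectance", "transmittance")) {
    if (any(values < 0) || any(values > 1 + 1e-9))
      stop(unit, " values must lie in [0, 1]")
  }
  structure(list(wavelengths_nm = wavelengths_nm, values = values,
                 unit = unit),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  rng <- range(x$wavelengths_nm)
  cat(sprintf("<spectrum> %s, %d samples, %.3f-%.3f nm\n",
              x$unit, length(x$values), rng[1], rng[2]))
  invisible(x)
}

#' @rdname spectrum
#' @param x object to test.
#' @export
is_spectrum <- function(x) inherits(x, "spectrum")

#' Index of the grid sample nearest a nominal wavelength
#'
#' Ties (a nominal wavelength exactly between two samples) are broken toward
#' the shorter wavelength.
#'
#' @param s a [spectrum()].
#' @param wavelength_nm nominal wavelength (nm); may be a vector.
#' @return integer vector of indices into the spectrum grid.
#' @export
nearest_index <- function(s, wavelength_nm) {
  stopifnot(is_spectrum(s))
  vapply(wavelength_nm, function(w) {
    if (w < s$wavelengths_nm[1] || w > s$wavelengths_nm[length(s$wavelengths_nm)])
      stop(sprintf("wavelength %.3f nm outside spectral coverage [%.3f, %.3f]",
                   w, s$wavelengths_nm[1],
                   s$wavelengths_nm[length(s$wavelengths_nm)]))
    d <- abs(s$wavelengths_nm - w)
    # which.min returns the first minimum, i.e. the shorter wavelength on ties
    which.min(d)
  }, integer(1))
}

#' Value of a spectrum at the nearest grid sample
#'
#' @inheritParams nearest_index
#' @return numeric vector of values at the nearest samples.
#' @export
spectrum_value <- function(s, wavelength_nm) {
  s$values[nearest_index(s, wavelength_nm)]
}

#' Restrict a spectrum to a wavelength interval
#'
#' @param s a [spectrum()].
#' @param lo,hi interval bounds in nm (inclusive).
#' @return a [spectrum()] covering only `[lo, hi]`.
#' @export
spectrum_window <- function(s, lo, hi) {
  stopifnot(is_spectrum(s), lo < hi)
  keep <- s$wavelengths_nm >= lo & s$wavelengths_nm <= hi
  if (!any(keep))
    stop(sprintf("no samples in [%.2f, %.2f] nm", lo, hi))
  spectrum(s$wavelengths_nm[keep], s$values[keep], s$unit)
}

# internal: check two spectra share one grid
same_grid <- function(a, b, tol = 1e-9) {
  length(a$wavelengths_nm) == length(b$wavelengths_nm) &&
    max(abs(a$wavelengths_nm - b$wavelengths_nm)) <= tol
}
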