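#' Instrument configuration
#'
#' Spectral resolution (FWHM of the Gaussian instrument line shape),
#' sampling interval, and signal-to-noise ratio of a field spectrometer.
#' SNR is interpreted as the wavelength-local signal-to-sigma of additive
#' Gaussian noise.
#'
#' @param sr_fwhm_nm spectral resolution (FWHM, nm), > 0.
#' @param sampling_interval_nm sample spacing (nm); defaults to half the
#'   FWHM and must not exceed it.
#' @param snr signal-to-noise ratio (> 0), or `Inf` for noise-free.
#' @return object of class `instrument_config`.
#' @export
instrument_config <- function(sr_fwhm_nm,
                              sampling_interval_nm = sr_fwhm_nm / 2,
                              snr = Inf) {
  stopifnot(sr_fwhm_nm > 0, sampling_interval_nm > 0, snr > 0)
  if (sampling_interval_nm > sr_fwhm_nm)
    stop("sampling interval must not exceed the FWHM")
  structure(list(sr_fwhm_nm = sr_fwhm_nm,
                 sampling_interval_nm = sampling_interval_nm,
                 snr = snr),
            class = "instrument_config")
}

#' Spectrometer presets
#'
#' `qe_pro()` is a 0.31 nm FWHM / 0.155 nm sampling / SNR 1000
#' high-resolution spectrometer; `asd_fieldspec()` is a 3 nm / 1.5 nm /
#' SNR 4000 field spectroradiometer.
#'
#' @return an [instrument_config()].
#' @export
qe_pro <- function() instrument_config(0.31, 0.155, 1000)

#' @rdname qe_pro
#' @export
asd_fieldspec <- function() instrument_config(3.0, 1.5, 4000)

# internal: discrete Gaussian instrument line shape on the native grid
# spacing, truncated at +/- 4 sigma and renormalized to unit sum.
ils_kernel <- function(fwhm_nm, step_nm) {
  sigma <- fwhm_nm / (2 * sqrt(2 * log(2)))
  half <- ceiling(4 * sigma / step_nm)
  x <- (-half:half) * step_nm
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Convolve a spectrum with the instrument line shape and resample
#'
#' Convolution with a unit-area Gaussian of FWHM `cfg$sr_fwhm_nm`
#' (truncated at +/- 4 sigma), evaluated at output centers spaced
#' `cfg$sampling_interval_nm`. A flat input maps to the same flat value.
#' Output centers are snapped to input grid points and restricted to the
#' region where the full kernel fits (no edge extrapolation).
#'
#' @param s input [spectrum()] on a uniform fine grid; the grid spacing
#'   must be at most `sr_fwhm_nm / 10`.
#' @param cfg an [instrument_config()].
#' @return the degraded, resampled [spectrum()].
#' @export
convolve_resample <- function(s, cfg) {
  stopifnot(is_spectrum(s), inherits(cfg, "instrument_config"))
  wl <- s$wavelengths_nm
  step <- diff(wl)
  if (max(step) - min(step) > 1e-9)
    stop("convolve_resample requires a uniform input grid")
  step <- step[1]
  if (step > cfg$sr_fwhm_nm / 10)
    stop(sprintf("input grid spacing %.4f nm too coarse for FWHM %.3f nm",
                 step, cfg$sr_fwhm_nm))
  k <- ils_kernel(cfg$sr_fwhm_nm, step)
  half <- (length(k) - 1L) %/% 2L
  n <- length(wl)
  if (n <= length(k)) stop("spectrum shorter than the instrument kernel")
  # 'filter'-type convolution (valid region only), computed via FFT
  sm <- stats::convolve(s$values, k, type = "filter")
  wl_valid <- wl[(half + 1L):(n - half)]
  stride <- cfg$sampling_interval_nm / step
  if (abs(stride - round(stride)) > 1e-6) {
    # sampling interval not a grid multiple: take nearest valid grid points
    centers <- seq(wl_valid[1], wl_valid[length(wl_valid)],
                   by = cfg$sampling_interval_nm)
    idx <- round((centers - wl_valid[1]) / step) + 1L
  } else {
    idx <- seq(1L, length(wl_valid), by = round(stride))
  }
  spectrum(wl_valid[idx], sm[idx], s$unit)
}

#' Add channel noise at a given signal-to-noise ratio
#'
#' Adds zero-mean Gaussian noise per channel with standard deviation
#' `|value| / snr`. With `snr = Inf` the spectrum is returned unchanged.
#' Draws come from the R random number stream; pass `seed` for a
#' reproducible draw that leaves the global stream untouched.
#'
#' @param s a [spectrum()].
#' @param cfg an [instrument_config()] carrying `snr`.
#' @param seed optional integer seed for this draw only.
#' @return a noisy [spectrum()].
#' @export
add_noise <- function(s, cfg, seed = NULL) {
  stopifnot(is_spectrum(s), inherits(cfg, "instrument_config"))
  if (!is.finite(cfg$snr)) return(s)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  noisy <- s$values + stats::rnorm(length(s$values),
                                   sd = abs(s$values) / cfg$snr)
  out <- s
  out$values <- noisy
  out
}
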