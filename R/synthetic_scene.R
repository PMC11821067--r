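#' Default look-up-table parameter grids
#'
#' The default canopy/leaf grids used by the scene generator: chlorophyll
#' content Cab (ug cm-2) in {20, 40, 60}, dry-matter content Cdm in
#' {2, 10, 20}, leaf water Cw (1e-3 cm) in {5, 10, 20}, leaf structure N in
#' {1, 2}, leaf area index LAI in {1, 3, 5}, and fluorescence quantum yield
#' Fqe in {0.01, 0.02}: 324 combinations in total. The atmosphere side of
#' the table uses water-vapor columns 1-5 g cm-2 with a solar zenith angle
#' of 30 degrees and nadir view.
#'
#' @return named list of numeric parameter grids.
#' @export
lut_default_grids <- function() {
  list(cab_ug_cm2 = c(20, 40, 60),
       cdm_g_cm2  = c(2, 10, 20),
       cw_1e3cm   = c(5, 10, 20),
       n_struct   = c(1, 2),
       lai        = c(1, 3, 5),
       fqe        = c(0.01, 0.02))
}

#' Enumerate scene parameter combinations
#'
#' Builds the Cartesian product of the supplied parameter grids in row-major
#' order over the listed grids (the last grid varies fastest), optionally
#' crossed with a set of water-vapor column concentrations.
#'
#' @param grids named list of non-empty numeric vectors, as from
#'   [lut_default_grids()].
#' @param wvc_g_cm2 optional vector of water-vapor columns (g cm-2) to cross
#'   with the canopy grids; `NULL` keeps a single-column `wvc` of the
#'   default 3 g cm-2 midrange value.
#' @param sza_deg solar zenith angle (degrees). Default 30.
#' @param vza_deg view zenith angle (degrees). Default 0 (nadir).
#' @return data frame with one row per scene (`scene_id`, the six canopy
#'   parameters, `wvc_g_cm2`, `sza_deg`, `vza_deg`).
#' @examples
#' nrow(generate_lut())  # 324
#' @export
generate_lut <- function(grids = lut_default_grids(), wvc_g_cm2 = NULL,
                         sza_deg = 30, vza_deg = 0) {
  if (!length(grids) || any(!vapply(grids, length, 1L)))
    stop("every parameter grid must be non-empty")
  req <- c("cab_ug_cm2", "cdm_g_cm2", "cw_1e3cm", "n_struct", "lai", "fqe")
  if (!all(req %in% names(grids)))
    stop("grids must name: ", paste(req, collapse = ", "))
  # row-major over the listing order: the last listed grid varies fastest
  lut <- rev(expand.grid(rev(grids[req]), KEEP.OUT.ATTRS = FALSE))
  if (!is.null(wvc_g_cm2)) {
    if (!length(wvc_g_cm2)) stop("every parameter grid must be non-empty")
    lut <- lut[rep(seq_len(nrow(lut)), each = length(wvc_g_cm2)), , drop = FALSE]
    lut$wvc_g_cm2 <- rep(wvc_g_cm2, length.out = nrow(lut))
  } else {
    lut$wvc_g_cm2 <- 3
  }
  lut$sza_deg <- sza_deg
  lut$vza_deg <- vza_deg
  rownames(lut) <- NULL
  cbind(scene_id = seq_len(nrow(lut)), lut)
}

#' Native simulation wavelength grid
#'
#' Fine grid on which scenes are generated before instrument degradation:
#' 0.005 nm spacing so that convolution to a 0.3 nm instrument line shape is
#' well resolved.
#'
#' @param lo,hi grid limits in nm.
#' @param step grid spacing in nm.
#' @return numeric vector of wavelengths.
#' @export
native_grid <- function(lo = 650, hi = 815, step = 0.005) {
  seq(lo, hi, by = step)
}

# ---------------------------------------------------------------------------
# Atmosphere: parametric absorption-line emulator
#
# Transmittance is Beer-Lambert over a small list of Gaussian optical-depth
# lines per band: T(lambda) = exp(-u * k(lambda)) with u the water-vapor
# column (g cm-2) for the H2O multiplet and u = 1 (fixed column) for the two
# oxygen bands. The line lists are package constants; they emulate the
# spectral morphology of a line-by-line radiative transfer run (positions,
# relative depths, band widths), not its physics.
# ---------------------------------------------------------------------------

.h2o_lines <- data.frame(
  center = c(716.6, 717.5, 718.35, 718.9, 719.45, 719.9, 721.1, 722.4,
             723.5, 725.0, 726.8, 728.5, 730.5),
  sigma  = c(0.22,  0.20,  0.12,   0.28,  0.12,   0.22,  0.25,  0.30,
             1.00,  1.80,  1.20,   1.50,  1.20),
  od     = c(0.12,  0.18,  0.08,   0.55,  0.06,   0.20,  0.12,  0.08,
             0.05,  0.06,  0.05,   0.05,  0.03))

.o2b_lines <- data.frame(
  center = c(687.0, 688.3),
  sigma  = c(0.30, 0.25),
  od     = c(0.22, 0.10))

.o2a_lines <- data.frame(
  center = c(759.8, 760.6, 761.7, 762.8),
  sigma  = c(0.40, 0.45, 0.50, 0.60),
  od     = c(1.60, 3.00, 1.30, 0.50))

#' Atmosphere specification
#'
#' Bundles the package's absorption-line tables with a water-vapor column.
#' H2O line strengths scale with `wvc_g_cm2`; the O2-B (~687 nm) and O2-A
#' (~760 nm) lines use a fixed unit column, so their depths are independent
#' of water vapor.
#'
#' @param wvc_g_cm2 water-vapor column concentration in g cm-2. Valid range
#'   0.5-6 (the emulator's calibration range); exactly 0 is also accepted as
#'   the no-absorption reference.
#' @return object of class `atmosphere_spec`.
#' @export
atmosphere_spec <- function(wvc_g_cm2 = 3) {
  if (!(identical(wvc_g_cm2, 0) || wvc_g_cm2 == 0 ||
        (wvc_g_cm2 >= 0.5 && wvc_g_cm2 <= 6)))
    stop("wvc_g_cm2 must be 0 or within [0.5, 6] g cm-2")
  structure(list(wvc_g_cm2 = wvc_g_cm2,
                 h2o = .h2o_lines, o2b = .o2b_lines, o2a = .o2a_lines),
            class = "atmosphere_spec")
}

# internal: optical depth of a Gaussian line list at unit column
line_optical_depth <- function(wl, lines) {
  k <- numeric(length(wl))
  for (i in seq_len(nrow(lines))) {
    k <- k + lines$od[i] * exp(-(wl - lines$center[i])^2 / (2 * lines$sigma[i]^2))
  }
  k
}

#' Atmospheric transmittance on a wavelength grid
#'
#' @param atm an [atmosphere_spec()].
#' @param grid numeric wavelength grid (nm).
#' @return a transmittance [spectrum()].
#' @export
transmittance <- function(atm, grid) {
  stopifnot(inherits(atm, "atmosphere_spec"))
  k <- atm$wvc_g_cm2 * line_optical_depth(grid, atm$h2o) +
    line_optical_depth(grid, atm$o2b) +
    line_optical_depth(grid, atm$o2a)
  spectrum(grid, exp(-k), "transmittance")
}

# internal: smooth solar continuum envelope, mW m-2 nm-1 before the
# cos(SZA) factor. A Planck envelope at 5800 K scaled so that the
# zenith-normalized continuum at 780 nm is 1300 mW m-2 nm-1, placing
# clear-sky E(780)/cos(SZA) well above the 930 sunny/cloudy threshold.
solar_continuum <- function(wl, scale_780 = 1300) {
  planck <- function(l_nm) {
    l <- l_nm * 1e-9
    1 / (l^5 * (exp(0.0143877688 / (l * 5800)) - 1))
  }
  scale_780 * planck(wl) / planck(780)
}

#' Downwelling solar irradiance
#'
#' Composes the smooth solar continuum, the band transmittances of the
#' atmosphere, and the solar-zenith cosine:
#' `E = continuum(lambda) * T(lambda) * cos(sza)`. At every H2O line center
#' the irradiance strictly decreases as the water-vapor column increases,
#' while the O2 line depths are unaffected.
#'
#' @param atm an [atmosphere_spec()].
#' @param grid wavelength grid (nm); for end-to-end use this should be the
#'   fine [native_grid()] (spacing <= 0.01 nm) so instrument convolution is
#'   well resolved.
#' @param sza_deg solar zenith angle in degrees, < 90.
#' @return an irradiance [spectrum()] (mW m-2 nm-1).
#' @export
solar_irradiance <- function(atm, grid, sza_deg = 30) {
  stopifnot(inherits(atm, "atmosphere_spec"))
  if (sza_deg >= 90) stop("sun below horizon: sza_deg must be < 90")
  tr <- transmittance(atm, grid)
  e <- solar_continuum(grid) * tr$values * cos(sza_deg * pi / 180)
  spectrum(grid, e, "irradiance")
}

# ---------------------------------------------------------------------------
# Canopy emulator: red-edge reflectance and two-peak fluorescence emission.
# Only the monotone responses and value ranges are contractual; the
# functional forms are package conventions standing in for a full canopy
# radiative transfer simulation.
# ---------------------------------------------------------------------------

#' Normalized fluorescence emission shape
#'
#' Two-Gaussian red/far-red emission emulator with peaks near 685 and
#' 740 nm. `peak_ratio` is the red:far-red amplitude ratio. The shape is
#' normalized to a maximum of 1; its 719/760.6 nm value ratio is about 1.26,
#' matching the spectral slope of canopy fluorescence between the two
#' retrieval bands.
#'
#' @param wl wavelength vector (nm).
#' @param peak_ratio red:far-red peak amplitude ratio.
#' @return numeric vector, max 1.
#' @export
sif_shape <- function(wl, peak_ratio = 0.8) {
  raw <- function(l) {
    peak_ratio * exp(-(l - 685)^2 / (2 * 10^2)) +
      exp(-(l - 738.3)^2 / (2 * 16.3^2))
  }
  peak_wl <- seq(650, 780, by = 0.1)
  raw(wl) / max(raw(peak_wl))
}

#' Canopy reflectance and fluorescence for one scene
#'
#' Emulates a canopy radiative-transfer output: reflectance is a red-edge
#' sigmoid (a double-logistic mixture) between a red minimum (deepening
#' with Cab) and a NIR plateau
#' (rising with LAI, modulated weakly by N, Cw and Cdm); fluorescence is the
#' two-Gaussian [sif_shape()] scaled by Fqe and a saturating function of LAI
#' and Cab. Both are smooth (no absorption lines). Far-red fluorescence peak
#' magnitudes span roughly 0.3-2.5 mW m-2 nm-1 sr-1 over the default grids.
#'
#' @param scene one-row data frame (or list) with the [generate_lut()]
#'   canopy fields.
#' @param grid wavelength grid (nm); must cover 650-815 nm.
#' @return list with elements `R` (reflectance [spectrum()]) and `SIF`
#'   (radiance [spectrum()]).
#' @export
canopy_spectra <- function(scene, grid = native_grid()) {
  if (min(grid) > 650 || max(grid) < 815)
    stop("grid must cover 650-815 nm")
  cab <- scene$cab_ug_cm2; cdm <- scene$cdm_g_cm2; cw <- scene$cw_1e3cm
  nst <- scene$n_struct; lai <- scene$lai; fqe <- scene$fqe
  # red minimum deepens with chlorophyll; NIR plateau rises with LAI
  r_red <- 0.025 + 0.085 * exp(-cab / 35)
  r_nir <- 0.30 + 0.13 * tanh(lai / 2.2) + 0.012 * (nst - 1) -
    0.02 * (1 - exp(-cw / 15)) + 0.006 * log1p(cdm / 10)
  # compound (double-logistic) red edge: a steep chlorophyll edge and a
  # softer upper shoulder whose weight shifts with leaf water
  w2 <- 0.40 + 0.10 * cw / 20
  mix <- (1 - w2) / (1 + exp(-(grid - 708) / 7.5)) +
    w2 / (1 + exp(-(grid - 722) / 10))
  r <- r_red + (r_nir - r_red) * mix
  # emission amplitude: linear in Fqe, saturating in LAI and Cab
  amp <- 260 * fqe * (1 - exp(-0.7 * lai)) * cab / (cab + 40)
  list(R = spectrum(grid, r, "reflectance"),
       SIF = spectrum(grid, amp * sif_shape(grid), "radiance"))
}

#' At-sensor upwelling radiance (forward model)
#'
#' `L(lambda) = E(lambda) / pi * R(lambda) + SIF(lambda)`: reflected
#' sunlight under a Lambertian surface plus the additive fluorescence
#' emission.
#'
#' @param E downwelling irradiance [spectrum()].
#' @param R reflectance [spectrum()] on the same grid.
#' @param SIF fluorescence radiance [spectrum()] on the same grid.
#' @return a radiance [spectrum()].
#' @export
forward_radiance <- function(E, R, SIF) {
  stopifnot(is_spectrum(E), is_spectrum(R), is_spectrum(SIF))
  if (!same_grid(E, R) || !same_grid(E, SIF))
    stop("E, R and SIF must share one wavelength grid")
  if (E$unit != "irradiance" || R$unit != "reflectance" ||
      SIF$unit != "radiance")
    stop("unit mismatch: expected irradiance, reflectance, radiance")
  spectrum(E$wavelengths_nm, E$values / pi * R$values + SIF$values,
           "radiance")
}
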