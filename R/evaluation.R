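#' Root mean square error
#'
#' @param truth,est numeric vectors of equal nonzero length.
#' @return `sqrt(mean((truth - est)^2))`.
#' @export
rmse <- function(truth, est) {
  if (length(truth) != length(est)) stop("length mismatch")
  if (!length(truth)) stop("empty input")
  sqrt(mean((truth - est)^2))
}

#' Relative root mean square error (percent)
#'
#' RMSE divided by the mean of the reference values, times 100.
#'
#' @inheritParams rmse
#' @return RRMSE in percent.
#' @export
rrmse <- function(truth, est) {
  m <- mean(truth)
  if (abs(m) < .Machine$double.eps) stop("zero-mean truth: RRMSE undefined")
  rmse(truth, est) / m * 100
}

#' Agreement metrics of estimates against truth
#'
#' Ordinary least squares of `est` on `truth` (with intercept); returns the
#' regression slope and the squared Pearson correlation (identical to the
#' regression R-squared for OLS with intercept).
#'
#' @inheritParams rmse
#' @return list with `r2` and `slope`.
#' @export
regression_metrics <- function(truth, est) {
  if (length(truth) != length(est)) stop("length mismatch")
  if (length(truth) < 3) stop("need at least 3 points")
  if (stats::var(truth) < .Machine$double.eps)
    stop("zero variance in truth: slope undefined")
  slope <- stats::cov(truth, est) / stats::var(truth)
  list(r2 = stats::cor(truth, est)^2, slope = slope)
}

# ---------------------------------------------------------------------------
# Experiment harness
# ---------------------------------------------------------------------------

#' Condition design helper
#'
#' Builds a condition grid for [run_experiment()]: every combination of the
#' supplied bands, spectral resolutions, SNRs and water-vapor columns.
#'
#' @param band character vector of bands.
#' @param sr_fwhm_nm numeric vector of spectral resolutions (nm).
#' @param snr numeric vector of signal-to-noise ratios (`Inf` = noise-free).
#' @param wvc_g_cm2 numeric vector of water-vapor columns (g cm-2).
#' @return data frame of conditions.
#' @export
experiment_design <- function(band = "h2o", sr_fwhm_nm = 0.3, snr = Inf,
                              wvc_g_cm2 = 3) {
  expand.grid(band = band, sr_fwhm_nm = sr_fwhm_nm, snr = snr,
              wvc_g_cm2 = wvc_g_cm2, KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE)
}

#' Run a retrieval accuracy experiment over a scene set
#'
#' For every condition (band, spectral resolution, SNR, water-vapor
#' column): simulate each scene's reflectance and fluorescence, compose
#' at-sensor radiance, degrade both channels to the instrument
#' configuration, apply all seven retrieval algorithms, and score the
#' estimates against the true (instrument-degraded) fluorescence at the
#' band's absorption wavelength. The SVD training set per condition and
#' replicate is the set of (noisy) downwelling spectra of all scenes; the
#' pFLD basis for each scene is trained on the other scenes' reflectances
#' (leave-one-out).
#'
#' @param design condition data frame from [experiment_design()].
#' @param scenes scene table from [generate_lut()] (its `wvc_g_cm2` column
#'   is overridden by the condition).
#' @param seed integer seed controlling every noise draw.
#' @param replicates independent noise replicates per condition (ignored
#'   for noise-free conditions).
#' @param keep_estimates return per-scene estimates alongside the summary.
#' @return data frame with one row per algorithm x condition: `band`,
#'   `sr_fwhm_nm`, `snr`, `wvc_g_cm2`, `algorithm`, `rmse`,
#'   `rrmse_percent`, `r2`, `slope`, `n_scenes`, `n_excluded`. When
#'   `keep_estimates` is TRUE, the per-scene table is attached as attribute
#'   `"estimates"`.
#' @export
run_experiment <- function(design, scenes = generate_lut(), seed = 1,
                           replicates = 1, keep_estimates = FALSE) {
  stopifnot(nrow(design) >= 1, nrow(scenes) >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  grid <- native_grid()
  canopy <- lapply(seq_len(nrow(scenes)),
                   function(i) canopy_spectra(scenes[i, ], grid))
  cache <- new.env(parent = emptyenv())
  summaries <- list()
  estimates <- list()
  for (ci in seq_len(nrow(design))) {
    cond <- design[ci, ]
    cfg <- instrument_config(cond$sr_fwhm_nm, cond$sr_fwhm_nm / 2, cond$snr)
    prep <- condition_prep(cond, scenes, canopy, grid, cache)
    wins <- default_windows(cond$band, cond$sr_fwhm_nm)
    nrep <- if (is.finite(cond$snr)) replicates else 1L
    est_tab <- run_condition(prep, wins, cfg, nrep)
    est_tab$band <- cond$band
    est_tab$sr_fwhm_nm <- cond$sr_fwhm_nm
    est_tab$snr <- cond$snr
    est_tab$wvc_g_cm2 <- cond$wvc_g_cm2
    estimates[[ci]] <- est_tab
    summaries[[ci]] <- summarize_condition(est_tab)
  }
  out <- do.call(rbind, summaries)
  rownames(out) <- NULL
  if (keep_estimates)
    attr(out, "estimates") <- do.call(rbind, estimates)
  attr(out, "manifest") <- list(seed = seed, replicates = replicates,
                                n_scenes = nrow(scenes),
                                package_version = as.character(utils::packageVersion("sifband")))
  out
}

# internal: noise-free per-condition spectra, cached by (sr) and (sr, wvc)
condition_prep <- function(cond, scenes, canopy, grid, cache) {
  cfg0 <- instrument_config(cond$sr_fwhm_nm, cond$sr_fwhm_nm / 2, Inf)
  key_sr <- sprintf("sr_%g", cond$sr_fwhm_nm)
  if (is.null(cache[[key_sr]])) {
    cache[[key_sr]] <- list(
      SIF = lapply(canopy, function(cs) convolve_resample(cs$SIF, cfg0)),
      R = lapply(canopy, function(cs) convolve_resample(cs$R, cfg0)))
  }
  key_ew <- sprintf("e_%g_%g", cond$sr_fwhm_nm, cond$wvc_g_cm2)
  if (is.null(cache[[key_ew]])) {
    atm <- atmosphere_spec(cond$wvc_g_cm2)
    e_nat <- solar_irradiance(atm, grid, sza_deg = scenes$sza_deg[1])
    cache[[key_ew]] <- list(
      E = convolve_resample(e_nat, cfg0),
      L = lapply(canopy, function(cs) {
        convolve_resample(forward_radiance(e_nat, cs$R, cs$SIF), cfg0)
      }))
  }
  c(cache[[key_sr]], cache[[key_ew]], list(cond = cond))
}

# internal: leave-one-out pFLD bases over the window's shoulder region
loo_bases <- function(R_list, w, sr_fwhm_nm) {
  wl <- R_list[[1]]$wavelengths_nm
  sh <- shoulder_region(wl, w$absorption_nm, sr_fwhm_nm)
  wl_reg <- wl[sh$region]
  M <- vapply(R_list, function(r) r$values[sh$region], numeric(length(wl_reg)))
  lapply(seq_along(R_list), function(i) {
    reflectance_basis(M[, -i, drop = FALSE], wl_reg)
  })
}

# internal: run all algorithms over all scenes/replicates of one condition
run_condition <- function(prep, wins, cfg, nrep) {
  ns <- length(prep$L)
  bases <- loo_bases(prep$R, wins$pfld, cfg$sr_fwhm_nm)
  rows <- vector("list", ns * nrep)
  idx <- 0L
  for (rep_i in seq_len(nrep)) {
    E_noisy <- lapply(seq_len(ns), function(i) add_noise(prep$E, cfg))
    training <- svd_training(E_noisy, wins$svd)
    for (si in seq_len(ns)) {
      Ei <- E_noisy[[si]]
      Li <- add_noise(prep$L[[si]], cfg)
      truth <- spectrum_value(prep$SIF[[si]], wins$sfld$absorption_nm)
      tab <- retrieve_all(Ei, Li, wins, basis = bases[[si]],
                          training = training, sr_fwhm_nm = cfg$sr_fwhm_nm)
      tab$scene <- si
      tab$replicate <- rep_i
      tab$truth <- truth
      idx <- idx + 1L
      rows[[idx]] <- tab
    }
  }
  do.call(rbind, rows)
}

# internal: accuracy metrics per algorithm from a per-scene estimate table
summarize_condition <- function(est_tab) {
  algs <- unique(est_tab$algorithm)
  rows <- lapply(algs, function(a) {
    sub <- est_tab[est_tab$algorithm == a, ]
    ok <- is.finite(sub$sif)
    reg <- if (sum(ok) >= 3 && stats::var(sub$truth[ok]) > .Machine$double.eps) {
      regression_metrics(sub$truth[ok], sub$sif[ok])
    } else list(r2 = NA_real_, slope = NA_real_)
    data.frame(band = sub$band[1], sr_fwhm_nm = sub$sr_fwhm_nm[1],
               snr = sub$snr[1], wvc_g_cm2 = sub$wvc_g_cm2[1],
               algorithm = a,
               rmse = if (any(ok)) rmse(sub$truth[ok], sub$sif[ok]) else NA_real_,
               rrmse_percent = if (any(ok)) rrmse(sub$truth[ok], sub$sif[ok]) else NA_real_,
               r2 = reg$r2, slope = reg$slope,
               n_scenes = sum(ok), n_excluded = sum(!ok),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
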