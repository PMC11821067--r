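# Tower time-series processing: alternating ("sandwich") downwelling /
# upwelling acquisitions -> per-spectrum retrievals -> 30-min and daily
# aggregates, with sunny/cloudy classification and an O2-A-referenced
# cross-band comparison.

#' Build a tower record list
#'
#' A tower series is a list of records, each with a `timestamp` (POSIXct),
#' a `channel` (`"down_irradiance"` or `"up_radiance"`) and a
#' [spectrum()]. `tower_records()` assembles one from parallel vectors;
#' [read_tower_long()] builds one from the documented long-format delimited
#' text layout.
#'
#' @param timestamps POSIXct vector.
#' @param channels character vector of channel tags.
#' @param spectra list of [spectrum()] objects.
#' @return list of records, ordered by timestamp.
#' @export
tower_records <- function(timestamps, channels, spectra) {
  stopifnot(length(timestamps) == length(channels),
            length(channels) == length(spectra))
  channels <- match.arg(channels, c("down_irradiance", "up_radiance"),
                        several.ok = TRUE)
  recs <- lapply(seq_along(timestamps), function(i) {
    list(timestamp = timestamps[i], channel = channels[i],
         spectrum = spectra[[i]])
  })
  recs[order(as.numeric(timestamps))]
}

#' Read a tower series from long-format delimited text
#'
#' Expected columns (renameable through `col_map`): `timestamp`, `channel`,
#' `wavelength_nm`, `value`. Channel labels are mapped through
#' `channel_map`.
#'
#' @param path file path of a delimited text file.
#' @param sep field separator (default `,`).
#' @param col_map named character vector mapping the expected column names
#'   to those present in the file.
#' @param channel_map named character vector mapping file channel labels to
#'   `"down_irradiance"` / `"up_radiance"`.
#' @param tz timezone of the timestamps.
#' @return list of records as from [tower_records()].
#' @export
read_tower_long <- function(path, sep = ",",
                            col_map = c(timestamp = "timestamp",
                                        channel = "channel",
                                        wavelength_nm = "wavelength_nm",
                                        value = "value"),
                            channel_map = c(down_irradiance = "down_irradiance",
                                            up_radiance = "up_radiance"),
                            tz = "UTC") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- unname(col_map[c("timestamp", "channel", "wavelength_nm", "value")])
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  ts <- as.POSIXct(df[[col_map["timestamp"]]], tz = tz)
  ch_raw <- df[[col_map["channel"]]]
  ch <- names(channel_map)[match(ch_raw, unname(channel_map))]
  if (anyNA(ch)) stop("unmapped channel labels: ",
                      paste(unique(ch_raw[is.na(ch)]), collapse = ", "))
  key <- paste(format(ts, "%Y-%m-%d %H:%M:%OS3"), ch)
  recs <- lapply(split(seq_len(nrow(df)), key), function(ii) {
    o <- ii[order(df[[col_map["wavelength_nm"]]][ii])]
    unit <- if (ch[ii[1]] == "down_irradiance") "irradiance" else "radiance"
    list(timestamp = ts[ii[1]], channel = ch[ii[1]],
         spectrum = spectrum(df[[col_map["wavelength_nm"]]][o],
                             df[[col_map["value"]]][o], unit))
  })
  unname(recs[order(vapply(recs, function(r) as.numeric(r$timestamp), 1))])
}

#' Pair upwelling radiance with time-interpolated downwelling irradiance
#'
#' For each upwelling acquisition bracketed by two downwelling acquisitions
#' within `max_gap_s`, the irradiance is interpolated linearly in time per
#' wavelength. Unbracketed radiance records are dropped and counted.
#'
#' @param records list from [tower_records()].
#' @param max_gap_s maximum bracketing gap in seconds (default 300).
#' @return list with `pairs` (each: `timestamp`, `E`, `L`) and `n_dropped`.
#' @export
sandwich_interpolate <- function(records, max_gap_s = 300) {
  ch <- vapply(records, `[[`, "", "channel")
  tt <- vapply(records, function(r) as.numeric(r$timestamp), 1)
  ei <- which(ch == "down_irradiance")
  li <- which(ch == "up_radiance")
  pairs <- list()
  dropped <- 0L
  for (i in li) {
    before <- ei[tt[ei] <= tt[i]]
    after <- ei[tt[ei] >= tt[i]]
    if (!length(before) || !length(after)) { dropped <- dropped + 1L; next }
    b <- before[length(before)]; a <- after[1]
    if (tt[i] - tt[b] > max_gap_s || tt[a] - tt[i] > max_gap_s) {
      dropped <- dropped + 1L; next
    }
    eb <- records[[b]]$spectrum; ea <- records[[a]]$spectrum
    if (!same_grid(eb, ea)) stop("irradiance grids differ between acquisitions")
    wgt <- if (tt[a] == tt[b]) 0 else (tt[i] - tt[b]) / (tt[a] - tt[b])
    ev <- (1 - wgt) * eb$values + wgt * ea$values
    pairs[[length(pairs) + 1L]] <-
      list(timestamp = records[[i]]$timestamp,
           E = spectrum(eb$wavelengths_nm, ev, "irradiance"),
           L = records[[i]]$spectrum)
  }
  list(pairs = pairs, n_dropped = dropped)
}

#' Classify a spectrum's sky condition
#'
#' Sunny when the zenith-normalized irradiance at 780 nm exceeds the
#' threshold: `E(780) / cos(sza) > threshold` (default 930 mW m-2 nm-1).
#'
#' @param E downwelling irradiance [spectrum()] covering 780 nm.
#' @param sza_deg solar zenith angle (degrees), < 90.
#' @param threshold_mw threshold in mW m-2 nm-1.
#' @return `"sunny"` or `"cloudy"`.
#' @export
classify_weather <- function(E, sza_deg, threshold_mw = 930) {
  if (sza_deg >= 90) stop("sza_deg must be below 90 degrees")
  e780 <- spectrum_value(E, 780)
  if (e780 / cos(sza_deg * pi / 180) > threshold_mw) "sunny" else "cloudy"
}

#' Convert O2-A-band SIF to the water-vapor band
#'
#' Elementwise multiplication by the cross-band conversion ratio
#' (`SIF(718.9) / SIF(760.6)` of the fluorescence spectral shape), either
#' user-supplied or estimated with [estimate_ratio()].
#'
#' @param sif_o2a numeric vector of O2-A-band retrievals.
#' @param ratio positive conversion ratio.
#' @return converted numeric vector.
#' @export
band_convert <- function(sif_o2a, ratio) {
  if (!is.numeric(ratio) || length(ratio) != 1 || ratio <= 0)
    stop("ratio must be a positive scalar")
  sif_o2a * ratio
}

#' Estimate the cross-band conversion ratio from fluorescence spectra
#'
#' Zero-intercept least-squares slope of `SIF(lambda_b)` on
#' `SIF(lambda_a)` across a set of fluorescence spectra (set
#' `intercept = TRUE` for the with-intercept slope).
#'
#' @param sif_spectra list of fluorescence [spectrum()]s covering both
#'   wavelengths.
#' @param lambda_a source wavelength (nm), default 760.6 (O2-A).
#' @param lambda_b target wavelength (nm), default 718.9 (H2O).
#' @param intercept fit an intercept as well (default FALSE).
#' @return the slope (conversion ratio).
#' @export
estimate_ratio <- function(sif_spectra, lambda_a = 760.6, lambda_b = 718.9,
                           intercept = FALSE) {
  if (length(sif_spectra) < 2) stop("need at least 2 fluorescence spectra")
  xa <- vapply(sif_spectra, spectrum_value, 1, lambda_a)
  xb <- vapply(sif_spectra, spectrum_value, 1, lambda_b)
  if (all(abs(xa) < .Machine$double.eps))
    stop("degenerate input: all spectra are zero at the source wavelength")
  if (intercept) {
    unname(stats::coef(stats::lm(xb ~ xa))[2])
  } else {
    sum(xa * xb) / sum(xa^2)
  }
}

#' Aggregate a retrieval series to 30-min or daily means
#'
#' Arithmetic mean of QC-passing retrievals per time bin and algorithm;
#' empty bins are omitted and member counts reported.
#'
#' @param sif_df data frame with columns `timestamp` (POSIXct),
#'   `algorithm`, `sif`, and optionally `qc_pass` (logical; missing means
#'   all pass).
#' @param interval `"30 min"` or `"1 day"`.
#' @return data frame with `bin` (POSIXct bin start), `algorithm`, `sif`
#'   (bin mean), `n` (members).
#' @export
aggregate_sif <- function(sif_df, interval = c("30 min", "1 day")) {
  interval <- match.arg(interval)
  stopifnot(all(c("timestamp", "algorithm", "sif") %in% names(sif_df)))
  keep <- if ("qc_pass" %in% names(sif_df)) sif_df$qc_pass else rep(TRUE, nrow(sif_df))
  keep <- keep & is.finite(sif_df$sif)
  df <- sif_df[keep, ]
  if (!nrow(df)) return(data.frame(bin = as.POSIXct(character()),
                                   algorithm = character(), sif = numeric(),
                                   n = integer()))
  width <- if (interval == "30 min") 1800 else 86400
  bin <- as.POSIXct(floor(as.numeric(df$timestamp) / width) * width,
                    origin = "1970-01-01", tz = attr(df$timestamp, "tzone") %||% "UTC")
  agg <- stats::aggregate(df$sif, by = list(bin = bin, algorithm = df$algorithm),
                          FUN = mean)
  cnt <- stats::aggregate(df$sif, by = list(bin = bin, algorithm = df$algorithm),
                          FUN = length)
  out <- data.frame(bin = agg$bin, algorithm = agg$algorithm, sif = agg$x,
                    n = cnt$x, stringsAsFactors = FALSE)
  out[order(out$algorithm, out$bin), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solar zenith angle for a simple diurnal model
#'
#' Spherical-geometry zenith angle from latitude, day of year and local
#' solar hour, using the standard small-angle solar declination
#' approximation. Used by the synthetic tower-day generator.
#'
#' @param hour local solar hour (0-24).
#' @param lat_deg site latitude (degrees).
#' @param doy day of year.
#' @return zenith angle in degrees.
#' @export
solar_zenith <- function(hour, lat_deg = 38.85, doy = 188) {
  decl <- -23.44 * cos(2 * pi * (doy + 10) / 365) * pi / 180
  lat <- lat_deg * pi / 180
  h <- (hour - 12) * 15 * pi / 180
  cosz <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(h)
  acos(pmin(1, pmax(-1, cosz))) * 180 / pi
}

#' Simulate a synthetic tower day of sandwich acquisitions
#'
#' Generates alternating downwelling/upwelling acquisitions for one scene
#' over a day. Irradiance follows the clear-sky solar-zenith cosine (times
#' a smooth stochastic cloud transmission when `cloudy = TRUE`); canopy
#' fluorescence scales with the incident light. Both channels are degraded
#' to the instrument configuration and carry channel noise.
#'
#' @param scene one-row scene table as from [generate_lut()].
#' @param cfg an [instrument_config()].
#' @param wvc_g_cm2 mean water-vapor column (g cm-2).
#' @param wvc_drift peak amplitude (g cm-2) of a smooth diurnal drift of
#'   the water-vapor column around its mean; 0 for a static atmosphere.
#' @param date date string (`"YYYY-MM-DD"`), sets the day of year.
#' @param lat_deg site latitude.
#' @param interval_s full sandwich cycle period in seconds (one E and one L
#'   acquisition per cycle; default 180 s = 3-min retrievals).
#' @param hours local solar hour range to simulate.
#' @param cloudy simulate broken-cloud attenuation.
#' @param seed integer seed.
#' @return list with `records` (tower record list), `truth` (data frame of
#'   per-acquisition true SIF at 718.9 nm) and `sza` (data frame of
#'   timestamp, sza_deg).
#' @export
simulate_tower_day <- function(scene, cfg = qe_pro(), wvc_g_cm2 = 3,
                               wvc_drift = 0.4, date = "2021-07-07",
                               lat_deg = 38.85, interval_s = 180,
                               hours = c(8, 18), cloudy = FALSE, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  doy <- as.integer(strftime(as.Date(date), "%j"))
  grid <- native_grid()
  cs <- canopy_spectra(scene, grid)
  cfg0 <- instrument_config(cfg$sr_fwhm_nm, cfg$sampling_interval_nm, Inf)
  sif_conv <- convolve_resample(cs$SIF, cfg0)
  t0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  cyc <- seq(hours[1] * 3600, hours[2] * 3600, by = interval_s)
  n <- length(cyc)
  cloud_tr <- if (cloudy) {
    # smooth broken-cloud transmission in [0.25, 0.75]
    raw <- stats::filter(stats::runif(n + 40), rep(1 / 20, 20), sides = 1)
    0.25 + 0.5 * as.numeric(raw[seq_len(n) + 30]) / max(raw, na.rm = TRUE)
  } else rep(1, n)
  # smooth diurnal water-vapor drift (humidity rises through the day)
  wvc_t <- wvc_g_cm2 + wvc_drift * sin(pi * (cyc / 3600 - hours[1]) /
                                         (hours[2] - hours[1] + 1e-9))
  recs <- vector("list", 2L * n)
  truth <- vector("list", n)
  sza_tab <- data.frame(timestamp = t0 + cyc,
                        sza_deg = solar_zenith(cyc / 3600, lat_deg, doy))
  ref_cos <- cos(30 * pi / 180)
  for (i in seq_len(n)) {
    atm <- atmosphere_spec(wvc_t[i])
    sza <- sza_tab$sza_deg[i]
    szaL <- solar_zenith((cyc[i] + interval_s / 2) / 3600, lat_deg, doy)
    e_nat <- solar_irradiance(atm, grid, sza_deg = min(sza, 89.9))
    E_i <- convolve_resample(spectrum(grid, e_nat$values * cloud_tr[i],
                                      "irradiance"), cfg0)
    # L is acquired interval_s/2 later; the sun has moved slightly,
    # and fluorescence tracks the incident light
    muL <- cos(szaL * pi / 180) / cos(sza * pi / 180)
    light <- cos(szaL * pi / 180) * cloud_tr[i] / ref_cos
    l_nat <- spectrum(grid, (e_nat$values * muL * cloud_tr[i]) / pi *
                        cs$R$values + light * cs$SIF$values, "radiance")
    L_i <- convolve_resample(l_nat, cfg0)
    recs[[2L * i - 1L]] <- list(timestamp = t0 + cyc[i],
                                channel = "down_irradiance",
                                spectrum = add_noise(E_i, cfg))
    recs[[2L * i]] <- list(timestamp = t0 + cyc[i] + interval_s / 2,
                           channel = "up_radiance",
                           spectrum = add_noise(L_i, cfg))
    truth[[i]] <- data.frame(timestamp = t0 + cyc[i] + interval_s / 2,
                             sif_true = spectrum_value(sif_conv, 718.9) * light,
                             sza_deg = szaL)
  }
  list(records = recs, truth = do.call(rbind, truth), sza = sza_tab)
}

#' Process a tower series into a per-acquisition retrieval table
#'
#' Runs the sandwich pairing, quality screening (positive irradiance in the
#' retrieval window, daytime floor on `E(780)`), weather classification,
#' the seven water-vapor-band algorithms, and the O2-A 3FLD reference
#' retrieval converted to the water-vapor band.
#'
#' @param records tower record list.
#' @param sza_fun function mapping POSIXct timestamps to solar zenith
#'   angles (degrees).
#' @param cfg the [instrument_config()] of the spectrometer.
#' @param ratio cross-band conversion ratio applied to the O2-A reference;
#'   default the package fluorescence shape's 718.9/760.6 ratio.
#' @param basis optional [reflectance_basis()] for pFLD; by default a
#'   simulated canopy-reflectance library (a subsample of the scene LUT,
#'   degraded to the instrument grid) is built.
#' @param e780_floor_mw dawn/dusk QC floor on `E(780)` in mW m-2 nm-1.
#' @param max_gap_s sandwich bracketing limit in seconds.
#' @return data frame with one row per acquisition x algorithm:
#'   `timestamp`, `algorithm`, `sif`, `weather`, `sza_deg`, `qc_pass`;
#'   reference rows carry algorithm `"ref_o2a_3fld"` (already converted to
#'   the water-vapor band).
#' @export
process_tower <- function(records, sza_fun, cfg = qe_pro(),
                          ratio = NULL, basis = NULL, e780_floor_mw = 50,
                          max_gap_s = 300) {
  if (is.null(ratio)) ratio <- sif_shape(718.9) / sif_shape(760.6)
  sw <- sandwich_interpolate(records, max_gap_s)
  wins_h2o <- default_windows("h2o", cfg$sr_fwhm_nm)
  wins_o2a <- default_windows("o2a", cfg$sr_fwhm_nm)
  # one SVD training set from all interpolated downwelling spectra
  training <- if (length(sw$pairs) >= 2) {
    svd_training(lapply(sw$pairs, `[[`, "E"), wins_h2o$svd)
  } else NULL
  # pFLD basis: a simulated canopy-reflectance library (subsampled LUT)
  # degraded to the instrument grid, as in the simulation experiments
  basis <- if (is.null(basis) && length(sw$pairs) >= 1) {
    wl <- sw$pairs[[1]]$E$wavelengths_nm
    sh <- shoulder_region(wl, wins_h2o$pfld$absorption_nm, cfg$sr_fwhm_nm)
    lib <- generate_lut()[seq(1, 324, by = 6), ]
    cfg0 <- instrument_config(cfg$sr_fwhm_nm, cfg$sampling_interval_nm, Inf)
    grid <- native_grid()
    tryCatch({
      M <- vapply(seq_len(nrow(lib)), function(i) {
        rc <- convolve_resample(canopy_spectra(lib[i, ], grid)$R, cfg0)
        rc$values[match(round(wl[sh$region], 6), round(rc$wavelengths_nm, 6))]
      }, numeric(length(sh$region)))
      if (anyNA(M)) stop("instrument grid does not match the library grid")
      reflectance_basis(M, wl[sh$region])
    }, error = function(e) NULL)
  } else basis
  rows <- list()
  for (p in sw$pairs) {
    sza <- sza_fun(p$timestamp)
    e780 <- spectrum_value(p$E, 780)
    qc <- is.finite(e780) && e780 > e780_floor_mw && sza < 80 &&
      all(spectrum_window(p$E, 716, 722)$values > 0)
    weather <- if (sza < 90) classify_weather(p$E, sza) else "cloudy"
    tab <- retrieve_all(p$E, p$L, wins_h2o, basis = basis,
                        training = training, sr_fwhm_nm = cfg$sr_fwhm_nm)
    ref <- tryCatch(threefld(wins_o2a$fld3, p$E, p$L)$sif_at_line,
                    error = function(e) NA_real_)
    tab <- rbind(tab[, c("algorithm", "sif")],
                 data.frame(algorithm = "ref_o2a_3fld",
                            sif = band_convert(ref, ratio)))
    tab$timestamp <- p$timestamp
    tab$weather <- weather
    tab$sza_deg <- sza
    tab$qc_pass <- qc
    rows[[length(rows) + 1L]] <- tab
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("timestamp", "algorithm", "sif", "weather", "sza_deg", "qc_pass")]
}
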