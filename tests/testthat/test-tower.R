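make_series <- function(times_e, values_e, times_l, values_l,
                        grid = seq(650, 815, 5)) {
  n <- length(grid)
  recs <- c(
    lapply(seq_along(times_e), function(i)
      list(timestamp = times_e[i], channel = "down_irradiance",
           spectrum = spectrum(grid, rep(values_e[i], n), "irradiance"))),
    lapply(seq_along(times_l), function(i)
      list(timestamp = times_l[i], channel = "up_radiance",
           spectrum = spectrum(grid, rep(values_l[i], n), "radiance"))))
  recs[order(vapply(recs, function(r) as.numeric(r$timestamp), 1))]
}

test_that("sandwich pairing interpolates irradiance linearly in time", {
  t0 <- as.POSIXct("2021-07-07 10:00:00", tz = "UTC")
  # identical E before/after
  s <- make_series(t0 + c(0, 180), c(700, 700), t0 + 90, 5)
  p <- sandwich_interpolate(s)
  expect_equal(length(p$pairs), 1)
  expect_equal(unique(p$pairs[[1]]$E$values), 700)
  # linear ramp: midpoint L gets the mean
  s <- make_series(t0 + c(0, 180), c(600, 800), t0 + 90, 5)
  expect_equal(unique(sandwich_interpolate(s)$pairs[[1]]$E$values), 700)
  # unbracketed and over-gap acquisitions are dropped, not fatal
  s <- make_series(t0 + c(0, 1000), c(600, 800), t0 + c(-50, 500), c(5, 5))
  p <- sandwich_interpolate(s, max_gap_s = 300)
  expect_equal(length(p$pairs), 0)
  expect_equal(p$n_dropped, 2)
})

test_that("time interpolation beats nearest-neighbor on a diurnal ramp", {
  t0 <- as.POSIXct("2021-07-07 06:00:00", tz = "UTC")
  e_of_t <- function(s) 900 * sin(pi * (s / 3600 + 1) / 14)  # smooth ramp
  te <- seq(0, 7200, by = 180)
  tl <- te[-length(te)] + 90
  s <- make_series(t0 + te, e_of_t(te), t0 + tl, rep(5, length(tl)))
  p <- sandwich_interpolate(s)
  est_interp <- vapply(p$pairs, function(q) q$E$values[1], 1)
  truth <- e_of_t(tl)
  # nearest-neighbor picks the closer of the bracketing acquisitions
  est_nn <- e_of_t(te[findInterval(tl, te)])
  expect_lt(rmse(truth, est_interp), rmse(truth, est_nn))
})

test_that("weather classification applies the 930 threshold at 780 nm", {
  grid <- seq(650, 815, 5)
  mk <- function(v) spectrum(grid, rep(v, length(grid)), "irradiance")
  sza <- 40
  thr <- 930 * cos(sza * pi / 180)
  expect_equal(classify_weather(mk(thr * 1.01), sza), "sunny")
  expect_equal(classify_weather(mk(thr * 0.99), sza), "cloudy")
  expect_equal(classify_weather(mk(0), sza), "cloudy")
  expect_equal(formals(classify_weather)$threshold_mw, 930)
  expect_error(classify_weather(mk(500), 90), "below 90")
})

test_that("cross-band conversion is a guarded elementwise ratio", {
  expect_equal(band_convert(c(1, 2), 1), c(1, 2))
  expect_equal(band_convert(1.0, 1.2626), 1.2626)
  x <- c(0.3, 0.9, 1.4)
  expect_equal(band_convert(band_convert(x, 1.2626), 1 / 1.2626), x,
               tolerance = 1e-12)
  expect_error(band_convert(1, -2), "positive")
})

test_that("conversion-ratio estimation recovers constructed slopes", {
  grid <- seq(650, 815, 0.5)
  shape <- sif_shape(grid)
  sp <- lapply(c(0.4, 0.8, 1.5, 2.2), function(a) spectrum(grid, a * shape))
  r <- estimate_ratio(sp)
  expect_equal(r, spectrum_value(sp[[1]], 718.9) / spectrum_value(sp[[1]], 760.6),
               tolerance = 1e-9)
  # constructed 1.25 relation
  i_a <- which.min(abs(grid - 760.6)); i_b <- which.min(abs(grid - 718.9))
  sp2 <- lapply(c(1, 2, 3), function(a) {
    v <- rep(0, length(grid)); v[i_a] <- a; v[i_b] <- 1.25 * a
    spectrum(grid, v)
  })
  expect_equal(estimate_ratio(sp2), 1.25, tolerance = 1e-12)
  z <- replicate(3, spectrum(grid, rep(0, length(grid))), simplify = FALSE)
  expect_error(estimate_ratio(z), "degenerate")
})

test_that("aggregation averages QC-passing members and conserves the mean", {
  t0 <- as.POSIXct("2021-07-07 08:00:00", tz = "UTC")
  ts <- t0 + seq(0, 3.5 * 3600 - 180, by = 180)
  df <- data.frame(timestamp = ts, algorithm = "sfm",
                   sif = rep(1.7, length(ts)))
  agg <- aggregate_sif(df, "30 min")
  expect_true(all(agg$sif == 1.7))
  expect_true(all(agg$n == 10))
  # a QC-flagged outlier is excluded
  df2 <- df; df2$sif[3] <- 99; df2$qc_pass <- TRUE; df2$qc_pass[3] <- FALSE
  expect_true(all(aggregate_sif(df2, "30 min")$sif == 1.7))
  # 3-min sampling of a known diurnal curve: bin means match bin integrals
  curve <- function(s) 2 * sin(pi * s / (12 * 3600))
  df3 <- data.frame(timestamp = ts, algorithm = "sfm",
                    sif = curve(as.numeric(ts - t0)))
  agg3 <- aggregate_sif(df3, "30 min")
  for (k in seq_len(nrow(agg3))) {
    lo <- as.numeric(difftime(agg3$bin[k], t0, units = "secs"))
    # each 3-min sample represents [t - 90 s, t + 90 s]
    analytic <- stats::integrate(curve, lo - 90, lo + 1710)$value / 1800
    expect_equal(agg3$sif[k], analytic, tolerance = 1e-4)
  }
  # weighted mean of bin means equals the overall mean
  expect_equal(sum(agg3$sif * agg3$n) / sum(agg3$n), mean(df3$sif),
               tolerance = 1e-12)
})

test_that("a synthetic tower day separates sFLD from the consistent algorithms", {
  scene <- generate_lut()[220, ]
  day <- simulate_tower_day(scene, cfg = qe_pro(), wvc_g_cm2 = 3,
                            interval_s = 300, hours = c(10, 14), seed = 2)
  sza_fun <- function(tt) {
    hrs <- as.numeric(difftime(tt, as.POSIXct("2021-07-07 00:00:00",
                                              tz = "UTC"), units = "hours"))
    solar_zenith(hrs, 38.85, 188)
  }
  res <- process_tower(day$records, sza_fun, cfg = qe_pro())
  expect_true(all(res$weather == "sunny"))
  # compare 30-min averaged series against the converted O2-A 3FLD reference
  agg <- aggregate_sif(res[res$qc_pass, ], "30 min")
  ref <- agg[agg$algorithm == "ref_o2a_3fld", c("bin", "sif")]
  errs <- vapply(c("sfld", "fld3", "ifld", "pfld", "sfm", "svd", "doas"),
                 function(a) {
    m <- merge(agg[agg$algorithm == a, ], ref, by = "bin",
               suffixes = c("", "_ref"))
    rmse(m$sif_ref, m$sif)
  }, 1)
  # sFLD overestimates severely; every other algorithm tracks the reference
  expect_equal(names(which.max(errs)), "sfld")
  expect_true(all(errs[names(errs) != "sfld"] < 0.5 * errs["sfld"]))
  # sFLD sits above the reference (overestimation), the fitted methods close
  sfld_series <- merge(agg[agg$algorithm == "sfld", ], ref, by = "bin",
                       suffixes = c("", "_ref"))
  expect_true(all(sfld_series$sif > sfld_series$sif_ref))
})

test_that("tower series round-trip through the long-format text layout", {
  t0 <- as.POSIXct("2021-07-07 10:00:00", tz = "UTC")
  grid <- seq(650, 815, 5)
  df <- rbind(
    data.frame(timestamp = format(t0), channel = "E", wavelength_nm = grid,
               value = 700 + grid / 10),
    data.frame(timestamp = format(t0 + 90), channel = "L",
               wavelength_nm = grid, value = 40 + grid / 100))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  recs <- read_tower_long(path, channel_map = c(down_irradiance = "E",
                                                up_radiance = "L"))
  expect_equal(length(recs), 2)
  expect_equal(recs[[1]]$channel, "down_irradiance")
  expect_equal(recs[[2]]$spectrum$values, 40 + grid / 100)
  expect_equal(recs[[1]]$spectrum$unit, "irradiance")
})
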