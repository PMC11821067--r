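# Shared fixture builders. Everything is generated in code; no stored data.

# fine uniform grid around the 719 nm window
fine_grid <- function(lo = 712, hi = 736, step = 0.05) seq(lo, hi, by = step)

# irradiance with Gaussian absorption dips (unit-free continuum level)
line_irradiance <- function(grid, centers = 718.9, depths = 0.5,
                            sigmas = 0.3, level = 1000) {
  tr <- rep(1, length(grid))
  for (i in seq_along(centers))
    tr <- tr * (1 - depths[i] * exp(-(grid - centers[i])^2 / (2 * sigmas[i]^2)))
  spectrum(grid, level * tr, "irradiance")
}

# compose L = E R / pi + F from value vectors
compose_L <- function(E, r_values, f_values) {
  spectrum(E$wavelengths_nm, E$values / pi * r_values + f_values, "radiance")
}

# subsample the LUT reproducibly (stride keeps all parameter levels in play)
lut_subset <- function(stride = 3) {
  scenes <- generate_lut()
  scenes[seq(1, nrow(scenes), by = stride), , drop = FALSE]
}

# noise-free retrieval of all algorithms over a scene table at one condition,
# returning per-scene estimates and truth (independent of run_experiment's
# bookkeeping; used by ordering/property tests)
retrieve_lut <- function(scenes, band = "h2o", sr = 0.3, wvc = 3, snr = Inf,
                         seed = 1) {
  design <- experiment_design(band = band, sr_fwhm_nm = sr, snr = snr,
                              wvc_g_cm2 = wvc)
  rep <- run_experiment(design, scenes, seed = seed, keep_estimates = TRUE)
  attr(rep, "estimates")
}
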