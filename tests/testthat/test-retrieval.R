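test_that("window tables follow the per-resolution reference configuration", {
  w <- default_windows("h2o", 0.31)   # QE Pro maps to the 0.3 nm row
  expect_equal(w$sfld$absorption_nm, 718.9)
  expect_equal(w$sfld$left_ref_nm, 718.5)
  expect_equal(c(w$fld3$left_ref_nm, w$fld3$right_ref_nm), c(718.6, 719.2))
  expect_equal(w$sfm$fit_range_nm, c(716.2, 721.6))
  expect_equal(w$svd$fit_range_nm, c(713.8, 733.75))
  expect_equal(w$doas$fit_range_nm, c(716.2, 721.0))
  w3 <- default_windows("h2o", 3)
  expect_equal(w3$sfld$absorption_nm, 719.5)
  expect_equal(w3$svd$fit_range_nm, c(659.6, 768.8))
  expect_equal(default_windows("h2o", 0.5)$sfld$absorption_nm, 718.75)
  expect_equal(default_windows("h2o", 1)$sfld$absorption_nm, 719.0)
  expect_error(retrieval_window("h2o", 719, left_ref_nm = 720), "short of")
  expect_error(retrieval_window("h2o", 719, fit_range_nm = c(720, 730)),
               "must contain")
})

test_that("band sampling picks nearest grid points and records wavelengths", {
  E <- line_irradiance(fine_grid(step = 0.155))
  L <- compose_L(E, rep(0.2, length(E$values)), rep(1, length(E$values)))
  w <- default_windows("h2o", 0.3)$fld3
  b <- extract_band_samples(E, L, w)
  expect_lte(abs(b$wl_in - 718.9), 0.155 / 2 + 1e-9)
  expect_true(b$Iout > b$Iin && b$Iin > 0)
  # flat irradiance: in-line equals out-of-line
  Ef <- spectrum(fine_grid(), rep(500, length(fine_grid())), "irradiance")
  bf <- extract_band_samples(Ef, compose_L(Ef, rep(0.2, length(Ef$values)),
                                           rep(0, length(Ef$values))), w)
  expect_equal(bf$Iin, bf$Iout)
  wbad <- retrieval_window("h2o", 719, left_ref_nm = 600)
  expect_error(extract_band_samples(E, L, wbad), "coverage")
})

test_that("sFLD and 3FLD match direct evaluation of their quotients", {
  grid <- fine_grid()
  E <- line_irradiance(grid)
  r <- 0.15 + 0.002 * (grid - 718.9)
  f <- 1.1 + 0.03 * (grid - 718.9)
  L <- compose_L(E, r, f)
  w <- default_windows("h2o", 0.3)
  b <- extract_band_samples(E, L, w$fld3)
  # independent symbolic oracle for both quotients
  sfld_direct <- (b$Iout * b$Lin - b$Iin * b$Lout) / (b$Iout - b$Iin)
  wl <- (b$wl_right - b$wl_in) / (b$wl_right - b$wl_left)
  i3 <- wl * b$Iout + (1 - wl) * b$Iout_r
  l3 <- wl * b$Lout + (1 - wl) * b$Lout_r
  fld3_direct <- (i3 * b$Lin - b$Iin * l3) / (i3 - b$Iin)
  expect_equal(sfld(b)$sif_at_line, sfld_direct, tolerance = 1e-14)
  expect_equal(threefld(b)$sif_at_line, fld3_direct, tolerance = 1e-14)
})

test_that("FLD family recovers truth exactly when its assumptions hold", {
  grid <- fine_grid()
  E <- line_irradiance(grid)  # symmetric dip at 718.9
  n <- length(grid)
  # sFLD: constant R and SIF
  L <- compose_L(E, rep(0.2, n), rep(1.2, n))
  w <- default_windows("h2o", 0.3)
  expect_equal(sfld(w$sfld, E, L)$sif_at_line, 1.2, tolerance = 1e-12)
  expect_equal(sfld(w$sfld, E, compose_L(E, rep(0.2, n), rep(0, n)))$sif_at_line,
               0, tolerance = 1e-12)
  # 3FLD: constant R, linear SIF (shoulders symmetric about the line)
  f_lin <- 0.9 + 0.05 * (grid - 718.9)
  L3 <- compose_L(E, rep(0.25, n), f_lin)
  expect_equal(threefld(w$fld3, E, L3)$sif_at_line, 0.9, tolerance = 1e-10)
  # degenerate line rejected
  Ef <- spectrum(grid, rep(700, n), "irradiance")
  expect_error(sfld(w$sfld, Ef, compose_L(Ef, rep(0.2, n), rep(1, n))),
               "degenerate")
})

test_that("iFLD reduces to sFLD under unit correction factors and nulls cleanly", {
  grid <- fine_grid()
  E <- line_irradiance(grid, centers = c(716.6, 718.9, 721.1),
                       depths = c(0.2, 0.5, 0.15), sigmas = c(0.2, 0.3, 0.25))
  n <- length(grid)
  r <- 0.18 + 0.004 * (grid - 718.9)
  L <- compose_L(E, r, 0.8 * sif_shape(grid))
  w <- default_windows("h2o", 0.3)
  ov <- ifld(E, L, w$ifld, sr_fwhm_nm = 0.3, alpha_override = c(1, 1))
  expect_equal(ov$sif_at_line, sfld(w$sfld, E, L)$sif_at_line,
               tolerance = 1e-12)
  # SIF-free scene with constant R: alphaR estimate is 1, retrieval is 0
  L0 <- compose_L(E, rep(0.21, n), rep(0, n))
  est0 <- ifld(E, L0, w$ifld, sr_fwhm_nm = 0.3)
  expect_lt(abs(est0$sif_at_line), 1e-8)
})

test_that("pFLD is exact inside the basis span and beats 3FLD there", {
  grid <- fine_grid()
  E <- line_irradiance(grid, centers = c(716.6, 718.9, 721.1),
                       depths = c(0.2, 0.5, 0.15), sigmas = c(0.2, 0.3, 0.25))
  lam <- grid - 718.9
  # curved reflectance family; test scene inside the span
  train <- sapply(list(c(0.18, 0.004, 8e-4), c(0.22, 0.002, 5e-4),
                       c(0.20, 0.006, -4e-4), c(0.16, 0.003, 6e-4),
                       c(0.24, 0.005, 2e-4)),
                  function(cf) cf[1] + cf[2] * lam + cf[3] * lam^2)
  basis <- reflectance_basis(train, grid, var_explained = 0.9999)
  r_test <- 0.19 + 0.004 * lam + 6e-4 * lam^2
  L <- compose_L(E, r_test, rep(0, length(grid)))
  w <- default_windows("h2o", 0.3)
  p <- pfld(E, L, w$pfld, basis, sr_fwhm_nm = 0.3)
  expect_lt(abs(p$sif_at_line), 1e-8)
  f3 <- threefld(w$fld3, E, L)$sif_at_line
  expect_lt(abs(p$sif_at_line), abs(f3))
  # a basis on a different sampling cannot serve the window
  basis_coarse <- reflectance_basis(train[seq(1, nrow(train), 4), ],
                                    grid[seq(1, length(grid), 4)])
  expect_error(pfld(E, L, w$pfld, basis_coarse, sr_fwhm_nm = 0.3),
               "does not cover")
})

test_that("SFM recovers polynomial-realizable truth and flags bad designs", {
  grid <- fine_grid()
  E <- line_irradiance(grid, centers = c(717.5, 718.9, 719.9),
                       depths = c(0.25, 0.5, 0.2), sigmas = c(0.2, 0.3, 0.22))
  lam <- (grid - 718.9) / (diff(c(716.2, 721.6)) / 2)
  r <- 0.2 + 0.01 * lam + 0.005 * lam^2
  f <- 1.0 + 0.02 * lam
  L <- compose_L(E, r, f)
  w <- default_windows("h2o", 0.3)
  fit <- sfm(E, L, w$sfm)
  expect_equal(fit$sif_at_line, 1.0, tolerance = 1e-8)
  expect_lt(fit$residual_rms, 1e-8)
  L0 <- compose_L(E, r, rep(0, length(grid)))
  expect_lt(abs(sfm(E, L0, w$sfm)$sif_at_line), 1e-8)
  # under-sampled window errors with a helpful message
  few <- retrieval_window("h2o", 718.9, fit_range_nm = c(718.7, 719.1))
  Es <- line_irradiance(fine_grid(step = 0.155))
  expect_error(sfm(Es, compose_L(Es, rep(0.2, length(Es$values)),
                                 rep(0, length(Es$values))), few), "samples")
})

test_that("SVD retrieval recovers a training-realizable composite", {
  grid <- fine_grid(710, 736)
  E <- line_irradiance(grid, centers = c(716.6, 718.9, 721.1, 725),
                       depths = c(0.2, 0.5, 0.15, 0.1),
                       sigmas = c(0.2, 0.3, 0.25, 1.5))
  w <- default_windows("h2o", 0.3)$svd
  tr <- svd_training(E, w, nv = 4, np = 3)
  sel <- match(round(tr$wl, 6), round(grid, 6))
  lam <- (tr$wl - w$absorption_nm) / (diff(w$fit_range_nm) / 2)
  hfn <- sif_shape(tr$wl) / sif_shape(w$absorption_nm)
  vals <- numeric(length(grid))
  vals[sel] <- (2 + 0.4 * lam - 0.1 * lam^2) * tr$v[, 1] + 1.5 * hfn
  L <- spectrum(grid, vals, "radiance")
  est <- svd_retrieve(L, tr, w)
  expect_equal(est$sif_at_line, 1.5, tolerance = 1e-6)
  # fluorescence-free composite -> coefficient ~ 0
  vals0 <- numeric(length(grid)); vals0[sel] <- (3 - 0.2 * lam) * tr$v[, 1]
  expect_lt(abs(svd_retrieve(spectrum(grid, vals0, "radiance"), tr, w)$sif_at_line),
            1e-8)
})

test_that("DOAS nulls an exp-polynomial reflectance and ignores hF scaling", {
  grid <- fine_grid()
  E <- line_irradiance(grid, centers = c(717.5, 718.9, 719.9),
                       depths = c(0.25, 0.5, 0.2), sigmas = c(0.2, 0.3, 0.22))
  w <- default_windows("h2o", 0.3)$doas
  lam <- (grid - w$absorption_nm) / (diff(w$fit_range_nm) / 2)
  r <- exp(-1.6 + 0.08 * lam + 0.02 * lam^2 - 0.01 * lam^3)
  L0 <- compose_L(E, r, rep(0, length(grid)))
  expect_lt(abs(doas_retrieve(E, L0, w)$sif_at_line), 1e-6)
  # the bilinear fluorescence term is scale-invariant in the shape amplitude
  L <- compose_L(E, r, 0.7 * sif_shape(grid))
  est1 <- doas_retrieve(E, L, w, hF = sif_shape)
  est2 <- doas_retrieve(E, L, w, hF = function(x) 2 * sif_shape(x))
  expect_equal(est1$sif_at_line, est2$sif_at_line, tolerance = 1e-12)
  expect_equal(est1$residual_rms, est2$residual_rms, tolerance = 1e-12)
  # nonpositive radiance rejected
  Lneg <- spectrum(grid, rep(-1, length(grid)), "radiance")
  expect_error(doas_retrieve(E, Lneg, w), "nonpositive")
})

test_that("retrieve_all isolates failures and is a pure function of its inputs", {
  grid <- fine_grid(710, 736)
  E <- line_irradiance(grid, centers = c(716.6, 718.9, 721.1, 725),
                       depths = c(0.2, 0.5, 0.15, 0.1),
                       sigmas = c(0.2, 0.3, 0.25, 1.5))
  L <- compose_L(E, 0.2 + 0.003 * (grid - 718.9), 0.9 * sif_shape(grid))
  wins <- default_windows("h2o", 0.3)
  out1 <- retrieve_all(E, L, wins, sr_fwhm_nm = 0.3)
  expect_setequal(out1$algorithm,
                  c("sfld", "fld3", "ifld", "pfld", "sfm", "svd", "doas"))
  # no basis supplied: only pFLD fails
  expect_true(is.na(out1$sif[out1$algorithm == "pfld"]))
  expect_true(all(is.finite(out1$sif[out1$algorithm != "pfld"])))
  # breaking one window breaks only that algorithm
  wins2 <- wins
  wins2$fld3 <- retrieval_window("h2o", 718.9, left_ref_nm = 718.6,
                                 right_ref_nm = 790)
  out2 <- retrieve_all(E, L, wins2, sr_fwhm_nm = 0.3)
  expect_true(is.na(out2$sif[out2$algorithm == "fld3"]))
  expect_match(out2$error[out2$algorithm == "fld3"], "coverage")
  expect_true(all(is.finite(out2$sif[!out2$algorithm %in% c("fld3", "pfld")])))
  # purity
  expect_identical(out1, retrieve_all(E, L, wins, sr_fwhm_nm = 0.3))
})
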