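# The seven SIF retrieval algorithms.
#
# All algorithms report SIF at the window's absorption wavelength in
# mW m-2 nm-1 sr-1. The FLD family works from irradiance/radiance samples
# at the line and at out-of-line references; SFM, SVD and DOAS are linear
# least-squares fits over a wavelength range.

retrieval_result <- function(algorithm, sif, window, residual_rms = NA_real_,
                             flag = NA_character_) {
  if (!is.finite(sif)) stop(algorithm, ": non-finite SIF estimate")
  structure(list(algorithm = algorithm, sif_at_line = sif,
                 absorption_nm = window$absorption_nm, band = window$band,
                 residual_rms = residual_rms, flag = flag),
            class = "retrieval_result")
}

#' @export
print.retrieval_result <- function(x, ...) {
  cat(sprintf("<%s> SIF(%.2f nm) = %.4f mW m-2 nm-1 sr-1%s\n",
              x$algorithm, x$absorption_nm, x$sif_at_line,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Extract in-line and out-of-line band samples
#'
#' Picks irradiance and radiance at the grid samples nearest the window's
#' absorption and reference wavelengths (ties broken toward the shorter
#' wavelength) and records the wavelengths actually used.
#'
#' @param E downwelling irradiance [spectrum()].
#' @param L upwelling radiance [spectrum()] on the same grid.
#' @param w a [retrieval_window()] with at least a left reference.
#' @return list with `Iin`, `Lin`, `Iout`, `Lout`, the sampled wavelengths
#'   `wl_in`, `wl_left`, and — when the window has a right reference —
#'   `Iout_r`, `Lout_r`, `wl_right`.
#' @export
extract_band_samples <- function(E, L, w) {
  stopifnot(is_spectrum(E), is_spectrum(L),
            inherits(w, "retrieval_window"))
  if (!same_grid(E, L)) stop("E and L must share one wavelength grid")
  if (is.null(w$left_ref_nm)) stop("window has no reference wavelength")
  i_in <- nearest_index(E, w$absorption_nm)
  i_l <- nearest_index(E, w$left_ref_nm)
  out <- list(Iin = E$values[i_in], Lin = L$values[i_in],
              Iout = E$values[i_l], Lout = L$values[i_l],
              wl_in = E$wavelengths_nm[i_in],
              wl_left = E$wavelengths_nm[i_l])
  if (!is.null(w$right_ref_nm)) {
    i_r <- nearest_index(E, w$right_ref_nm)
    out$Iout_r <- E$values[i_r]
    out$Lout_r <- L$values[i_r]
    out$wl_right <- E$wavelengths_nm[i_r]
  }
  out
}

#' Standard Fraunhofer line discrimination (sFLD)
#'
#' `SIF = (Iout * Lin - Iin * Lout) / (Iout - Iin)`, exact when reflectance
#' and fluorescence are constant between the in-line and reference samples.
#' On red-edge vegetation at the 719 nm band the reflectance rises through
#' the window, which makes sFLD overestimate SIF.
#'
#' @param b band samples from [extract_band_samples()], or a window: when a
#'   [retrieval_window()] is given, `E` and `L` must be supplied and samples
#'   are extracted first.
#' @param E,L optional spectra when `b` is a window.
#' @return a `retrieval_result`.
#' @export
sfld <- function(b, E = NULL, L = NULL) {
  if (inherits(b, "retrieval_window")) {
    w <- b
    b <- extract_band_samples(E, L, w)
  } else {
    w <- retrieval_window("h2o", b$wl_in, left_ref_nm = b$wl_left)
  }
  if (abs(b$Iout - b$Iin) < .Machine$double.eps * max(abs(b$Iout), 1))
    stop("degenerate absorption line: Iout equals Iin")
  sif <- (b$Iout * b$Lin - b$Iin * b$Lout) / (b$Iout - b$Iin)
  retrieval_result("sFLD", sif, w)
}

#' Three-band Fraunhofer line discrimination (3FLD)
#'
#' The two shoulder samples are interpolated linearly to the absorption
#' wavelength (weights `(wr - wa)/(wr - wl)` and `(wa - wl)/(wr - wl)`),
#' then the FLD quotient is applied with the interpolated outside values.
#' Exact when reflectance and fluorescence are linear in wavelength across
#' the window.
#'
#' @inheritParams sfld
#' @return a `retrieval_result`.
#' @export
threefld <- function(b, E = NULL, L = NULL) {
  if (inherits(b, "retrieval_window")) {
    w <- b
    b <- extract_band_samples(E, L, w)
  } else {
    w <- retrieval_window("h2o", b$wl_in, left_ref_nm = b$wl_left,
                          right_ref_nm = b$wl_right)
  }
  if (is.null(b$Iout_r))
    stop("3FLD requires a right reference sample")
  wl_l <- b$wl_left; wl_r <- b$wl_right; wl_a <- b$wl_in
  wt_l <- (wl_r - wl_a) / (wl_r - wl_l)
  wt_r <- (wl_a - wl_l) / (wl_r - wl_l)
  Iout <- wt_l * b$Iout + wt_r * b$Iout_r
  Lout <- wt_l * b$Lout + wt_r * b$Lout_r
  if (abs(Iout - b$Iin) < .Machine$double.eps * max(abs(Iout), 1))
    stop("degenerate absorption line: interpolated Iout equals Iin")
  sif <- (Iout * b$Lin - b$Iin * Lout) / (Iout - b$Iin)
  retrieval_result("3FLD", sif, w)
}

# internal: shoulder mask for correction-factor methods. The region spans
# absorption +/- max(6 nm, 4 FWHM); the core +/- 2 FWHM around the line is
# excluded.
shoulder_region <- function(wl, absorption_nm, sr_fwhm_nm) {
  half <- max(6, 4 * sr_fwhm_nm)
  region <- which(wl >= absorption_nm - half & wl <= absorption_nm + half)
  core <- abs(wl[region] - absorption_nm) < 2 * sr_fwhm_nm
  list(region = region, shoulder = region[!core])
}

# internal: which region samples are line-free, judged against a linear
# irradiance baseline between the region endpoints. Samples inside any
# absorption feature (E below depth_thresh x baseline) or within the
# +/- 2 FWHM core are masked; falls back to the core-only mask when fewer
# than min_keep samples survive.
line_free_mask <- function(wl_region, e_region, absorption_nm, sr_fwhm_nm,
                           depth_thresh = 0.97, min_keep = 4) {
  n <- length(wl_region)
  baseline <- e_region[1] + (e_region[n] - e_region[1]) *
    (wl_region - wl_region[1]) / (wl_region[n] - wl_region[1])
  outside_core <- abs(wl_region - absorption_nm) >= 2 * sr_fwhm_nm
  keep <- outside_core & e_region >= depth_thresh * baseline
  if (sum(keep) < min_keep) keep <- outside_core
  keep
}

# internal: infer the instrument FWHM from the sampling spacing under the
# package's FWHM = 2 x sampling-interval convention
infer_fwhm <- function(s) 2 * stats::median(diff(s$wavelengths_nm))

#' Improved Fraunhofer line discrimination (iFLD)
#'
#' `SIF = (aR * Iout * Lin - Iin * Lout) / (aR * Iout - aS * Iin)` with
#' `aR = R^(out)/R^(in)` and `aS = F^(out)/F^(in)`. The line-free
#' reflectance shape `R^` is estimated by a cubic spline through the
#' apparent reflectance `pi L / E` on the window shoulders; the absorption
#' core (+/- 2 FWHM around the line) and samples inside other absorption
#' features (irradiance below 97% of a linear baseline) are masked. The
#' fluorescence shape `F^` defaults to the package's two-peak emission
#' shape.
#'
#' @param E,L spectra on one grid.
#' @param w a [retrieval_window()] with a left reference.
#' @param sr_fwhm_nm instrument FWHM (nm) used to mask the absorption core;
#'   by default twice the median sample spacing.
#' @param alpha_override optional `c(alpha_R, alpha_SIF)` bypassing the
#'   shape estimation (with `c(1, 1)` iFLD reduces to [sfld()]).
#' @param hF fluorescence shape function of wavelength; default
#'   [sif_shape()].
#' @return a `retrieval_result`; flagged when too few shoulder samples
#'   support the interpolation.
#' @export
ifld <- function(E, L, w, sr_fwhm_nm = NULL, alpha_override = NULL,
                 hF = sif_shape) {
  b <- extract_band_samples(E, L, w)
  flag <- NA_character_
  if (is.null(alpha_override)) {
    if (is.null(sr_fwhm_nm)) sr_fwhm_nm <- infer_fwhm(E)
    wl <- E$wavelengths_nm
    sh <- shoulder_region(wl, w$absorption_nm, sr_fwhm_nm)
    keep <- line_free_mask(wl[sh$region], E$values[sh$region],
                           w$absorption_nm, sr_fwhm_nm)
    shoulder <- sh$region[keep]
    if (length(shoulder) < 4)
      stop("too few shoulder samples to interpolate the reflectance shape")
    if (length(shoulder) < 8) flag <- "sparse_shoulder"
    rho <- pi * L$values[shoulder] / E$values[shoulder]
    x <- wl[shoulder]
    rhat <- if (length(x) >= 10) {
      fit <- stats::smooth.spline(x, rho, df = min(8, length(x) - 1))
      function(z) stats::predict(fit, z)$y
    } else {
      stats::splinefun(x, rho, method = "natural")
    }
    a_r <- rhat(b$wl_left) / rhat(b$wl_in)
    a_s <- hF(b$wl_left) / hF(b$wl_in)
  } else {
    a_r <- alpha_override[1]
    a_s <- alpha_override[2]
  }
  den <- a_r * b$Iout - a_s * b$Iin
  if (abs(den) < .Machine$double.eps * max(abs(b$Iout), 1))
    stop("degenerate iFLD denominator")
  sif <- (a_r * b$Iout * b$Lin - b$Iin * b$Lout) / den
  retrieval_result("iFLD", sif, w, flag = flag)
}

#' Reflectance basis for pFLD
#'
#' Principal-component basis of a reflectance training library: components
#' are retained until they explain at least `var_explained` of the training
#' variance.
#'
#' @param refl_matrix matrix of training reflectances, one column per
#'   spectrum, rows matching `wl`.
#' @param wl wavelength grid (nm) of the rows.
#' @param var_explained fraction of variance to retain (default 0.999).
#' @param max_components hard cap on the number of retained components
#'   (useful when the library is noisy, where a variance criterion alone
#'   keeps noise components).
#' @return object of class `reflectance_basis` with the mean spectrum and
#'   the retained component vectors.
#' @export
reflectance_basis <- function(refl_matrix, wl, var_explained = 0.999,
                              max_components = Inf) {
  stopifnot(nrow(refl_matrix) == length(wl), ncol(refl_matrix) >= 2)
  pc <- stats::prcomp(t(refl_matrix), center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- max(1L, which(cum >= var_explained)[1])
  k <- min(k, max_components, length(pc$sdev))
  structure(list(wl = wl, mean = pc$center,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 n_components = k),
            class = "reflectance_basis")
}

#' Principal-component Fraunhofer line discrimination (pFLD)
#'
#' Like [ifld()], but the line-free reflectance is reconstructed by
#' projecting the shoulder apparent reflectance onto a principal-component
#' basis trained on a reflectance library (which must not contain the scene
#' under test): `R..(lambda) = mean + sum_i k_i Phi_i(lambda)`. The
#' correction factor `aR` comes from the reconstruction; `aS` from the
#' fluorescence shape.
#'
#' @inheritParams ifld
#' @param basis a [reflectance_basis()] whose grid covers the window region
#'   on the same sampling as `E`.
#' @return a `retrieval_result`.
#' @export
pfld <- function(E, L, w, basis, sr_fwhm_nm = NULL, hF = sif_shape) {
  stopifnot(inherits(basis, "reflectance_basis"))
  b <- extract_band_samples(E, L, w)
  if (is.null(sr_fwhm_nm)) sr_fwhm_nm <- infer_fwhm(E)
  wl <- E$wavelengths_nm
  sh <- shoulder_region(wl, w$absorption_nm, sr_fwhm_nm)
  # map spectrum samples onto the basis grid
  bi <- match(round(wl[sh$region], 6), round(basis$wl, 6))
  if (anyNA(bi))
    stop("basis grid does not cover the retrieval window at this sampling")
  shoulder_in_region <- line_free_mask(wl[sh$region], E$values[sh$region],
                                       w$absorption_nm, sr_fwhm_nm)
  if (basis$n_components > sum(shoulder_in_region))
    stop("basis dimension exceeds the number of shoulder samples")
  rho <- pi * L$values[sh$region] / E$values[sh$region]
  phi <- basis$rotation[bi, , drop = FALSE]
  mu <- basis$mean[bi]
  kfit <- stats::lsfit(phi[shoulder_in_region, , drop = FALSE],
                       rho[shoulder_in_region] - mu[shoulder_in_region],
                       intercept = FALSE)
  recon <- mu + drop(phi %*% kfit$coefficients)
  r_at <- function(target) recon[which.min(abs(wl[sh$region] - target))]
  a_r <- r_at(b$wl_left) / r_at(b$wl_in)
  a_s <- hF(b$wl_left) / hF(b$wl_in)
  den <- a_r * b$Iout - a_s * b$Iin
  if (abs(den) < .Machine$double.eps * max(abs(b$Iout), 1))
    stop("degenerate pFLD denominator")
  sif <- (a_r * b$Iout * b$Lin - b$Iin * b$Lout) / den
  retrieval_result("pFLD", sif, w,
                   residual_rms = sqrt(mean((rho[shoulder_in_region] -
                                               recon[shoulder_in_region])^2)))
}

#' Spectral fitting method (SFM)
#'
#' Least-squares fit of the forward model
#' `L(lambda) = R(lambda) E(lambda) / pi + SIF(lambda)` over the window's
#' fit range, with `R` a polynomial of degree `deg_r` and `SIF` a
#' polynomial of degree `deg_f`. SIF is reported at the absorption
#' wavelength. By default `deg_r` is 2 for windows narrower than 8 nm and
#' 3 otherwise; `deg_f` is 1.
#'
#' @param E,L spectra on one grid.
#' @param w a [retrieval_window()] with a fit range.
#' @param deg_r,deg_f polynomial degrees for reflectance and fluorescence.
#' @return a `retrieval_result` with the fit residual RMS.
#' @export
sfm <- function(E, L, w, deg_r = NULL, deg_f = 1) {
  stopifnot(inherits(w, "retrieval_window"))
  if (is.null(w$fit_range_nm)) stop("SFM requires a window with a fit range")
  if (!same_grid(E, L)) stop("E and L must share one wavelength grid")
  sel <- which(E$wavelengths_nm >= w$fit_range_nm[1] &
                 E$wavelengths_nm <= w$fit_range_nm[2])
  width <- diff(w$fit_range_nm)
  if (is.null(deg_r)) deg_r <- if (width <= 8) 2 else 3
  if (length(sel) < deg_r + deg_f + 2)
    stop(sprintf("SFM window [%.1f, %.1f] nm has %d samples; need >= %d",
                 w$fit_range_nm[1], w$fit_range_nm[2], length(sel),
                 deg_r + deg_f + 2))
  wl <- E$wavelengths_nm[sel]
  lam <- (wl - w$absorption_nm) / (width / 2)  # centered, scaled
  ev <- E$values[sel] / pi
  xr <- outer(lam, 0:deg_r, `^`) * ev
  xf <- outer(lam, 0:deg_f, `^`)
  X <- cbind(xr, xf)
  fit <- stats::lsfit(X, L$values[sel], intercept = FALSE)
  if (any(is.na(fit$coefficients)))
    stop(sprintf("rank-deficient SFM design in [%.1f, %.1f] nm (deg_r=%d, deg_f=%d)",
                 w$fit_range_nm[1], w$fit_range_nm[2], deg_r, deg_f))
  cf <- fit$coefficients[(deg_r + 2):(deg_r + deg_f + 2)]
  lam_a <- 0  # absorption wavelength is the centering point
  sif <- sum(cf * lam_a^(0:deg_f))
  retrieval_result("SFM", sif, w,
                   residual_rms = sqrt(mean(fit$residuals^2)))
}

#' Training set for the singular-vector retrieval
#'
#' Computes singular vectors of a column-normalized training matrix of
#' downwelling spectra over the window's fit range. The vectors capture the
#' spectral structure (absorption lines and their variation) of the
#' non-fluorescent signal.
#'
#' @param E_list list of irradiance [spectrum()]s (or a single spectrum)
#'   sharing one grid — e.g. all downwelling acquisitions of a day.
#' @param w a [retrieval_window()] with a fit range.
#' @param nv number of singular vectors to retain (capped at the matrix
#'   rank).
#' @param np polynomial degree multiplying each vector.
#' @return object of class `svd_training`.
#' @export
svd_training <- function(E_list, w, nv = 4, np = 3) {
  if (is_spectrum(E_list)) E_list <- list(E_list)
  stopifnot(length(E_list) >= 1, inherits(w, "retrieval_window"))
  if (is.null(w$fit_range_nm)) stop("SVD requires a window with a fit range")
  g <- E_list[[1]]$wavelengths_nm
  sel <- which(g >= w$fit_range_nm[1] & g <= w$fit_range_nm[2])
  if (length(sel) < 3) stop("training spectra do not resolve the fit range")
  M <- vapply(E_list, function(s) {
    if (!same_grid(s, E_list[[1]])) stop("training spectra must share one grid")
    s$values[sel]
  }, numeric(length(sel)))
  M <- as.matrix(M)
  M <- sweep(M, 2, sqrt(colSums(M^2)), `/`)  # column-scaled
  sv <- svd(M)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  structure(list(wl = g[sel], v = sv$u[, seq_len(min(nv, rank)), drop = FALSE],
                 nv = min(nv, rank), np = np, fit_range_nm = w$fit_range_nm),
            class = "svd_training")
}

#' Singular-vector (SVD) retrieval
#'
#' Models the at-sensor radiance as polynomial-modulated singular vectors of
#' the downwelling training set plus a fixed fluorescence shape:
#' `L = sum_i sum_j a_ij lambda^i v_j + SIF * hF * Tup`, solved by linear
#' least squares. The upward transmittance `Tup` is 1 for tower geometry;
#' `hF` is normalized to 1 at the absorption wavelength so the coefficient
#' is SIF at the line.
#'
#' @param L upwelling radiance [spectrum()] covering the fit range at the
#'   training sampling.
#' @param training an [svd_training()].
#' @param w the [retrieval_window()] used for training.
#' @param hF fluorescence shape function; default [sif_shape()].
#' @param t_up upward transmittance (default 1).
#' @return a `retrieval_result`.
#' @export
svd_retrieve <- function(L, training, w, hF = sif_shape, t_up = 1) {
  stopifnot(inherits(training, "svd_training"), is_spectrum(L))
  sel <- match(round(training$wl, 6), round(L$wavelengths_nm, 6))
  if (anyNA(sel)) stop("radiance grid does not match the training grid")
  y <- L$values[sel]
  lam <- (training$wl - w$absorption_nm) / (diff(training$fit_range_nm) / 2)
  cols <- list()
  for (i in 0:training$np)
    for (j in seq_len(training$nv))
      cols[[length(cols) + 1L]] <- lam^i * training$v[, j]
  hvec <- hF(training$wl) / hF(w$absorption_nm) * t_up
  X <- cbind(do.call(cbind, cols), hvec)
  if (ncol(X) >= length(y))
    stop("SVD design has more columns than samples; reduce nv or np")
  fit <- stats::lsfit(X, y, intercept = FALSE)
  sif <- unname(fit$coefficients[ncol(X)])
  retrieval_result("SVD", sif, w,
                   residual_rms = sqrt(mean(fit$residuals^2)))
}

#' DOAS log-ratio retrieval
#'
#' Fits the optical-depth-like quantity `D = ln(pi L / E)` as a smooth
#' polynomial in wavelength plus a linearized fluorescence term
#' `SIF * hF(lambda) / L(lambda)` (one-pass linearization using the
#' measured radiance). By default the polynomial degree is 3 for windows
#' narrower than 8 nm and 5 otherwise.
#'
#' @param E,L spectra on one grid, strictly positive over the fit range.
#' @param w a [retrieval_window()] with a fit range.
#' @param hF fluorescence shape function; default [sif_shape()],
#'   normalized to 1 at the absorption wavelength.
#' @param np polynomial degree.
#' @return a `retrieval_result`.
#' @export
doas_retrieve <- function(E, L, w, hF = sif_shape, np = NULL) {
  stopifnot(inherits(w, "retrieval_window"))
  if (is.null(w$fit_range_nm)) stop("DOAS requires a window with a fit range")
  if (!same_grid(E, L)) stop("E and L must share one wavelength grid")
  sel <- which(E$wavelengths_nm >= w$fit_range_nm[1] &
                 E$wavelengths_nm <= w$fit_range_nm[2])
  width <- diff(w$fit_range_nm)
  if (is.null(np)) np <- if (width <= 8) 3 else 5
  if (length(sel) < np + 3)
    stop("DOAS window under-sampled for the requested polynomial degree")
  ev <- E$values[sel]; lv <- L$values[sel]
  if (any(ev <= 0) || any(lv <= 0))
    stop("nonpositive irradiance or radiance in the DOAS window")
  d <- log(pi * lv / ev)
  wl <- E$wavelengths_nm[sel]
  lam <- (wl - w$absorption_nm) / (width / 2)
  hvec <- hF(wl) / hF(w$absorption_nm)
  X <- cbind(outer(lam, 0:np, `^`), hvec / lv)
  fit <- stats::lsfit(X, d, intercept = FALSE)
  sif <- unname(fit$coefficients[ncol(X)])
  retrieval_result("DOAS", sif, w,
                   residual_rms = sqrt(mean(fit$residuals^2)))
}

#' Run all seven algorithms on one irradiance/radiance pair
#'
#' Applies sFLD, 3FLD, iFLD, pFLD, SFM, SVD and DOAS with the supplied
#' window set. Per-algorithm failures are recorded in the result table, not
#' raised.
#'
#' @param E,L spectra on one grid.
#' @param windows named window list from [default_windows()].
#' @param basis optional [reflectance_basis()] for pFLD (without it pFLD is
#'   recorded as failed).
#' @param training optional [svd_training()]; by default trained on `E`
#'   alone.
#' @param sr_fwhm_nm instrument FWHM for the shoulder masks; inferred from
#'   the sampling when missing.
#' @param hF fluorescence shape function shared by iFLD/pFLD/SVD/DOAS.
#' @return data frame with one row per algorithm: `algorithm`, `sif`,
#'   `residual_rms`, `error` (NA when the algorithm succeeded).
#' @export
retrieve_all <- function(E, L, windows, basis = NULL, training = NULL,
                         sr_fwhm_nm = NULL, hF = sif_shape) {
  if (is.null(sr_fwhm_nm)) sr_fwhm_nm <- infer_fwhm(E)
  if (is.null(training))
    training <- tryCatch(svd_training(E, windows$svd), error = function(e) NULL)
  runs <- list(
    sfld = function() sfld(windows$sfld, E, L),
    fld3 = function() threefld(windows$fld3, E, L),
    ifld = function() ifld(E, L, windows$ifld, sr_fwhm_nm, hF = hF),
    pfld = function() {
      if (is.null(basis)) stop("no reflectance basis supplied")
      pfld(E, L, windows$pfld, basis, sr_fwhm_nm, hF = hF)
    },
    sfm  = function() sfm(E, L, windows$sfm),
    svd  = function() {
      if (is.null(training)) stop("no SVD training set")
      svd_retrieve(L, training, windows$svd, hF = hF)
    },
    doas = function() doas_retrieve(E, L, windows$doas, hF = hF))
  rows <- lapply(names(runs), function(nm) {
    res <- tryCatch(runs[[nm]](), error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(algorithm = nm, sif = NA_real_, residual_rms = NA_real_,
                 error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      data.frame(algorithm = nm, sif = res$sif_at_line,
                 residual_rms = res$residual_rms, error = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
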