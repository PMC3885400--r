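#' Reflectance spectrum
#'
#' @param wavelengths strictly increasing wavelengths, nm.
#' @param reflectance dimensionless reflectance in (0, 1].
#' @return a `spectrum`.
#' @export
spectrum <- function(wavelengths, reflectance) {
  if (length(wavelengths) != length(reflectance))
    stop("wavelengths and reflectance must have equal length")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(reflectance <= 0))
    stop("reflectance must be positive (absorbance must be finite)")
  if (any(reflectance > 1))
    stop("reflectance must not exceed 1")
  structure(list(wavelengths = wavelengths, reflectance = reflectance),
            class = "spectrum")
}

#' Absorbance spectrum
#'
#' `A(lambda) = -log10 R(lambda)`.
#'
#' @param spec a [spectrum()].
#' @return a list with `wavelengths` and `absorbance` (class `absorbance`).
#' @export
absorbance <- function(spec) {
  stopifnot(inherits(spec, "spectrum"))
  structure(list(wavelengths = spec$wavelengths,
                 absorbance = -log10(spec$reflectance)),
            class = "absorbance")
}

#' Regress an absorbance spectrum on hemoglobin extinction spectra
#'
#' Ordinary least squares of `A(lambda)` on `eps_HbO(lambda)`,
#' `eps_HbR(lambda)` and an intercept over the wavelength window. The
#' intercept `alpha_0` absorbs the attenuation due to light scattering; the
#' slopes measure how much each extinction spectrum contributes to the
#' absorbance.
#'
#' @param absorb an [absorbance()] object.
#' @param table a [chromophore_table()].
#' @param window `c(low, high)` wavelength window, nm; must contain at least
#'   10 samples.
#' @return list with `alpha_HbO`, `alpha_HbR`, `alpha_0`
#'   (class `regression_coefficients`).
#' @export
regress_chromophores <- function(absorb, table = hemoglobin_extinction(),
                                 window = c(500, 620)) {
  stopifnot(inherits(absorb, "absorbance"))
  sel <- absorb$wavelengths >= window[1] & absorb$wavelengths <= window[2]
  if (sum(sel) < 10)
    stop("window must contain at least 10 wavelength samples")
  wl <- absorb$wavelengths[sel]
  X <- cbind(eps_HbO = extinction(table, wl, "HbO"),
             eps_HbR = extinction(table, wl, "HbR"),
             intercept = 1)
  y <- absorb$absorbance[sel]
  qrX <- qr(X)
  if (qrX$rank < 3)
    stop("rank-deficient design: window too narrow or collinear extinctions")
  beta <- qr.coef(qrX, y)
  structure(list(alpha_HbO = unname(beta[1]), alpha_HbR = unname(beta[2]),
                 alpha_0 = unname(beta[3])),
            class = "regression_coefficients")
}

#' Default conversion-model training grid
#'
#' Rectangular box in `(C_HbO, C_HbR, a)` covering the physiological range of
#' the measurements: hemoglobin concentrations 0.01-0.12 mM (4 levels each)
#' and scattering amplitude 1-3 1/mm (3 levels).
#'
#' @param C_HbO,C_HbR,a axis levels.
#' @return a `conversion_grid` list of axis levels.
#' @export
conversion_grid <- function(C_HbO = seq(0.01, 0.12, length.out = 4),
                            C_HbR = seq(0.01, 0.12, length.out = 4),
                            a = c(1, 2, 3)) {
  for (ax in list(C_HbO = C_HbO, C_HbR = C_HbR, a = a)) {
    if (!length(ax) %in% c(1L, length(ax)) || any(ax < 0))
      stop("grid levels must be non-negative")
  }
  chk <- function(v, nm) {
    if (length(v) != 1 && length(v) < 3)
      stop(sprintf("axis '%s' needs at least 3 levels (or exactly 1 for a collapsed axis)", nm))
  }
  chk(C_HbO, "C_HbO"); chk(C_HbR, "C_HbR"); chk(a, "a")
  structure(list(C_HbO = sort(C_HbO), C_HbR = sort(C_HbR), a = sort(a)),
            class = "conversion_grid")
}

# quadratic design in the three (standardised) regression coefficients
quad_design <- function(a1, a2, a3) {
  cbind(1, a1, a2, a3, a1^2, a2^2, a3^2, a1 * a2, a1 * a3, a2 * a3)
}

#' Forward reflectance spectrum for a homogeneous cortex
#'
#' Forward model family shared by the conversion-model builder, the inversion
#' round trips and the synthetic spectrum generator: semi-infinite
#' single-layer cortex viewed by the fiber pair, computed either by Monte
#' Carlo (`method = "mc"`, the reference) or by the analytic
#' diffusion-approximation fallback (`method = "diffusion"`, fast).
#'
#' @param C_HbO,C_HbR hemoglobin concentrations, mM.
#' @param a scattering amplitude at 500 nm, 1/mm.
#' @param wavelengths nm.
#' @param fibers a [fiber_geometry()].
#' @param method `"mc"` or `"diffusion"`.
#' @param n_photons,seed Monte Carlo settings (ignored for diffusion).
#' @param table a [chromophore_table()].
#' @param exponent_b,anisotropy_g,refractive_index cortex optical defaults.
#' @return a [spectrum()].
#' @export
forward_spectrum <- function(C_HbO, C_HbR, a, wavelengths = seq(500, 620, 5),
                             fibers = fiber_geometry(),
                             method = c("diffusion", "mc"),
                             n_photons = 1e5, seed = 1,
                             table = hemoglobin_extinction(),
                             exponent_b = 1.3, anisotropy_g = 0.9,
                             refractive_index = 1.37) {
  method <- match.arg(method)
  law <- scattering_law(a, exponent_b)
  if (method == "diffusion") {
    mua <- absorption_coefficient(C_HbO, C_HbR, wavelengths, table)
    musp <- reduced_scattering(law, wavelengths)
    r <- diffusion_fiber_reflectance(mua, musp, fibers)
  } else {
    tis <- cortex_model(C_HbO = C_HbO, C_HbR = C_HbR, a = a,
                        exponent_b = exponent_b, anisotropy_g = anisotropy_g,
                        refractive_index = refractive_index)
    r <- vapply(seq_along(wavelengths), function(i) {
      simulate_reflectance(tis, fibers, wavelengths[i],
                           n_photons = n_photons,
                           seed = seed * 1000 + i,
                           table = table)$reflectance_detected
    }, numeric(1))
  }
  if (any(r <= 0))
    stop("forward model produced non-positive reflectance (no detected photons?)")
  spectrum(wavelengths, pmin(r, 1))
}

#' Fit the conversion model mapping regression coefficients to tissue truth
#'
#' For every point of the `(C_HbO, C_HbR, a)` training grid the fiber-pair
#' reflectance spectrum is forward-simulated over the regression window, the
#' absorbance is regressed on the extinction spectra
#' ([regress_chromophores()]), and a full quadratic polynomial map from the
#' coefficient triple `(alpha_HbO, alpha_HbR, alpha_0)` to each of `C_HbO`,
#' `C_HbR` and `a` is fitted by least squares. The fitted object inverts
#' measured spectra via [invert_spectrum()].
#'
#' With `method = "mc"` the builder runs one absorption-free path-recording
#' simulation per (scattering amplitude, wavelength) and reweights the
#' recorded photon paths with `exp(-mua L)` across the whole concentration
#' grid; this absorption-rescaling identity leaves the estimand unchanged (see
#' the methods vignette) and reduces 10^5-photon grid construction to about a
#' minute of CPU.
#'
#' @param grid a [conversion_grid()].
#' @param fibers a [fiber_geometry()].
#' @param wavelengths regression-window wavelengths, nm.
#' @param method `"mc"` (reference) or `"diffusion"` (fast analytic).
#' @param n_photons photons per forward run (MC only).
#' @param seed integer seed.
#' @param table a [chromophore_table()].
#' @param exponent_b,anisotropy_g,refractive_index cortex optical defaults.
#' @param min_r2 minimum in-sample R^2 for the two concentration maps; the
#'   fit errors out below this.
#' @param min_r2_a hard floor for the scattering-amplitude map. The
#'   amplitude is weakly identified by the coefficient triple over the
#'   visible window, so under Monte Carlo noise its in-sample R^2 sits below
#'   that of the concentration maps; values below `min_r2` trigger a warning,
#'   values below `min_r2_a` an error. StO2 depends only on the
#'   concentration maps (see the methods vignette).
#' @return a `conversion_model`.
#' @export
fit_conversion_model <- function(grid = conversion_grid(),
                                 fibers = fiber_geometry(),
                                 wavelengths = seq(500, 620, 5),
                                 method = c("mc", "diffusion"),
                                 n_photons = 2e5, seed = 1,
                                 table = hemoglobin_extinction(),
                                 exponent_b = 1.3, anisotropy_g = 0.9,
                                 refractive_index = 1.37, min_r2 = 0.95,
                                 min_r2_a = 0.5) {
  method <- match.arg(method)
  stopifnot(inherits(grid, "conversion_grid"))
  pts <- expand.grid(C_HbO = grid$C_HbO, C_HbR = grid$C_HbR, a = grid$a,
                     KEEP.OUT.ATTRS = FALSE)
  window <- range(wavelengths)
  e_o <- extinction(table, wavelengths, "HbO")
  e_r <- extinction(table, wavelengths, "HbR")

  refl <- matrix(NA_real_, nrow(pts), length(wavelengths))
  if (method == "mc") {
    for (ia in seq_along(grid$a)) {
      law <- scattering_law(grid$a[ia], exponent_b)
      for (iw in seq_along(wavelengths)) {
        musp <- reduced_scattering(law, wavelengths[iw])
        run <- mc_path_run(musp, anisotropy_g, refractive_index, fibers,
                           n_photons,
                           seed = seed * 1e5 + ia * 1000 + iw)
        rows <- which(pts$a == grid$a[ia])
        for (j in rows) {
          mua <- log(10) * (e_o[iw] * pts$C_HbO[j] + e_r[iw] * pts$C_HbR[j]) / 10
          refl[j, iw] <- sum(run$depth_weights * exp(-mua * run$path_lengths)) /
            n_photons
        }
      }
    }
  } else {
    for (j in seq_len(nrow(pts))) {
      sp <- forward_spectrum(pts$C_HbO[j], pts$C_HbR[j], pts$a[j],
                             wavelengths, fibers, method = "diffusion",
                             table = table, exponent_b = exponent_b)
      refl[j, ] <- sp$reflectance
    }
  }
  if (any(refl <= 0))
    stop("Monte Carlo forward runs produced non-positive reflectance; ",
         "increase n_photons")

  alphas <- t(apply(refl, 1, function(r) {
    co <- regress_chromophores(absorbance(spectrum(wavelengths, pmin(r, 1))),
                               table, window)
    c(co$alpha_HbO, co$alpha_HbR, co$alpha_0)
  }))
  colnames(alphas) <- c("alpha_HbO", "alpha_HbR", "alpha_0")

  ctr <- colMeans(alphas)
  scl <- apply(alphas, 2, stats::sd)
  scl[scl == 0] <- 1
  Z <- sweep(sweep(alphas, 2, ctr), 2, scl, "/")
  X <- quad_design(Z[, 1], Z[, 2], Z[, 3])

  fit_one <- function(y) {
    collapsed <- length(unique(y)) == 1
    if (collapsed)
      return(list(coef = c(y[1], rep(0, 9)), r2 = 1, constant = TRUE))
    f <- stats::lm.fit(X, y)
    r2 <- 1 - sum(f$residuals^2) / sum((y - mean(y))^2)
    list(coef = ifelse(is.na(f$coefficients), 0, f$coefficients), r2 = r2,
         constant = FALSE)
  }
  maps <- list(C_HbO = fit_one(pts$C_HbO),
               C_HbR = fit_one(pts$C_HbR),
               a = fit_one(pts$a))
  r2 <- vapply(maps, `[[`, numeric(1), "r2")
  if (any(r2[c("C_HbO", "C_HbR")] < min_r2) || r2["a"] < min_r2_a)
    stop(sprintf(
      "conversion-map quality below tolerance: R^2 = (%s) for (C_HbO, C_HbR, a)",
      paste(sprintf("%.3f", r2), collapse = ", ")))
  if (r2["a"] < min_r2)
    warning(sprintf(
      "scattering-amplitude map R^2 = %.3f < %.2f: `a` estimates are coarse ",
      r2["a"], min_r2),
      "at this photon budget; concentration maps are unaffected")

  structure(list(maps = maps, r2 = r2, center = ctr, scale = scl,
                 grid = grid,
                 forward_grid = cbind(pts, alphas),
                 window = window, wavelengths = wavelengths,
                 method = method, n_photons = n_photons, seed = seed,
                 fibers = fibers, table = table,
                 optics = list(exponent_b = exponent_b,
                               anisotropy_g = anisotropy_g,
                               refractive_index = refractive_index),
                 alpha_range = apply(alphas, 2, range)),
            class = "conversion_model")
}

#' @export
print.conversion_model <- function(x, ...) {
  cat("Conversion model (", x$method, " forward runs, ",
      nrow(x$forward_grid), " grid points, ",
      length(x$wavelengths), " wavelengths in ",
      x$window[1], "-", x$window[2], " nm)\n", sep = "")
  cat(sprintf("  in-sample R^2: C_HbO %.4f, C_HbR %.4f, a %.4f\n",
              x$r2[1], x$r2[2], x$r2[3]))
  cat(sprintf("  box: C_HbO [%g, %g] mM, C_HbR [%g, %g] mM, a [%g, %g] 1/mm\n",
              min(x$grid$C_HbO), max(x$grid$C_HbO),
              min(x$grid$C_HbR), max(x$grid$C_HbR),
              min(x$grid$a), max(x$grid$a)))
  invisible(x)
}

#' @export
summary.conversion_model <- function(object, ...) {
  print(object)
  cat("\nIn-sample recovery (map evaluated at each grid point's own alphas):\n")
  pred <- predict(object, object$forward_grid[, c("alpha_HbO", "alpha_HbR",
                                                  "alpha_0")])
  err <- pred - object$forward_grid[, c("C_HbO", "C_HbR", "a")]
  print(apply(abs(err), 2, stats::quantile, probs = c(0.5, 0.95)))
  invisible(object)
}

#' Evaluate the conversion map at regression-coefficient triples
#'
#' @param object a `conversion_model`.
#' @param newdata data frame with columns `alpha_HbO`, `alpha_HbR`, `alpha_0`.
#' @param ... unused.
#' @return data frame with columns `C_HbO`, `C_HbR`, `a`.
#' @export
predict.conversion_model <- function(object, newdata, ...) {
  z1 <- (newdata$alpha_HbO - object$center[1]) / object$scale[1]
  z2 <- (newdata$alpha_HbR - object$center[2]) / object$scale[2]
  z3 <- (newdata$alpha_0 - object$center[3]) / object$scale[3]
  X <- quad_design(z1, z2, z3)
  out <- data.frame(C_HbO = drop(X %*% object$maps$C_HbO$coef),
                    C_HbR = drop(X %*% object$maps$C_HbR$coef),
                    a = drop(X %*% object$maps$a$coef))
  out
}

#' Invert a reflectance spectrum to hemoglobin parameters
#'
#' Absorbance conversion, regression on the extinction spectra, and the
#' fitted conversion map give `(C_HbO, C_HbR, a)`; saturation follows as
#' `StO2 = C_HbO / (C_HbO + C_HbR)`. Negative mapped concentrations are
#' clipped to zero and flagged; coefficient triples outside the model's
#' training range are flagged `"extrapolated"` (an estimate is still
#' returned).
#'
#' @param spec a [spectrum()].
#' @param model a `conversion_model`.
#' @param window wavelength window; defaults to the model's.
#' @return an `hb_estimate`: `C_HbO`, `C_HbR`, `C_HbT`, `a` and `StO2`
#'   plus a character vector of `flags`.
#' @export
invert_spectrum <- function(spec, model, window = model$window) {
  stopifnot(inherits(spec, "spectrum"), inherits(model, "conversion_model"))
  if (window[1] < model$window[1] || window[2] > model$window[2])
    stop("window must lie within the window the model was built on")
  co <- regress_chromophores(absorbance(spec), model$table, window)
  al <- c(co$alpha_HbO, co$alpha_HbR, co$alpha_0)
  flags <- character(0)
  rng <- model$alpha_range
  span <- rng[2, ] - rng[1, ]
  if (any(al < rng[1, ] - 0.1 * span | al > rng[2, ] + 0.1 * span)) {
    flags <- c(flags, "extrapolated")
    warning("regression coefficients outside the conversion model's ",
            "training hull; estimate flagged as extrapolated")
  }
  est <- predict(model, data.frame(alpha_HbO = al[1], alpha_HbR = al[2],
                                   alpha_0 = al[3]))
  if (est$C_HbO < 0 || est$C_HbR < 0) flags <- c(flags, "clipped")
  C_HbO <- max(est$C_HbO, 0)
  C_HbR <- max(est$C_HbR, 0)
  C_HbT <- C_HbO + C_HbR
  structure(list(C_HbO = C_HbO, C_HbR = C_HbR, C_HbT = C_HbT,
                 a = est$a,
                 StO2 = if (C_HbT > 0) C_HbO / C_HbT else NA_real_,
                 alpha = co, flags = flags),
            class = "hb_estimate")
}

#' @export
print.hb_estimate <- function(x, ...) {
  cat(sprintf(
    "C_HbO %.4f mM  C_HbR %.4f mM  C_HbT %.4f mM  a %.3f 1/mm  StO2 %s\n",
    x$C_HbO, x$C_HbR, x$C_HbT, x$a,
    if (is.na(x$StO2)) "undefined" else sprintf("%.1f%%", 100 * x$StO2)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Invert a spectrum time series
#'
#' @param series a [spectrum_series()].
#' @param model a `conversion_model`.
#' @param window wavelength window; defaults to the model's.
#' @return data frame with one row per time point: `time_s`, `C_HbO_mM`,
#'   `C_HbR_mM`, `C_HbT_mM`, `a_mm`, `StO2`, `flags`.
#' @export
invert_series <- function(series, model, window = model$window) {
  stopifnot(inherits(series, "spectrum_series"))
  rows <- lapply(seq_along(series$time_s), function(i) {
    est <- invert_spectrum(spectrum(series$wavelengths,
                                    series$reflectance[, i]),
                           model, window)
    data.frame(time_s = series$time_s[i], C_HbO_mM = est$C_HbO,
               C_HbR_mM = est$C_HbR, C_HbT_mM = est$C_HbT, a_mm = est$a,
               StO2 = est$StO2,
               flags = paste(est$flags, collapse = ";"))
  })
  do.call(rbind, rows)
}

#' Hemoglobin oxygen saturation
#'
#' `StO2 = C_HbO / (C_HbO + C_HbR)`.
#'
#' @param C_HbO,C_HbR non-negative concentrations (vectorised); an error is
#'   raised where both are zero.
#' @return saturation fraction in `[0, 1]`.
#' @export
oxygen_saturation <- function(C_HbO, C_HbR) {
  if (any(C_HbO < 0) || any(C_HbR < 0))
    stop("concentrations must be non-negative")
  tot <- C_HbO + C_HbR
  if (any(tot == 0))
    stop("saturation undefined: C_HbO and C_HbR are both zero")
  C_HbO / tot
}
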