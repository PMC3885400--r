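#' Monte Carlo diffuse reflectance for a fiber pair
#'
#' Weighted-photon random walk in the layered tissue (step length
#' `-log(xi)/mu_t`, per-interaction weight decrement `W mu_a/mu_t`,
#' Henyey-Greenstein deflection, Fresnel reflection/refraction at every
#' refractive-index mismatch, Russian-roulette termination). Photons are
#' launched uniformly over the source-fiber face within the NA cone; photons
#' exiting the top surface inside the detector-fiber footprint and acceptance
#' cone are scored into `reflectance_detected`, recording each one's maximum
#' visited depth. Detection uses an exact azimuthal-arc estimator (see the
#' methods vignette), so detected "photons" carry fractional weights.
#'
#' A fixed seed gives bit-identical results: the kernel uses its own
#' deterministic generator, independent of R's RNG state.
#'
#' @param tissue a [tissue_model()].
#' @param fibers a [fiber_geometry()].
#' @param wavelength wavelength in nm.
#' @param n_photons number of photons to launch (at least 1000).
#' @param seed integer seed for the kernel RNG.
#' @param table a [chromophore_table()].
#' @param roulette_threshold,roulette_m Russian-roulette weight threshold and
#'   survival factor.
#' @param max_path photons are terminated once their geometric path exceeds
#'   this length (mm); guards against unbounded walks when `mu_a = 0`.
#' @return an `mc_result` with fields `reflectance_detected`,
#'   `reflectance_total`, `absorbed_fraction`, `transmitted_fraction`,
#'   `max_depth_samples`, `depth_weights`, `n_detected`, `n_photons`, `seed`,
#'   `wavelength`.
#' @export
#' @examples
#' res <- simulate_reflectance(cortex_model(), fiber_geometry(), 569,
#'                             n_photons = 5000, seed = 1)
#' res$reflectance_detected
simulate_reflectance <- function(tissue, fibers, wavelength,
                                 n_photons = 1e5, seed = 1,
                                 table = hemoglobin_extinction(),
                                 roulette_threshold = 1e-4, roulette_m = 10,
                                 max_path = 2000) {
  stopifnot(inherits(tissue, "tissue_model"), inherits(fibers, "fiber_geometry"))
  if (n_photons < 1e3) stop("n_photons must be at least 1000")
  lm_ <- layer_matrix(tissue, wavelength, table)
  raw <- .mc_run(lm_,
                 n_above = fibers$coupling_index, n_below = 1.0,
                 src_radius = fibers$core_diameter_um / 2000,
                 det_distance = fibers$center_separation_mm,
                 det_radius = fibers$core_diameter_um / 2000,
                 na = fibers$numerical_aperture,
                 n_photons = as.integer(n_photons), seed = seed,
                 roulette_threshold = roulette_threshold,
                 roulette_m = roulette_m, max_path = max_path,
                 record_paths = FALSE, path_roulette_start = Inf)
  structure(c(raw, list(n_photons = n_photons, seed = seed,
                        wavelength = wavelength,
                        cortex_offset = cortex_offset(tissue))),
            class = "mc_result")
}

# absorption-free path-recording run used by the conversion-model builder:
# one run per (scattering, wavelength) is reweighted across the whole
# concentration grid with the Beer-Lambert factor exp(-mua * L)
mc_path_run <- function(musp, g, n_tissue, fibers, n_photons, seed,
                        max_path = 300) {
  lm_ <- matrix(c(Inf, 0, musp / (1 - g), g, n_tissue), nrow = 1)
  .mc_run(lm_,
          n_above = fibers$coupling_index, n_below = 1.0,
          src_radius = fibers$core_diameter_um / 2000,
          det_distance = fibers$center_separation_mm,
          det_radius = fibers$core_diameter_um / 2000,
          na = fibers$numerical_aperture,
          n_photons = as.integer(n_photons), seed = seed,
          roulette_threshold = 1e-4, roulette_m = 10,
          max_path = max_path, record_paths = TRUE,
          path_roulette_start = 30)
}

#' Sampling-depth percentiles of detected photons
#'
#' Percentiles of the per-detected-photon maximum visited depth (the depth
#' statistic describing which cortical depths the fiber pair interrogates).
#' Depths are reported relative to the cortical surface when a skull layer is
#' present. Percentiles are weighted by the detection weights; `(0, 100)`
#' returns the sample minimum and maximum.
#'
#' @param result an `mc_result` with at least 100 detected photons.
#' @param lower_pct,upper_pct percentiles in `[0, 100]`.
#' @return named numeric `c(depth_low, depth_high)` in mm.
#' @export
sampling_depth <- function(result, lower_pct = 25, upper_pct = 75) {
  stopifnot(inherits(result, "mc_result"))
  if (result$n_detected < 100)
    stop("insufficient statistics: fewer than 100 detected photons")
  d <- result$max_depth_samples - result$cortex_offset
  q <- weighted_quantile(d, result$depth_weights,
                         c(lower_pct, upper_pct) / 100)
  c(depth_low = q[1], depth_high = q[2])
}

#' @export
print.mc_result <- function(x, ...) {
  cat("Monte Carlo reflectance (", format(x$n_photons, big.mark = ","),
      " photons, seed ", x$seed, ", ", x$wavelength, " nm)\n", sep = "")
  cat(sprintf("  detected   %.3e\n  total      %.4f\n  absorbed   %.4f\n",
              x$reflectance_detected, x$reflectance_total,
              x$absorbed_fraction))
  cat(sprintf("  transmitted %.4f   detected photons: %d\n",
              x$transmitted_fraction, as.integer(x$n_detected)))
  invisible(x)
}

#' Diffusion-approximation total diffuse reflectance
#'
#' Closed form for a semi-infinite medium with matched boundaries: an
#' isotropic point source of strength `a' = mu_s'/(mu_a + mu_s')` buried at
#' `z0 = 1/(mu_a + mu_s')` with an image source across the extrapolated
#' boundary `z_b = 2D`; integrating the escaping flux over the surface gives
#' `R = (a'/2) (exp(-mu_eff z0) + exp(-mu_eff (z0 + 2 z_b)))` with
#' `mu_eff = sqrt(3 mu_a (mu_a + mu_s'))`. Valid in the diffusive regime
#' (`mu_s' >> mu_a`); used as an independent oracle for the Monte Carlo.
#'
#' @param mua absorption coefficient, 1/mm.
#' @param musp reduced scattering coefficient, 1/mm.
#' @return total diffuse reflectance (fraction).
#' @export
diffusion_total_reflectance <- function(mua, musp) {
  at <- musp / (mua + musp)
  z0 <- 1 / (mua + musp)
  mueff <- sqrt(3 * mua * (mua + musp))
  zb <- 2 / (3 * (mua + musp))
  (at / 2) * (exp(-mueff * z0) + exp(-mueff * (z0 + 2 * zb)))
}

#' Diffusion-approximation fiber-pair reflectance
#'
#' Steady-state diffusion-theory radially resolved diffuse reflectance
#' (dipole source with extrapolated boundary) evaluated at the fiber
#' separation and multiplied by the detector-fiber area: the fast analytic
#' forward model exposed behind the same interface as the Monte Carlo. Used
#' for quick tests and round trips; the Monte Carlo path is the reference.
#'
#' @param mua,musp optical coefficients, 1/mm (vectorised).
#' @param fibers a [fiber_geometry()].
#' @return detected reflectance fraction (dimensionless).
#' @export
diffusion_fiber_reflectance <- function(mua, musp, fibers = fiber_geometry()) {
  rho <- fibers$center_separation_mm
  at <- musp / (mua + musp)
  z0 <- 1 / (mua + musp)
  mueff <- sqrt(3 * mua * (mua + musp))
  zb <- 2 / (3 * (mua + musp))
  r1 <- sqrt(rho^2 + z0^2)
  r2 <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  rr <- (at / (4 * pi)) *
    (z0 * (mueff + 1 / r1) * exp(-mueff * r1) / r1^2 +
     (z0 + 2 * zb) * (mueff + 1 / r2) * exp(-mueff * r2) / r2^2)
  area <- pi * (fibers$core_diameter_um / 2000)^2
  rr * area
}
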