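# shared fixtures and oracles

# raw packaged extinction table, read independently of the accessor under test
raw_extinction_csv <- function() {
  utils::read.csv(system.file("extdata", "hemoglobin_extinction.csv",
                              package = "sdoptics"))
}

# hand-rolled normal-equations OLS used as the independent regression oracle
normal_equations <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# moderately absorbing single-layer medium for fast MC runs
fast_tissue <- function(mua = 0.5, musp = 1.5, g = 0.9, n = 1.37) {
  tissue_model(tissue_layer(Inf, 0, 0, scattering_law(musp, 0), g, n,
                            mua_background = mua))
}

# near-normal-incidence fiber pair in an index-matched ambient (the geometry
# the diffusion closed forms assume)
matched_fibers <- function(na = 0.05) {
  fiber_geometry(coupling_index = 1.0, numerical_aperture = na)
}

# the Monte Carlo conversion model is expensive; build it once per test run
mc_model_cache <- new.env(parent = emptyenv())
get_mc_model <- function() {
  if (is.null(mc_model_cache$model)) {
    mc_model_cache$model <- suppressWarnings(
      fit_conversion_model(method = "mc", seed = 1))
  }
  mc_model_cache$model
}

diffusion_model_cache <- new.env(parent = emptyenv())
get_diffusion_model <- function() {
  if (is.null(diffusion_model_cache$model)) {
    diffusion_model_cache$model <- fit_conversion_model(method = "diffusion")
  }
  diffusion_model_cache$model
}
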