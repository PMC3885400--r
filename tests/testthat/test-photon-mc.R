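test_that("a fixed seed reproduces the Monte Carlo result bit for bit", {
  a <- simulate_reflectance(fast_tissue(), fiber_geometry(), 560,
                            n_photons = 2e4, seed = 123)
  b <- simulate_reflectance(fast_tissue(), fiber_geometry(), 560,
                            n_photons = 2e4, seed = 123)
  expect_identical(a[names(a) != "seed"], b[names(b) != "seed"])
  c <- simulate_reflectance(fast_tissue(), fiber_geometry(), 560,
                            n_photons = 2e4, seed = 124)
  expect_false(identical(a$reflectance_detected, c$reflectance_detected))
})

test_that("energy is conserved and fractions are well-formed", {
  res <- simulate_reflectance(fast_tissue(), fiber_geometry(), 560,
                              n_photons = 1e5, seed = 5)
  tot <- res$reflectance_total + res$absorbed_fraction +
    res$transmitted_fraction
  expect_lt(abs(tot - 1), 1e-3)
  fr <- c(res$reflectance_detected, res$reflectance_total,
          res$absorbed_fraction, res$transmitted_fraction)
  expect_true(all(fr >= 0 & fr <= 1))
  expect_lte(res$reflectance_detected, res$reflectance_total)
  # finite slab transmits
  slab <- tissue_model(tissue_layer(0.5, 0, 0, scattering_law(1, 0), 0.9,
                                    1.0, mua_background = 0.01))
  rs <- simulate_reflectance(slab, matched_fibers(), 560, n_photons = 2e4,
                             seed = 6)
  expect_gt(rs$transmitted_fraction, 0.5)
  expect_lt(abs(rs$reflectance_total + rs$absorbed_fraction +
                  rs$transmitted_fraction - 1), 1e-3)
})

test_that("limiting cases: no absorption reflects, heavy absorption kills", {
  # mua = 0, matched boundary, semi-infinite: everything eventually escapes up
  none <- tissue_model(tissue_layer(Inf, 0, 0, scattering_law(1, 0), 0,
                                    1.0, mua_background = 0))
  r0 <- simulate_reflectance(none, matched_fibers(), 560, n_photons = 2e4,
                             seed = 7, max_path = 1e5)
  expect_gt(r0$reflectance_total, 0.99)
  # mua >> mus': detected reflectance collapses
  heavy <- tissue_model(tissue_layer(Inf, 0, 0, scattering_law(1, 0), 0.9,
                                     1.37, mua_background = 50))
  rh <- simulate_reflectance(heavy, fiber_geometry(), 560, n_photons = 2e4,
                             seed = 8)
  expect_lt(rh$reflectance_detected, 1e-8)
  expect_error(tissue_layer(Inf, mua_background = -0.1), "non-negative")
  expect_error(
    sdoptics:::.mc_run(matrix(c(Inf, -0.1, 10, 0.9, 1.37), 1), 1.37, 1,
                       0.4, 2, 0.4, 0.22, 1000, 1),
    "non-physical")
  expect_error(simulate_reflectance(fast_tissue(), fiber_geometry(), 560,
                                    n_photons = 10, seed = 1), "at least")
})

test_that("total reflectance matches diffusion theory in the diffusive regime", {
  # mus'/mua = 100, matched boundary, near-normal incidence
  mua <- 0.01; musp <- 1.0
  tis <- tissue_model(tissue_layer(Inf, 0, 0, scattering_law(musp, 0), 0.9,
                                   1.0, mua_background = mua))
  res <- simulate_reflectance(tis, matched_fibers(), 560, n_photons = 1e5,
                              seed = 9)
  oracle <- diffusion_total_reflectance(mua, musp)
  expect_lt(abs(res$reflectance_total / oracle - 1), 0.05)
})

test_that("detected reflectance decreases monotonically with absorption", {
  fib <- fiber_geometry()
  r <- vapply(c(0.05, 0.2, 0.8), function(mua) {
    simulate_reflectance(fast_tissue(mua = mua), fib, 560, n_photons = 5e4,
                         seed = 11)$reflectance_detected
  }, numeric(1))
  expect_true(all(diff(r) < 0))
})

test_that("standard error scales as one over the square root of n", {
  fib <- fiber_geometry()
  spread <- function(n) {
    x <- vapply(1:8, function(s)
      simulate_reflectance(fast_tissue(mua = 0.2), fib, 560, n_photons = n,
                           seed = 200 + s)$reflectance_detected, numeric(1))
    stats::sd(x) / mean(x)
  }
  s1 <- spread(1e4)
  s16 <- spread(16e4)
  # expected ratio 4; allow generous slack for the 8-replicate estimate
  expect_gt(s1 / s16, 2)
  expect_lt(s1 / s16, 8)
})

test_that("sampling depth percentiles behave and respond to deep absorption", {
  res <- simulate_reflectance(fast_tissue(mua = 0.1), fiber_geometry(), 560,
                              n_photons = 1e5, seed = 13)
  q <- sampling_depth(res, 0, 100)
  expect_equal(unname(q[1]), min(res$max_depth_samples))
  expect_equal(unname(q[2]), max(res$max_depth_samples))
  iqr <- sampling_depth(res)
  expect_lt(iqr[1], iqr[2])
  # raising deep-layer absorption shifts both percentiles shallower
  two <- function(mua_deep, seed) {
    tis <- tissue_model(
      tissue_layer(1.2, 0, 0, scattering_law(1.5, 0), 0.9, 1.37,
                   mua_background = 0.05, name = "cortex"),
      tissue_layer(Inf, 0, 0, scattering_law(1.5, 0), 0.9, 1.37,
                   mua_background = mua_deep, name = "deep"))
    sampling_depth(simulate_reflectance(tis, fiber_geometry(), 560,
                                        n_photons = 1e5, seed = seed))
  }
  lo <- two(0.02, 14)
  hi <- two(1.0, 14)
  expect_lt(hi[1], lo[1])
  expect_lt(hi[2], lo[2])
  small <- simulate_reflectance(fast_tissue(mua = 5), fiber_geometry(), 560,
                                n_photons = 2e3, seed = 15)
  expect_error(sampling_depth(small), "insufficient")
})
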