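test_that("absorbance is the decadic log with an exact round trip", {
  wl <- seq(500, 620, 10)
  sp1 <- spectrum(wl, rep(1, length(wl)))
  expect_equal(absorbance(sp1)$absorbance, rep(0, length(wl)))
  sp2 <- spectrum(wl, rep(0.1, length(wl)))
  expect_equal(absorbance(sp2)$absorbance, rep(1, length(wl)))
  set.seed(1)
  r <- runif(length(wl), 0.01, 1)
  expect_equal(10^(-absorbance(spectrum(wl, r))$absorbance), r,
               tolerance = 1e-15)
  expect_error(spectrum(wl, c(0, rep(0.5, length(wl) - 1))), "positive")
})

test_that("chromophore regression is exact on linear constructions", {
  tab <- hemoglobin_extinction()
  wl <- seq(500, 620, 5)
  A <- 0.7 * extinction(tab, wl, "HbO") + 0.2 * extinction(tab, wl, "HbR") +
    0.05
  ab <- structure(list(wavelengths = wl, absorbance = A),
                  class = "absorbance")
  co <- regress_chromophores(ab, tab)
  expect_equal(co$alpha_HbO, 0.7, tolerance = 1e-10)
  expect_equal(co$alpha_HbR, 0.2, tolerance = 1e-10)
  expect_equal(co$alpha_0, 0.05, tolerance = 1e-10)
  ab2 <- structure(list(wavelengths = wl,
                        absorbance = extinction(tab, wl, "HbO")),
                   class = "absorbance")
  co2 <- regress_chromophores(ab2, tab)
  expect_equal(c(co2$alpha_HbO, co2$alpha_HbR, co2$alpha_0), c(1, 0, 0),
               tolerance = 1e-10)
})

test_that("regression equals the normal-equations oracle under noise", {
  tab <- hemoglobin_extinction()
  wl <- seq(500, 620, 5)
  X <- cbind(extinction(tab, wl, "HbO"), extinction(tab, wl, "HbR"), 1)
  set.seed(2)
  for (i in 1:5) {
    A <- drop(X %*% runif(3, 0, 1)) + rnorm(length(wl), 0, 0.02)
    ab <- structure(list(wavelengths = wl, absorbance = A),
                    class = "absorbance")
    co <- regress_chromophores(ab, tab)
    beta <- normal_equations(X, A)
    expect_equal(c(co$alpha_HbO, co$alpha_HbR, co$alpha_0), unname(beta),
                 tolerance = 1e-10)
  }
  expect_error(regress_chromophores(
    structure(list(wavelengths = wl[1:5], absorbance = rnorm(5)),
              class = "absorbance"), tab), "at least 10")
  # collinear predictors (equal extinctions) are rejected
  flat <- chromophore_table(wl, rep(10, length(wl)), rep(10, length(wl)))
  ab3 <- structure(list(wavelengths = wl, absorbance = rnorm(length(wl))),
                   class = "absorbance")
  expect_error(regress_chromophores(ab3, flat), "rank-deficient")
})

test_that("oxygen saturation follows its defining ratio", {
  expect_equal(oxygen_saturation(1, 1), 0.5)
  expect_equal(oxygen_saturation(0.37, 0), 1)
  expect_equal(oxygen_saturation(0.03, 0.02), 0.6)
  expect_error(oxygen_saturation(0, 0), "both zero")
  expect_error(oxygen_saturation(-1, 2), "non-negative")
})

test_that("the diffusion conversion model is self-consistent on its grid", {
  m <- get_diffusion_model()
  expect_true(all(m$r2 >= 0.95))
  fg <- m$forward_grid
  pred <- predict(m, fg[, c("alpha_HbO", "alpha_HbR", "alpha_0")])
  # interior grid points recover their own parameters within 5%
  interior <- fg$C_HbO > 0.01 & fg$C_HbO < 0.12 &
    fg$C_HbR > 0.01 & fg$C_HbR < 0.12 & fg$a == 2
  expect_lt(max(abs(pred$C_HbO[interior] / fg$C_HbO[interior] - 1)), 0.05)
  expect_lt(max(abs(pred$C_HbR[interior] / fg$C_HbR[interior] - 1)), 0.05)
  # the scattering amplitude is the weakly identified target (see vignette)
  expect_lt(max(abs(pred$a[interior] / fg$a[interior] - 1)), 0.10)
})

test_that("off-grid interior round trips recover concentrations and StO2", {
  m <- get_diffusion_model()
  sp <- forward_spectrum(0.055, 0.075, 1.7, method = "diffusion")
  est <- invert_spectrum(sp, m)
  expect_lt(abs(est$C_HbO / 0.055 - 1), 0.10)
  expect_lt(abs(est$C_HbR / 0.075 - 1), 0.10)
  # noiseless diffusion on both sides: saturation nearly exact
  expect_lt(abs(est$StO2 - 0.055 / 0.13), 0.01)
  expect_equal(est$C_HbT, est$C_HbO + est$C_HbR)
})

test_that("saturation recovery over random interior truths is tight", {
  m <- get_diffusion_model()
  set.seed(99)
  errs <- vapply(1:20, function(i) {
    C1 <- runif(1, 0.025, 0.105)
    C2 <- runif(1, 0.025, 0.105)
    av <- runif(1, 1.3, 2.7)
    sp <- forward_spectrum(C1, C2, av, method = "diffusion")
    est <- invert_spectrum(sp, m)
    100 * abs(est$StO2 - C1 / (C1 + C2))
  }, numeric(1))
  expect_lte(stats::median(errs), 3)
  expect_lte(max(errs), 8)
})

test_that("scattering scale changes do not bias the recovered saturation", {
  m <- get_diffusion_model()
  base <- invert_spectrum(forward_spectrum(0.06, 0.04, 1.8,
                                           method = "diffusion"), m)
  scaled <- invert_spectrum(forward_spectrum(0.06, 0.04, 2.7,
                                             method = "diffusion"), m)
  # amplitude recovery tracks the truth only coarsely (weak identifiability,
  # see the methods vignette); saturation must stay unbiased
  expect_equal(scaled$a / base$a, 1.5, tolerance = 0.25)
  expect_gt(scaled$a, base$a)
  expect_lt(100 * abs(scaled$StO2 - base$StO2), 3)
})

test_that("clipping and extrapolation are flagged, saturation stays in [0, 1]", {
  m <- get_diffusion_model()
  # C_HbR at the truth boundary: estimate may clip, StO2 stays high
  sp <- forward_spectrum(0.08, 0.01, 2, method = "diffusion")
  est <- invert_spectrum(sp, m)
  expect_gte(est$StO2, 0.8)
  expect_true(est$StO2 >= 0 && est$StO2 <= 1)
  # a spectrum far outside the training box is flagged as extrapolated
  wl <- m$wavelengths
  wild <- spectrum(wl, rep(0.9, length(wl)))
  expect_warning(est2 <- invert_spectrum(wild, m), "extrapolated")
  expect_true("extrapolated" %in% est2$flags)
  if (est2$C_HbT > 0) expect_true(est2$StO2 >= 0 && est2$StO2 <= 1)
})

test_that("a collapsed scattering axis still fits the concentration maps", {
  g1 <- conversion_grid(a = 2)
  m1 <- fit_conversion_model(grid = g1, method = "diffusion")
  expect_equal(m1$r2[["a"]], 1)
  sp <- forward_spectrum(0.05, 0.05, 2, method = "diffusion")
  est <- invert_spectrum(sp, m1)
  expect_equal(est$a, 2, tolerance = 1e-9) # constant axis returned as is
  expect_lt(abs(est$StO2 - 0.5), 0.02)
})

test_that("grid validation rejects too-sparse axes", {
  expect_error(conversion_grid(C_HbO = c(0.01, 0.12)), "at least 3")
  expect_silent(conversion_grid(a = 1.5))
})

test_that("series inversion returns one labelled row per time point", {
  m <- get_diffusion_model()
  traj <- sto2_trajectory(c(-30, 60, 300, 900))
  ser <- gen_forward_spectrum_series(traj, noise_sd = 0, seed = 1)
  est <- invert_series(ser, m)
  expect_identical(nrow(est), 4L)
  truth <- traj$C_HbO / (traj$C_HbO + traj$C_HbR)
  expect_lt(max(abs(est$StO2 - truth)), 0.02)
})
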