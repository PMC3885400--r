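test_that("baseline normalization maps the baseline to one and is scale invariant", {
  t <- seq(-60, 120)
  const <- optical_trace(t, rep(3.7, length(t)))
  expect_equal(baseline_normalize(const)$value, rep(1, length(t)))
  set.seed(1)
  v <- 2 + 0.1 * sin(t / 10) + rnorm(length(t), 0, 0.01)
  tr1 <- baseline_normalize(optical_trace(t, v))
  tr2 <- baseline_normalize(optical_trace(t, 17.3 * v))
  expect_equal(tr1$value, tr2$value, tolerance = 1e-12)
  b <- gen_trace_bundle(sd_event_profile(seed = 4))
  r569 <- baseline_normalize(b$r569)
  base <- mean(r569$value[r569$time_s <= 0])
  expect_equal(base, 1, tolerance = 1e-3)
  expect_error(baseline_normalize(const, c(0, 10)), "before the stimulus")
  expect_error(baseline_normalize(optical_trace(-1:120, c(1, rep(2, 121)))),
               "at least 5")
})

test_that("band ratios reject common-mode changes and track programmed steps", {
  wl <- c(569, 578, 605, 620, 805)
  t <- seq(-30, 90)
  step <- 1 + 0.2 * (t >= 40) # oxygenation step at t = 40
  refl <- rbind(rep(0.5, length(t)), 0.5 * step, rep(0.4, length(t)),
                rep(0.45, length(t)), rep(0.6, length(t)))
  ser <- spectrum_series(wl, t, refl)
  expect_equal(band_ratio(ser, 578, 578)$value, rep(1, length(t)))
  ser2 <- spectrum_series(wl, t, refl * 1.9)
  expect_equal(band_ratio(ser2, 578, 569)$value,
               band_ratio(ser, 578, 569)$value, tolerance = 1e-12)
  oxy <- band_ratio(ser, 578, 569)
  jump <- which(diff(oxy$value) > 0.1)
  expect_equal(t[jump + 1], 40, tolerance = max(diff(t)))
  # nearest-node lookup within 2 nm; beyond errors
  expect_silent(band_ratio(ser, 806.5))
  expect_error(band_ratio(ser, 700), "no wavelength")
})

test_that("turning point is the first baseline crossing after the extremum", {
  t <- seq(-30, 600)
  # noiseless rise then fall crossing 1.0 at exactly t = 250
  dev <- 0.05 * pmin(t / 50, 1) - 0.11 * pmax((t - 200) / 110, 0)
  tr <- optical_trace(t, 1 + ifelse(t > 0, dev, 0))
  tp <- detect_turning_point(tr)
  expect_equal(tp, 250, tolerance = 1.0) # within one sample interval
  # monotone trace never re-crossing -> none detected
  mono <- optical_trace(t, 1 + 0.1 * smoothstep(t / 100))
  expect_true(is.na(detect_turning_point(mono)))
  # generator truth: programmed turning point at 180 s (three-minute decline)
  prof <- sd_event_profile(hypoxemia_phase = list(
    turning_point_s = 180, duration_s = 5400, depth_frac = 0.06,
    fall_tau_s = 60, recover_tau_s = 120), seed = 7)
  b <- gen_trace_bundle(prof)
  expect_equal(detect_turning_point(baseline_normalize(b$oxy)), 180,
               tolerance = 10)
})

test_that("scattering-event detector recovers the programmed transient", {
  b <- gen_trace_bundle(sd_event_profile(seed = 2))
  res <- detect_scattering_event(baseline_normalize(b$r805))
  expect_true(res$detected)
  expect_equal(res$duration_s, 240, tolerance = 15)
  # polarity invariance (bright-first vs dark-first wave)
  bneg <- gen_trace_bundle(sd_event_profile(
    scattering_event = list(onset_s = 5, duration_s = 240,
                            amplitude_frac = 0.2, polarity = -1), seed = 2))
  resn <- detect_scattering_event(baseline_normalize(bneg$r805))
  expect_true(resn$detected)
  expect_equal(resn$duration_s, res$duration_s, tolerance = 10)
  # flat noisy trace far below threshold
  set.seed(3)
  flat <- optical_trace(seq(-60, 600), 1 + rnorm(661, 0, 0.005))
  expect_false(detect_scattering_event(flat)$detected)
})

test_that("EEG suppression duration matches the programmed epoch", {
  b <- gen_trace_bundle(sd_event_profile(seed = 5))
  res <- detect_eeg_suppression(b$eeg, fs_hz = 100)
  expect_true(res$detected)
  expect_equal(res$duration_s, 420, tolerance = 30)
  # stationary noise alone is not suppressed
  set.seed(8)
  noise <- optical_trace(seq(-60, 600, by = 0.01),
                         rnorm(66001, 0, 50))
  expect_false(detect_eeg_suppression(noise, fs_hz = 100)$detected)
  # duration recovery within one RMS window across suppression depths
  for (depth in c(0.6, 0.75, 0.9)) {
    bb <- gen_trace_bundle(sd_event_profile(
      eeg_suppression = list(onset_s = 10, duration_s = 300,
                             depth_frac = depth, amplitude_uV = 50),
      seed = 11))
    r <- detect_eeg_suppression(bb$eeg, fs_hz = 100)
    expect_true(r$detected)
    expect_equal(r$duration_s, 300, tolerance = 10 + 5)
  }
  expect_error(detect_eeg_suppression(
    optical_trace(0:5 / 100, rnorm(6), 0), fs_hz = 100), "shorter")
})

test_that("DC-shift detector recovers amplitude and onset", {
  b <- gen_trace_bundle(sd_event_profile(seed = 1))
  res <- detect_dc_shift(b$dc)
  expect_equal(res$max_negative_shift_mV, 7.2, tolerance = 0.3)
  expect_equal(res$onset_s, 120, tolerance = 10)
  expect_gt(res$time_to_min_s, 120)
  # onset recovery across seeds
  for (s in 2:4) {
    bb <- gen_trace_bundle(sd_event_profile(seed = s))
    expect_equal(detect_dc_shift(bb$dc)$onset_s, 120, tolerance = 10)
  }
  # flat trace: no shift beyond noise, no onset
  set.seed(12)
  flat <- optical_trace(seq(-60, 300, 0.1), rnorm(3601, 0, 0.05))
  rf <- detect_dc_shift(flat)
  expect_lt(abs(rf$max_negative_shift_mV), 0.3)
  expect_true(is.na(rf$onset_s))
})

test_that("long-hypoxemia detector respects duration threshold and boundary", {
  b <- gen_trace_bundle(sd_event_profile(seed = 3))
  res <- detect_long_hypoxemia(baseline_normalize(b$oxy))
  expect_true(res$detected)
  expect_equal(res$duration_s, 5400, tolerance = 120)
  # a brief two-minute dip is rejected at the default 1800 s floor
  short <- gen_trace_bundle(sd_event_profile(
    hypoxemia_phase = list(turning_point_s = 240, duration_s = 120,
                           depth_frac = 0.06, fall_tau_s = 60,
                           recover_tau_s = 120), seed = 3))
  expect_false(detect_long_hypoxemia(baseline_normalize(short$oxy))$detected)
  # boundary: programmed duration 10% either side of the floor flips detection
  for (cfg in list(c(1620, FALSE), c(1980, TRUE))) {
    bb <- gen_trace_bundle(sd_event_profile(
      hypoxemia_phase = list(turning_point_s = 240, duration_s = cfg[1],
                             depth_frac = 0.06, fall_tau_s = 60,
                             recover_tau_s = 120), seed = 9),
      duration_s = list(ratio = 3600, eeg = 900, dc = 600))
    expect_identical(
      detect_long_hypoxemia(baseline_normalize(bb$oxy))$detected,
      as.logical(cfg[2]))
  }
})

test_that("heme-reduction detector recovers onset and duration under noise", {
  b <- gen_trace_bundle(sd_event_profile(seed = 6))
  res <- detect_heme_reduction(baseline_normalize(b$heme))
  expect_true(res$detected)
  expect_equal(res$onset_s, 90, tolerance = 10)
  expect_equal(res$duration_s, 180, tolerance = 20)
  # no dip -> not detected
  flat <- gen_trace_bundle(sd_event_profile(
    heme_dip = list(onset_s = 90, duration_s = 180, depth_frac = 0),
    seed = 6))
  expect_false(detect_heme_reduction(baseline_normalize(flat$heme))$detected)
  # noise up to 20% of the dip depth
  for (s in 1:3) {
    bb <- gen_trace_bundle(sd_event_profile(
      noise_sd = list(ratio = 0.01, dc_mV = 0.05), seed = s))
    r <- detect_heme_reduction(baseline_normalize(bb$heme))
    expect_true(r$detected)
    expect_equal(r$onset_s, 90, tolerance = 10)
    expect_equal(r$duration_s, 180, tolerance = 20)
  }
  # reversed-polarity recordings are handled by the convention flag
  rev <- optical_trace(b$heme$time_s, 2 - b$heme$value)
  rr <- detect_heme_reduction(baseline_normalize(rev),
                              decrease_means_reduction = FALSE)
  expect_true(rr$detected)
  expect_equal(rr$onset_s, 90, tolerance = 10)
})

test_that("detector booleans are monotone in their thresholds", {
  b <- gen_trace_bundle(sd_event_profile(seed = 10))
  r805 <- baseline_normalize(b$r805)
  oxy <- baseline_normalize(b$oxy)
  heme <- baseline_normalize(b$heme)
  flips_ok <- function(flags) {
    # once FALSE, never TRUE again as the threshold rises
    all(diff(as.integer(flags)) <= 0)
  }
  expect_true(flips_ok(vapply(c(0.01, 0.05, 0.1, 0.25, 0.5), function(th)
    detect_scattering_event(r805, threshold_frac = th)$detected, logical(1))))
  expect_true(flips_ok(vapply(c(0.01, 0.03, 0.05, 0.08, 0.2), function(th)
    detect_long_hypoxemia(oxy, depth_frac = th)$detected, logical(1))))
  expect_true(flips_ok(vapply(c(0.01, 0.02, 0.04, 0.06, 0.2), function(th)
    detect_heme_reduction(heme, threshold_frac = th)$detected, logical(1))))
  expect_true(flips_ok(vapply(c(0.9, 0.5, 0.3, 0.1, 0.02), function(dr)
    detect_eeg_suppression(b$eeg, 100, drop_frac = dr)$detected, logical(1))))
})

test_that("classification assembles the four detector booleans", {
  full <- gen_trace_bundle(sd_event_profile(seed = 21))
  traces <- list(r805 = baseline_normalize(full$r805), eeg = full$eeg,
                 oxy = baseline_normalize(full$oxy),
                 heme = baseline_normalize(full$heme))
  row <- classify_recording(traces, rat_id = 5, fluence_J_cm2 = 1.0)
  expect_true(all(unlist(
    row[c("scattering_change", "eeg_suppression", "long_hypoxemia",
          "heme_reduction")])))
  # non-responder: all amplitudes zero
  flatp <- sd_event_profile(
    scattering_event = list(onset_s = 5, duration_s = 240,
                            amplitude_frac = 0, polarity = 1),
    hyperemia_phase = list(depth_frac = 0, onset_s = 10, rise_tau_s = 30),
    hypoxemia_phase = list(turning_point_s = 240, duration_s = 5400,
                           depth_frac = 0, fall_tau_s = 60,
                           recover_tau_s = 120),
    heme_dip = list(onset_s = 90, duration_s = 180, depth_frac = 0),
    eeg_suppression = list(onset_s = 10, duration_s = 420, depth_frac = 0,
                           amplitude_uV = 50),
    dc_shift = list(onset_s = 120, fall_s = 30, amplitude_mV = 0,
                    partial_recovery_frac = 0.5),
    seed = 22)
  flat <- gen_trace_bundle(flatp)
  row0 <- classify_recording(list(
    r805 = baseline_normalize(flat$r805), eeg = flat$eeg,
    oxy = baseline_normalize(flat$oxy),
    heme = baseline_normalize(flat$heme)))
  expect_false(any(unlist(
    row0[c("scattering_change", "eeg_suppression", "long_hypoxemia",
           "heme_reduction")])))
  # scattering + EEG only (the SD-without-sequelae phenotype)
  sdonly <- gen_trace_bundle(sd_event_profile(
    hypoxemia_phase = list(turning_point_s = 240, duration_s = 0,
                           depth_frac = 0, fall_tau_s = 60,
                           recover_tau_s = 120),
    heme_dip = list(onset_s = 90, duration_s = 180, depth_frac = 0),
    seed = 23))
  row2 <- classify_recording(list(
    r805 = baseline_normalize(sdonly$r805), eeg = sdonly$eeg,
    oxy = baseline_normalize(sdonly$oxy),
    heme = baseline_normalize(sdonly$heme)))
  expect_identical(unname(unlist(
    row2[c("scattering_change", "eeg_suppression", "long_hypoxemia",
           "heme_reduction")])), c(TRUE, TRUE, FALSE, FALSE))
  # missing modality is an explicit NA, never a silent FALSE
  row3 <- classify_recording(traces[c("r805", "eeg")])
  expect_true(is.na(row3$long_hypoxemia) && is.na(row3$heme_reduction))
  expect_true(row3$scattering_change)
})
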