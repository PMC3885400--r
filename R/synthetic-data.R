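# Generators emulating every input modality of the analysis: band-ratio
# traces with spreading-depolarization event morphology, EEG and DC-potential
# traces, forward-model reflectance spectrum series, radially expanding
# scattering-wave image stacks, multichannel oxygenation traces and cohort
# event tables. Trace templates are piecewise cubic-smoothed steps (not raw
# steps) so that crossing/turning-point interpolation is genuinely exercised.
# All generators are deterministic under a fixed seed. Generated signals are
# on the normalized scale (baseline 1 for ratio bands) because the instrument
# absolute reflectance scale is not part of the analysis.

# smoothed box window: 0 outside [t0, t1], 1 inside, cubic edges of width tau
soft_box <- function(t, t0, t1, tau = 10) {
  soft_step(t, t0, tau) * (1 - soft_step(t, t1 - tau, tau))
}

# start time of a cubic transition of length tau so that the deviation
# (from +d_up to -d_down) crosses zero exactly at t_cross
transition_start <- function(t_cross, tau, d_up, d_down) {
  q <- d_up / (d_up + d_down)
  xq <- stats::uniroot(function(x) x^2 * (3 - 2 * x) - q, c(0, 1),
                       tol = 1e-12)$root
  t_cross - xq * tau
}

#' Spreading-depolarization event profile
#'
#' Programmed ("ground truth") parameters for one animal's synthetic
#' recording. The defaults transcribe the canonical single-event morphology:
#' a vigorous ~4 min scattering transient, ~7 min EEG suppression, hyperemia /
#' hyperoxemia turning to oligemia / hypoxemia at ~4 min, ~1.5 h hypoxemia, a
#' heme aa3 dip from ~1.5 min lasting ~3 min, and a ~7.2 mV negative DC shift
#' starting at ~2 min with a ~30 s fall and partial recovery.
#'
#' @param scattering_event list `onset_s`, `duration_s`, `amplitude_frac`,
#'   `polarity` (+1 bright-first, -1 dark-first).
#' @param hyperemia_phase list `depth_frac` (also the hyperoxemia rise
#'   amplitude), `onset_s`, `rise_tau_s`.
#' @param hypoxemia_phase list `turning_point_s`, `duration_s`, `depth_frac`,
#'   `fall_tau_s`, `recover_tau_s`.
#' @param heme_dip list `onset_s`, `duration_s`, `depth_frac`.
#' @param eeg_suppression list `onset_s`, `duration_s`, `depth_frac`
#'   (fractional amplitude drop), `amplitude_uV`.
#' @param dc_shift list `onset_s`, `fall_s`, `amplitude_mV`,
#'   `partial_recovery_frac`.
#' @param noise_sd list of per-modality noise SDs: `ratio` (additive, on the
#'   normalized scale), `dc_mV`.
#' @param seed integer seed.
#' @return an `sd_event_profile`.
#' @export
sd_event_profile <- function(
    scattering_event = list(onset_s = 5, duration_s = 240,
                            amplitude_frac = 0.2, polarity = 1),
    hyperemia_phase = list(depth_frac = 0.05, onset_s = 10, rise_tau_s = 30),
    hypoxemia_phase = list(turning_point_s = 240, duration_s = 5400,
                           depth_frac = 0.06, fall_tau_s = 60,
                           recover_tau_s = 120),
    heme_dip = list(onset_s = 90, duration_s = 180, depth_frac = 0.05),
    eeg_suppression = list(onset_s = 10, duration_s = 420, depth_frac = 0.8,
                           amplitude_uV = 50),
    dc_shift = list(onset_s = 120, fall_s = 30, amplitude_mV = 7.2,
                    partial_recovery_frac = 0.5),
    noise_sd = list(ratio = 0.005, dc_mV = 0.05),
    seed = 1) {
  prof <- list(scattering_event = scattering_event,
               hyperemia_phase = hyperemia_phase,
               hypoxemia_phase = hypoxemia_phase,
               heme_dip = heme_dip,
               eeg_suppression = eeg_suppression,
               dc_shift = dc_shift,
               noise_sd = noise_sd, seed = seed)
  durs <- c(scattering_event$duration_s, hypoxemia_phase$duration_s,
            heme_dip$duration_s, eeg_suppression$duration_s)
  if (any(durs < 0)) stop("durations must be non-negative")
  depths <- c(scattering_event$amplitude_frac, hyperemia_phase$depth_frac,
              hypoxemia_phase$depth_frac, heme_dip$depth_frac,
              eeg_suppression$depth_frac)
  if (any(depths < 0 | depths > 1))
    stop("fractional depths/amplitudes must lie in [0, 1]")
  if (dc_shift$amplitude_mV < 0) stop("DC amplitude must be non-negative")
  structure(prof, class = "sd_event_profile")
}

# oxygenation-type deviation: rise to +d_up, fall through baseline exactly at
# t_turn, plateau at -d_down for `duration`, then recover to baseline
oxy_deviation <- function(t, onset, rise_tau, d_up, t_turn, fall_tau,
                          d_down, duration, recover_tau) {
  if (d_up + d_down == 0) return(rep(0, length(t)))
  t_fall <- transition_start(t_turn, fall_tau, d_up, d_down)
  d_up * soft_step(t, onset, rise_tau) -
    (d_up + d_down) * soft_step(t, t_fall, fall_tau) +
    d_down * soft_step(t, t_turn + duration, recover_tau)
}

#' Generate the single-animal trace bundle
#'
#' Produces the six time-aligned channels of one recording, honoring the
#' study's sign conventions: during the hyperemic phase the blood-volume band
#' R569 *decreases* (more total hemoglobin absorbs more at the isosbestic
#' wavelength) while the oxygenation ratio R578/R569 *increases*
#' (hyperoxemia); after the turning point both reverse into long-lasting
#' oligemia/hypoxemia. The heme ratio R605/R620 dips during mitochondrial
#' impairment; R805 shows the vigorous bipolar scattering transient; the EEG
#' amplitude is suppressed; the DC potential shows the negative
#' depolarization shift.
#'
#' @param profile an [sd_event_profile()].
#' @param fs_hz named list of per-modality sampling rates: `ratio`, `eeg`,
#'   `dc`.
#' @param pre_s seconds of pre-stimulus baseline.
#' @param duration_s named list of post-stimulus durations: `ratio`, `eeg`,
#'   `dc` (the ratio channels must outlast the hypoxemia plateau).
#' @return named list of [optical_trace()] objects: `r805`, `r569`, `oxy`
#'   (R578/R569), `heme` (R605/R620), `eeg` (uV), `dc` (mV); the profile is
#'   attached as attribute `truth`.
#' @export
gen_trace_bundle <- function(profile = sd_event_profile(),
                             fs_hz = list(ratio = 1, eeg = 100, dc = 10),
                             pre_s = 120,
                             duration_s = list(ratio = 7200, eeg = 900,
                                               dc = 600)) {
  stopifnot(inherits(profile, "sd_event_profile"))
  with_seed(profile$seed, {
    tr <- seq(-pre_s, duration_s$ratio, by = 1 / fs_hz$ratio)
    ns <- profile$noise_sd
    sc <- profile$scattering_event
    hyp <- profile$hypoxemia_phase
    her <- profile$hyperemia_phase
    hd <- profile$heme_dip

    # R805: bipolar oscillation under a smooth envelope
    env <- soft_box(tr, sc$onset_s, sc$onset_s + sc$duration_s, 5)
    osc <- sin(2 * pi * (tr - sc$onset_s) /
                 max(sc$duration_s / 2, .Machine$double.eps))
    r805 <- 1 + sc$polarity * sc$amplitude_frac * env * osc +
      stats::rnorm(length(tr), 0, ns$ratio)

    # R578/R569 oxygenation: hyperoxemia then hypoxemia
    oxy <- 1 + oxy_deviation(tr, her$onset_s, her$rise_tau_s, her$depth_frac,
                             hyp$turning_point_s, hyp$fall_tau_s,
                             hyp$depth_frac, hyp$duration_s,
                             hyp$recover_tau_s) +
      stats::rnorm(length(tr), 0, ns$ratio)

    # R569 blood volume: mirrored polarity (hyperemia = decreased R569)
    r569 <- 1 - oxy_deviation(tr, her$onset_s, her$rise_tau_s, her$depth_frac,
                              hyp$turning_point_s, hyp$fall_tau_s,
                              hyp$depth_frac, hyp$duration_s,
                              hyp$recover_tau_s) +
      stats::rnorm(length(tr), 0, ns$ratio)

    # R605/R620 heme dip
    heme <- 1 - hd$depth_frac * soft_box(tr, hd$onset_s,
                                         hd$onset_s + hd$duration_s, 10) +
      stats::rnorm(length(tr), 0, ns$ratio)

    # EEG: stationary noise with an amplitude-suppression epoch
    es <- profile$eeg_suppression
    te <- seq(-pre_s, duration_s$eeg, by = 1 / fs_hz$eeg)
    gain <- 1 - es$depth_frac * soft_box(te, es$onset_s,
                                         es$onset_s + es$duration_s, 10)
    eeg <- stats::rnorm(length(te), 0, es$amplitude_uV) * gain

    # DC potential: artifact bump, steep negative shift, partial recovery,
    # second decline to a sustained low level
    dcp <- profile$dc_shift
    td <- seq(-pre_s, duration_s$dc, by = 1 / fs_hz$dc)
    t_low <- dcp$onset_s + dcp$fall_s        # reaches the minimum
    t_rec <- t_low + 20                       # hold, then partial recovery
    t_dec2 <- t_rec + 150                     # second decline
    dc <- 1.5 * soft_box(td, -1, 4, 2) -
      dcp$amplitude_mV * soft_step(td, dcp$onset_s, dcp$fall_s) +
      dcp$amplitude_mV * dcp$partial_recovery_frac *
        soft_step(td, t_rec, 120) -
      dcp$amplitude_mV * dcp$partial_recovery_frac * 0.7 *
        soft_step(td, t_dec2, 120) +
      stats::rnorm(length(td), 0, ns$dc_mV)

    out <- list(r805 = optical_trace(tr, r805),
                r569 = optical_trace(tr, r569),
                oxy = optical_trace(tr, oxy),
                heme = optical_trace(tr, heme),
                eeg = optical_trace(te, eeg),
                dc = optical_trace(td, dc))
    attr(out, "truth") <- profile
    out
  })
}

#' Baseline-transient-hypoxemia hemoglobin trajectory
#'
#' Smooth `(C_HbO, C_HbR, a)` trajectory for the saturation time course:
#' baseline StO2 60% (0.06/0.04 mM), a transient rise to 70% (0.07/0.03)
#' shortly after the stimulus, then a sustained fall to the hypoxemic 35%
#' level (0.035/0.065) with a concurrent scattering-amplitude transient.
#'
#' @param times sample times, s (stimulus at 0).
#' @param baseline,transient,hypoxemic `c(C_HbO, C_HbR)` states, mM.
#' @param a scattering amplitude at baseline, 1/mm.
#' @return data frame `time_s`, `C_HbO`, `C_HbR`, `a`.
#' @export
sto2_trajectory <- function(times,
                            baseline = c(0.060, 0.040),
                            transient = c(0.070, 0.030),
                            hypoxemic = c(0.035, 0.065),
                            a = 2) {
  up <- soft_step(times, 30, 60) * (1 - soft_step(times, 240, 240))
  down <- soft_step(times, 240, 240)
  C_HbO <- baseline[1] + (transient[1] - baseline[1]) * up +
    (hypoxemic[1] - baseline[1]) * down
  C_HbR <- baseline[2] + (transient[2] - baseline[2]) * up +
    (hypoxemic[2] - baseline[2]) * down
  a_t <- a + 0.4 * soft_step(times, 0, 30) * (1 - soft_step(times, 120, 120))
  data.frame(time_s = times, C_HbO = C_HbO, C_HbR = C_HbR, a = a_t)
}

#' Generate a forward-modeled reflectance spectrum time series
#'
#' Each time point's spectrum is produced by the same forward-model family
#' used to build the conversion model (Monte Carlo reference or diffusion
#' fallback), with multiplicative Gaussian noise, for inversion round trips.
#'
#' @param trajectory data frame `time_s`, `C_HbO`, `C_HbR`, `a` (e.g. from
#'   [sto2_trajectory()]); must lie within `box`.
#' @param wavelengths nm.
#' @param fibers a [fiber_geometry()].
#' @param method `"diffusion"` or `"mc"`.
#' @param noise_sd multiplicative noise SD.
#' @param seed integer seed (drives both noise and MC).
#' @param n_photons MC photons per wavelength.
#' @param box a [conversion_grid()] delimiting the admissible parameter box.
#' @param table a [chromophore_table()].
#' @return a [spectrum_series()] with the trajectory attached as attribute
#'   `truth`.
#' @export
gen_forward_spectrum_series <- function(trajectory,
                                        wavelengths = seq(500, 620, 5),
                                        fibers = fiber_geometry(),
                                        method = c("diffusion", "mc"),
                                        noise_sd = 0.01, seed = 1,
                                        n_photons = 1e5,
                                        box = conversion_grid(),
                                        table = hemoglobin_extinction()) {
  method <- match.arg(method)
  inside <- function(v, lv) v >= min(lv) - 1e-12 & v <= max(lv) + 1e-12
  if (!all(inside(trajectory$C_HbO, box$C_HbO)) ||
      !all(inside(trajectory$C_HbR, box$C_HbR)) ||
      !all(inside(trajectory$a, box$a)))
    stop("trajectory leaves the conversion-model box")
  with_seed(seed, {
    refl <- vapply(seq_len(nrow(trajectory)), function(i) {
      sp <- forward_spectrum(trajectory$C_HbO[i], trajectory$C_HbR[i],
                             trajectory$a[i], wavelengths, fibers,
                             method = method, n_photons = n_photons,
                             seed = seed * 1000 + i, table = table)
      r <- sp$reflectance * (1 + stats::rnorm(length(wavelengths), 0,
                                              noise_sd))
      pmin(pmax(r, .Machine$double.xmin), 1)
    }, numeric(length(wavelengths)))
    out <- spectrum_series(wavelengths, trajectory$time_s, refl)
    attr(out, "truth") <- trajectory
    out
  })
}

#' Generate a radially expanding scattering-wave image stack
#'
#' Emulates the NIR difference-imaging experiment: a bright annulus expanding
#' from the application site at constant speed, trailed by a dark annulus, on
#' a constant background with Gaussian (CCD-like) noise, saturated to the
#' 8-bit range.
#'
#' @param speed_mm_per_min front speed.
#' @param origin_px `c(row, col)` application site.
#' @param pixel_pitch_mm pixel size.
#' @param frame_interval_s time between frames.
#' @param n_frames number of post-stimulus frames; the default keeps the
#'   front inside the field of view.
#' @param dim_px frame size `c(rows, cols)`.
#' @param bright_amp,dark_amp annulus amplitudes (8-bit counts).
#' @param ring_width_mm full width of the bright annulus.
#' @param background background level (counts).
#' @param noise_sd Gaussian noise SD (counts).
#' @param seed integer seed.
#' @return an [image_stack()] (first frame at t = 0 is the pre-wave
#'   reference) with the programmed speed in attribute `truth`.
#' @export
gen_wave_stack <- function(speed_mm_per_min = 2.4, origin_px = c(80, 80),
                           pixel_pitch_mm = 0.05, frame_interval_s = 5,
                           n_frames = NULL, dim_px = c(160, 160),
                           bright_amp = 60, dark_amp = 40,
                           ring_width_mm = 0.8, background = 120,
                           noise_sd = 2, seed = 1) {
  if (speed_mm_per_min <= 0) stop("speed must be positive")
  v <- speed_mm_per_min / 60 # mm/s
  edge_mm <- (min(origin_px[1] - 1, dim_px[1] - origin_px[1],
                  origin_px[2] - 1, dim_px[2] - origin_px[2])) *
    pixel_pitch_mm
  if (is.null(n_frames))
    n_frames <- max(4L, floor((edge_mm - 0.6) / v / frame_interval_s))
  with_seed(seed, {
    rows <- matrix(seq_len(dim_px[1]), dim_px[1], dim_px[2])
    cols <- matrix(seq_len(dim_px[2]), dim_px[1], dim_px[2], byrow = TRUE)
    dmm <- sqrt((rows - origin_px[1])^2 + (cols - origin_px[2])^2) *
      pixel_pitch_mm
    sig <- ring_width_mm / 2
    times <- seq(0, by = frame_interval_s, length.out = n_frames + 1)
    frames <- array(0, dim = c(n_frames + 1, dim_px[1], dim_px[2]))
    for (i in seq_along(times)) {
      t <- times[i]
      f <- matrix(background, dim_px[1], dim_px[2])
      r <- v * t
      if (r > 0) {
        f <- f + bright_amp * exp(-((dmm - r) / sig)^2)
        r_dark <- r - 1.5 * ring_width_mm
        if (r_dark > 0)
          f <- f - dark_amp * exp(-((dmm - r_dark) / sig)^2)
      }
      f <- f + stats::rnorm(length(f), 0, noise_sd)
      frames[i, , ] <- pmin(pmax(round(f), 0), 255)
    }
    out <- image_stack(frames, times, pixel_pitch_mm, origin_px)
    attr(out, "truth") <- list(speed_mm_per_min = speed_mm_per_min)
    out
  })
}

#' Generate multichannel oxygenation traces with distance-ordered onsets
#'
#' Each channel carries the oxygenation template (hyperoxemia rise, turning
#' point, hypoxemia plateau) delayed by its distance from the application
#' site divided by the programmed expansion speed, so the distance-versus-
#' turning-time regression slope equals the speed.
#'
#' @param speed_mm_per_min expansion speed.
#' @param distances_mm increasing positive channel distances.
#' @param turning_lag_s local lag from wave arrival to the turning point.
#' @param rise_depth,dip_depth template amplitudes.
#' @param fs_hz sampling rate.
#' @param duration_s post-stimulus duration.
#' @param noise_sd additive noise SD.
#' @param seed integer seed.
#' @return list of [optical_trace()] per channel, truth (speed and programmed
#'   turning times) in attribute `truth`.
#' @export
gen_multichannel <- function(speed_mm_per_min = 2.6,
                             distances_mm = c(2.0, 4.5, 7.0),
                             turning_lag_s = 134, rise_depth = 0.05,
                             dip_depth = 0.06, fs_hz = 1, duration_s = 900,
                             noise_sd = 0.005, seed = 1) {
  if (any(distances_mm <= 0) || any(diff(distances_mm) <= 0))
    stop("distances must be positive and increasing")
  v <- speed_mm_per_min / 60
  with_seed(seed, {
    t <- seq(-120, duration_s, by = 1 / fs_hz)
    turning <- distances_mm / v + turning_lag_s
    traces <- lapply(seq_along(distances_mm), function(i) {
      arrival <- distances_mm[i] / v
      dev <- oxy_deviation(t, onset = arrival + 10, rise_tau = 30,
                           d_up = rise_depth, t_turn = turning[i],
                           fall_tau = 60, d_down = dip_depth,
                           duration = duration_s, recover_tau = 120)
      optical_trace(t, 1 + dev + stats::rnorm(length(t), 0, noise_sd))
    })
    names(traces) <- paste0("ch", seq_along(distances_mm))
    attr(traces, "truth") <- list(speed_mm_per_min = speed_mm_per_min,
                                  turning_s = turning,
                                  distances_mm = distances_mm)
    traces
  })
}

#' Generate a synthetic cohort event table
#'
#' Bernoulli draws honoring the conditional structure of the observations:
#' hypoxemia and heme reduction occur only among animals showing spreading
#' depression (scattering change plus EEG suppression), with the given
#' conditional probabilities.
#'
#' @param n_per_fluence animals per fluence level.
#' @param fluences fluence levels, J/cm2.
#' @param p_sd probability of SD at each fluence (recycled).
#' @param p_hypoxemia_given_sd,p_heme_given_sd conditional probabilities.
#' @param seed integer seed.
#' @return an [event_table()].
#' @export
gen_cohort <- function(n_per_fluence = 6,
                       fluences = c(0.75, 1.0, 1.25, 1.5),
                       p_sd = c(0.4, 0.75, 1.0, 1.0),
                       p_hypoxemia_given_sd = 15 / 18,
                       p_heme_given_sd = 14 / 18, seed = 1) {
  p <- c(p_sd, p_hypoxemia_given_sd, p_heme_given_sd)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  p_sd <- rep_len(p_sd, length(fluences))
  with_seed(seed, {
    rows <- do.call(rbind, lapply(seq_along(fluences), function(i) {
      if (n_per_fluence == 0) return(NULL)
      sd_pos <- stats::runif(n_per_fluence) < p_sd[i]
      data.frame(rat_id = seq_len(n_per_fluence),
                 fluence_J_cm2 = fluences[i],
                 scattering_change = sd_pos,
                 eeg_suppression = sd_pos,
                 long_hypoxemia = sd_pos &
                   stats::runif(n_per_fluence) < p_hypoxemia_given_sd,
                 heme_reduction = sd_pos &
                   stats::runif(n_per_fluence) < p_heme_given_sd)
    }))
    if (is.null(rows))
      rows <- data.frame(rat_id = integer(), fluence_J_cm2 = numeric(),
                         scattering_change = logical(),
                         eeg_suppression = logical(),
                         long_hypoxemia = logical(),
                         heme_reduction = logical())
    event_table(rows)
  })
}
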