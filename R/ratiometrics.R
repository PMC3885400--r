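#' Physiological time-series trace
#'
#' A single-channel trace (reflectance ratio, EEG in uV, DC potential in mV)
#' with the stimulus (shock-wave application) time; by convention the stimulus
#' is at `t = 0`.
#'
#' @param time_s strictly increasing sample times, seconds.
#' @param value signal values.
#' @param stimulus_time_s stimulus time, within the sampled range.
#' @return an `optical_trace` (data frame `time_s`, `value` with a
#'   `stimulus_time_s` attribute).
#' @export
optical_trace <- function(time_s, value, stimulus_time_s = 0) {
  if (length(time_s) != length(value))
    stop("time_s and value must have equal length")
  if (any(diff(time_s) <= 0))
    stop("time must be strictly increasing")
  if (stimulus_time_s < time_s[1] || stimulus_time_s > time_s[length(time_s)])
    stop("stimulus_time_s must lie within the sampled time range")
  structure(data.frame(time_s = time_s, value = value),
            stimulus_time_s = stimulus_time_s,
            class = c("optical_trace", "data.frame"))
}

stimulus_time <- function(trace) attr(trace, "stimulus_time_s")

#' @export
plot.optical_trace <- function(x, ...) {
  graphics::plot(x$time_s, x$value, type = "l", xlab = "time (s)",
                 ylab = "value", ...)
  graphics::abline(v = stimulus_time(x), lty = 2)
  invisible(x)
}

#' Normalize a trace by its pre-stimulus baseline
#'
#' Divides the signal by the mean over a window lying wholly before the
#' stimulus, so the baseline maps to 1. Detectors operate on normalized
#' traces, which makes them invariant to positive rescaling of the raw
#' signal.
#'
#' @param trace an [optical_trace()].
#' @param baseline_window_s `c(from, to)` in seconds; must end at or before
#'   the stimulus and contain at least 5 samples.
#' @return the normalized `optical_trace`.
#' @export
baseline_normalize <- function(trace, baseline_window_s = c(-Inf, 0)) {
  stopifnot(inherits(trace, "optical_trace"))
  t0 <- stimulus_time(trace)
  if (baseline_window_s[2] > t0)
    stop("baseline window must lie wholly before the stimulus")
  sel <- trace$time_s >= baseline_window_s[1] &
    trace$time_s <= baseline_window_s[2]
  if (sum(sel) < 5)
    stop("baseline window must contain at least 5 pre-stimulus samples")
  m <- mean(trace$value[sel])
  if (m == 0) stop("baseline mean is zero; cannot normalize")
  optical_trace(trace$time_s, trace$value / m, t0)
}

#' Reflectance spectrum time series
#'
#' @param wavelengths strictly increasing wavelengths, nm.
#' @param time_s strictly increasing sample times, seconds.
#' @param reflectance matrix `length(wavelengths) x length(time_s)`, values in
#'   (0, 1].
#' @param stimulus_time_s stimulus time.
#' @return a `spectrum_series`.
#' @export
spectrum_series <- function(wavelengths, time_s, reflectance,
                            stimulus_time_s = 0) {
  reflectance <- as.matrix(reflectance)
  if (nrow(reflectance) != length(wavelengths) ||
      ncol(reflectance) != length(time_s))
    stop("reflectance must be a wavelength x time matrix")
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be increasing")
  if (any(diff(time_s) <= 0)) stop("time must be increasing")
  if (any(reflectance <= 0)) stop("reflectance must be positive")
  structure(list(wavelengths = wavelengths, time_s = time_s,
                 reflectance = reflectance,
                 stimulus_time_s = stimulus_time_s),
            class = "spectrum_series")
}

#' Band or band-ratio trace from a spectrum time series
#'
#' Nearest-node lookup (tolerance 2 nm) of one or two wavelength bands. With a
#' denominator the pointwise ratio trace is returned (e.g. R578/R569 for
#' hemoglobin oxygenation, R605/R620 for heme aa3); without one, the
#' single-band trace (e.g. R805 scattering, R569 blood volume).
#'
#' @param series a [spectrum_series()].
#' @param numerator_nm band wavelength, nm.
#' @param denominator_nm optional normalizing band, nm.
#' @param tolerance_nm nearest-node lookup tolerance.
#' @return an [optical_trace()].
#' @export
band_ratio <- function(series, numerator_nm, denominator_nm = NULL,
                       tolerance_nm = 2) {
  stopifnot(inherits(series, "spectrum_series"))
  lookup <- function(nm) {
    i <- which.min(abs(series$wavelengths - nm))
    if (abs(series$wavelengths[i] - nm) > tolerance_nm)
      stop(sprintf("no wavelength within %g nm of %g nm in the series",
                   tolerance_nm, nm))
    i
  }
  num <- series$reflectance[lookup(numerator_nm), ]
  v <- if (is.null(denominator_nm)) num
       else num / series$reflectance[lookup(denominator_nm), ]
  optical_trace(series$time_s, v, series$stimulus_time_s)
}

post_stimulus <- function(trace) {
  t0 <- stimulus_time(trace)
  trace[trace$time_s > t0, , drop = FALSE]
}

#' Turning point of a normalized trace
#'
#' Time of the first crossing of the baseline level (1.0) after the
#' post-stimulus extremum of the initial deflection, located by linear
#' interpolation between the bracketing samples; ties break toward the
#' earlier time. The initial-deflection polarity is the sign of the deviation
#' when it first reaches a tenth of the largest post-stimulus excursion, so a
#' hyperoxemic rise followed by a deeper hypoxemic plateau turns at the end
#' of the rise, not at the late recovery. This is the hyperoxemia-to-
#' hypoxemia (or hyperemia-to-oligemia) turning point marked by the dashed
#' lines in the band-signal figures.
#'
#' @param trace a baseline-normalized [optical_trace()], stimulus at `t = 0`.
#' @return crossing time in seconds, or `NA` if the trace never re-crosses
#'   baseline (none detected).
#' @export
detect_turning_point <- function(trace) {
  stopifnot(inherits(trace, "optical_trace"))
  post <- post_stimulus(trace)
  if (nrow(post) < 2) return(NA_real_)
  dev <- post$value - 1
  m <- max(abs(dev))
  if (m == 0) return(NA_real_)
  pre <- trace$value[trace$time_s <= stimulus_time(trace)] - 1
  nsd <- if (length(pre) > 2) stats::sd(pre) else 0
  eps <- max(0.1 * m, 5 * nsd) # the initial deflection must clear the noise
  i1 <- which(abs(dev) >= eps)[1]
  if (is.na(i1)) return(NA_real_)
  s <- sign(dev[i1])
  sdev <- s * dev
  i_ext <- which.max(sdev) # first index of the maximum (earlier-time ties)
  if (i_ext >= nrow(post)) return(NA_real_)
  for (i in seq(i_ext, nrow(post) - 1)) {
    if (sdev[i] >= 0 && sdev[i + 1] < 0) {
      # linear interpolation to the exact crossing of 1.0
      frac <- sdev[i] / (sdev[i] - sdev[i + 1])
      return(post$time_s[i] + frac * (post$time_s[i + 1] - post$time_s[i]))
    }
  }
  NA_real_
}

#' Detect a drastic scattering transient
#'
#' A scattering event is flagged when the normalized scattering band (R805)
#' deviates from baseline by more than `threshold_frac` within the first
#' `post_window_s` seconds after the stimulus. The event duration is the span
#' between the first and last threshold exceedance. Detection is polarity
#' blind (bright-first and dark-first waves score identically).
#'
#' @param r805 a normalized [optical_trace()].
#' @param threshold_frac deviation threshold as a fraction of baseline.
#' @param min_duration_s minimum exceedance span to count as detected.
#' @param post_window_s window after the stimulus inside which the event must
#'   start.
#' @return list `detected`, `duration_s`.
#' @export
detect_scattering_event <- function(r805, threshold_frac = 0.05,
                                    min_duration_s = 0, post_window_s = 300) {
  stopifnot(inherits(r805, "optical_trace"))
  post <- post_stimulus(r805)
  exceed <- abs(post$value - 1) > threshold_frac
  if (!any(exceed))
    return(list(detected = FALSE, duration_s = 0))
  t_ex <- post$time_s[exceed]
  t0 <- stimulus_time(r805)
  starts_in_window <- (t_ex[1] - t0) <= post_window_s
  duration <- t_ex[length(t_ex)] - t_ex[1]
  list(detected = starts_in_window && duration >= min_duration_s,
       duration_s = duration)
}

#' Detect EEG suppression
#'
#' Sliding-window RMS envelope of a uniformly sampled EEG trace; a suppression
#' epoch is a contiguous stretch where the envelope drops below `drop_frac`
#' times the pre-stimulus RMS for at least `min_duration_s`. The longest such
#' epoch is returned.
#'
#' @param eeg an [optical_trace()] sampled uniformly at `fs_hz`.
#' @param fs_hz sampling rate, Hz.
#' @param rms_window_s RMS window length, seconds.
#' @param drop_frac envelope threshold as a fraction of the baseline RMS.
#' @param min_duration_s minimum epoch duration, seconds.
#' @return list `detected`, `onset_s`, `duration_s`.
#' @export
detect_eeg_suppression <- function(eeg, fs_hz, rms_window_s = 10,
                                   drop_frac = 0.5, min_duration_s = 60) {
  stopifnot(inherits(eeg, "optical_trace"))
  n_win <- max(3L, as.integer(round(rms_window_s * fs_hz)))
  if (nrow(eeg) < n_win)
    stop("trace shorter than the RMS window")
  t0 <- stimulus_time(eeg)
  v <- eeg$value - mean(eeg$value[eeg$time_s <= t0])
  env <- sqrt(stats::filter(v^2, rep(1 / n_win, n_win), sides = 2))
  ok <- !is.na(env)
  pre <- ok & eeg$time_s <= t0
  if (!any(pre)) stop("no pre-stimulus samples to form a baseline RMS")
  rms0 <- sqrt(mean(env[pre]^2))
  low <- ok & eeg$time_s > t0 & env < drop_frac * rms0
  runs <- logical_runs(as.vector(low))
  if (!nrow(runs))
    return(list(detected = FALSE, onset_s = NA_real_, duration_s = 0))
  runs$dur <- eeg$time_s[runs$end] - eeg$time_s[runs$start]
  best <- runs[which.max(runs$dur), ]
  detected <- best$dur >= min_duration_s
  list(detected = detected,
       onset_s = if (detected) eeg$time_s[best$start] else NA_real_,
       duration_s = if (detected) best$dur else 0)
}

#' Characterize the negative DC potential shift
#'
#' The trace is smoothed with a moving average of length `smoothing_s`; the
#' stimulus artifact region (t in [-5, 5] s) is excluded. The shift is the
#' pre-stimulus mean minus the post-stimulus minimum of the smoothed trace
#' (positive for a negative deflection); the onset is the first time the
#' smoothed trace falls 3 pre-stimulus noise SDs below baseline and stays
#' there for at least two smoothing windows (the persistence requirement
#' keeps smoothed-noise excursions from registering as depolarizations).
#'
#' @param dc an [optical_trace()] in mV.
#' @param smoothing_s moving-average length, seconds.
#' @param artifact_s half-width of the excluded stimulus-artifact region.
#' @return list `max_negative_shift_mV`, `onset_s`, `time_to_min_s`.
#' @export
detect_dc_shift <- function(dc, smoothing_s = 5, artifact_s = 5) {
  stopifnot(inherits(dc, "optical_trace"))
  t0 <- stimulus_time(dc)
  dt <- stats::median(diff(dc$time_s))
  n_win <- max(1L, as.integer(round(smoothing_s / dt)))
  sm <- stats::filter(dc$value, rep(1 / n_win, n_win), sides = 2)
  ok <- !is.na(sm)
  pre <- ok & dc$time_s < t0 - artifact_s
  post <- ok & dc$time_s > t0 + artifact_s
  if (!any(pre) || !any(post))
    stop("trace must extend beyond the artifact region on both sides")
  base <- mean(sm[pre])
  noise_sd <- stats::sd(sm[pre])
  i_min <- which(post)[which.min(sm[post])]
  shift <- base - sm[i_min]
  below <- post & sm < base - 3 * noise_sd
  runs <- logical_runs(as.vector(below))
  onset <- NA_real_
  if (nrow(runs)) {
    runs$dur <- dc$time_s[runs$end] - dc$time_s[runs$start]
    ok <- runs$dur >= 2 * smoothing_s
    if (any(ok)) onset <- dc$time_s[runs$start[which(ok)[1]]]
  }
  list(max_negative_shift_mV = as.numeric(shift),
       onset_s = onset,
       time_to_min_s = dc$time_s[i_min] - t0)
}

#' Detect long-lasting hypoxemia
#'
#' After the turning point of the normalized oxygenation trace, hypoxemia is
#' flagged when the signal stays below `1 - depth_frac` continuously for at
#' least `min_duration_s`. The default floor of 1800 s is half the "more than
#' one hour in many cases" scale of the phenomenon.
#'
#' @param oxy a normalized oxygenation-ratio [optical_trace()].
#' @param min_duration_s minimum continuous duration, seconds.
#' @param depth_frac depth below baseline defining hypoxemia.
#' @return list `detected`, `duration_s` (longest qualifying epoch).
#' @export
detect_long_hypoxemia <- function(oxy, min_duration_s = 1800,
                                  depth_frac = 0.03) {
  stopifnot(inherits(oxy, "optical_trace"))
  tp <- detect_turning_point(oxy)
  if (is.na(tp)) return(list(detected = FALSE, duration_s = 0))
  seg <- oxy[oxy$time_s >= tp, , drop = FALSE]
  low <- seg$value < 1 - depth_frac
  runs <- logical_runs(low)
  if (!nrow(runs)) return(list(detected = FALSE, duration_s = 0))
  runs$dur <- seg$time_s[runs$end] - seg$time_s[runs$start]
  dur <- max(runs$dur)
  list(detected = dur >= min_duration_s, duration_s = dur)
}

#' Detect heme aa3 reduction
#'
#' A reduction event is a contiguous epoch, starting within `window_s` after
#' the stimulus, where the normalized heme ratio (R605/R620 by the default
#' polarity convention: a decrease of the ratio indicates reduction) falls
#' below `1 - threshold_frac`.
#'
#' @param ratio a normalized heme-ratio [optical_trace()].
#' @param threshold_frac depth threshold.
#' @param window_s post-stimulus window inside which the epoch must begin.
#' @param min_duration_s minimum epoch duration to count as detected.
#' @param decrease_means_reduction polarity convention flag; if `FALSE` the
#'   trace is mirrored about baseline before detection (for data recorded as
#'   R620/R605).
#' @return list `detected`, `onset_s`, `duration_s`.
#' @export
detect_heme_reduction <- function(ratio, threshold_frac = 0.02,
                                  window_s = 600, min_duration_s = 30,
                                  decrease_means_reduction = TRUE) {
  stopifnot(inherits(ratio, "optical_trace"))
  post <- post_stimulus(ratio)
  v <- if (decrease_means_reduction) post$value else 2 - post$value
  low <- v < 1 - threshold_frac
  runs <- logical_runs(low)
  t0 <- stimulus_time(ratio)
  if (nrow(runs)) {
    runs$onset <- post$time_s[runs$start] - t0
    runs$dur <- post$time_s[runs$end] - post$time_s[runs$start]
    runs <- runs[runs$onset <= window_s & runs$dur >= min_duration_s, ,
                 drop = FALSE]
  }
  if (!nrow(runs))
    return(list(detected = FALSE, onset_s = NA_real_, duration_s = 0))
  best <- runs[which.max(runs$dur), ]
  list(detected = TRUE, onset_s = best$onset, duration_s = best$dur)
}

#' Detector configuration
#'
#' Default thresholds for the four event detectors used in cohort
#' classification. All are overridable; the defaults make the programmed
#' events of the synthetic generator detectable while flat noisy traces are
#' not.
#'
#' @param scattering_threshold,scattering_window_s scattering-event detector.
#' @param eeg_fs_hz,eeg_rms_window_s,eeg_drop_frac,eeg_min_duration_s EEG
#'   suppression detector.
#' @param hypoxemia_depth,hypoxemia_min_duration_s hypoxemia detector.
#' @param heme_threshold,heme_window_s,heme_min_duration_s heme detector.
#' @return a named list of class `detector_config`.
#' @export
detector_config <- function(scattering_threshold = 0.05,
                            scattering_window_s = 300,
                            eeg_fs_hz = 100, eeg_rms_window_s = 10,
                            eeg_drop_frac = 0.5, eeg_min_duration_s = 60,
                            hypoxemia_depth = 0.03,
                            hypoxemia_min_duration_s = 1800,
                            heme_threshold = 0.02, heme_window_s = 600,
                            heme_min_duration_s = 30) {
  structure(as.list(environment()), class = "detector_config")
}

#' Classify one animal's recording into an event row
#'
#' Runs the four detectors (scattering change, EEG suppression, long-lasting
#' hypoxemia, heme aa3 reduction) on time-aligned traces and assembles the
#' per-animal boolean row of the cohort event table. A missing modality
#' yields an explicit `NA`, never a silent `FALSE`.
#'
#' @param traces named list with (any of) elements `r805`, `eeg`, `oxy`,
#'   `heme`: [optical_trace()] objects aligned to a common stimulus. Ratio
#'   traces must be baseline-normalized.
#' @param rat_id,fluence_J_cm2 identifiers copied into the row.
#' @param config a [detector_config()].
#' @return one-row data frame (class `event_row`): `rat_id`, `fluence_J_cm2`,
#'   `scattering_change`, `eeg_suppression`, `long_hypoxemia`,
#'   `heme_reduction`.
#' @export
classify_recording <- function(traces, rat_id = NA, fluence_J_cm2 = NA,
                               config = detector_config()) {
  get_flag <- function(name, fun) {
    if (is.null(traces[[name]])) return(NA)
    fun(traces[[name]])$detected
  }
  row <- data.frame(
    rat_id = rat_id, fluence_J_cm2 = fluence_J_cm2,
    scattering_change = get_flag("r805", function(tr)
      detect_scattering_event(tr, config$scattering_threshold,
                              post_window_s = config$scattering_window_s)),
    eeg_suppression = get_flag("eeg", function(tr)
      detect_eeg_suppression(tr, config$eeg_fs_hz, config$eeg_rms_window_s,
                             config$eeg_drop_frac, config$eeg_min_duration_s)),
    long_hypoxemia = get_flag("oxy", function(tr)
      detect_long_hypoxemia(tr, config$hypoxemia_min_duration_s,
                            config$hypoxemia_depth)),
    heme_reduction = get_flag("heme", function(tr)
      detect_heme_reduction(tr, config$heme_threshold, config$heme_window_s,
                            config$heme_min_duration_s)))
  class(row) <- c("event_row", "data.frame")
  row
}
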