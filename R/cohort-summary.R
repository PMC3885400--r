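#' Cohort event table
#'
#' Per-animal boolean observations: drastic light-scattering change, EEG
#' suppression, long-lasting hypoxemia and heme aa3 reduction, with the
#' shock-wave fluence of each exposure.
#'
#' @param rows data frame with columns `rat_id`, `fluence_J_cm2`,
#'   `scattering_change`, `eeg_suppression`, `long_hypoxemia`,
#'   `heme_reduction`.
#' @return an `event_table`.
#' @export
event_table <- function(rows) {
  req <- c("rat_id", "fluence_J_cm2", "scattering_change", "eeg_suppression",
           "long_hypoxemia", "heme_reduction")
  miss <- setdiff(req, names(rows))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(rows)) {
    dup <- duplicated(rows[, c("fluence_J_cm2", "rat_id")])
    if (any(dup)) stop("rat_ids must be unique within a fluence group")
  }
  structure(as.data.frame(rows), class = c("event_table", "data.frame"))
}

#' Read an event table from CSV
#'
#' @param path CSV with the [event_table()] columns; booleans as TRUE/FALSE.
#' @return an `event_table`.
#' @export
read_event_table <- function(path) {
  event_table(utils::read.csv(path))
}

#' The 24-rat exposure cohort
#'
#' The packaged transcription of the study's summary table: 24 rats exposed
#' at fluences 0.75-1.5 J/cm2, with the four per-animal event marks.
#'
#' @return an `event_table` with 24 rows.
#' @export
#' @examples
#' tally_events(lisw_cohort())
lisw_cohort <- function() {
  read_event_table(system.file("extdata", "table1_events.csv",
                               package = "sdoptics", mustWork = TRUE))
}

#' Tally spreading-depression-related events in a cohort
#'
#' Spreading depression (SD) is operationalized as the conjunction of a
#' drastic scattering change and EEG suppression. Conditional counts of
#' long-lasting hypoxemia and heme aa3 reduction are taken among the
#' SD-positive animals; fractions are exact count ratios (formatted to one
#' decimal percent by the print method). Animals positive for hypoxemia or
#' heme reduction without SD are reported separately.
#'
#' @param table an [event_table()].
#' @param filter_fluence optional fluence (J/cm2) to restrict the tally to.
#' @return a `cohort_tally`: `n_total`, `n_sd`, `n_hypoxemia_given_sd`,
#'   `n_heme_given_sd`, `frac_hypoxemia_given_sd`, `frac_heme_given_sd`,
#'   `n_hypoxemia_without_sd`, `n_heme_without_sd`.
#' @export
tally_events <- function(table, filter_fluence = NULL) {
  stopifnot(inherits(table, "event_table"))
  if (!nrow(table)) stop("event table is empty")
  rows <- table
  if (!is.null(filter_fluence))
    rows <- rows[rows$fluence_J_cm2 == filter_fluence, , drop = FALSE]
  if (!nrow(rows)) {
    return(structure(list(n_total = 0L, n_sd = 0L,
                          n_hypoxemia_given_sd = 0L, n_heme_given_sd = 0L,
                          frac_hypoxemia_given_sd = NA_real_,
                          frac_heme_given_sd = NA_real_,
                          n_hypoxemia_without_sd = 0L,
                          n_heme_without_sd = 0L),
                     class = "cohort_tally"))
  }
  sd_pos <- rows$scattering_change & rows$eeg_suppression
  n_sd <- sum(sd_pos, na.rm = TRUE)
  n_hyp <- sum(rows$long_hypoxemia & sd_pos, na.rm = TRUE)
  n_heme <- sum(rows$heme_reduction & sd_pos, na.rm = TRUE)
  structure(list(
    n_total = nrow(rows), n_sd = n_sd,
    n_hypoxemia_given_sd = n_hyp, n_heme_given_sd = n_heme,
    frac_hypoxemia_given_sd = if (n_sd > 0) n_hyp / n_sd else NA_real_,
    frac_heme_given_sd = if (n_sd > 0) n_heme / n_sd else NA_real_,
    n_hypoxemia_without_sd = sum(rows$long_hypoxemia & !sd_pos, na.rm = TRUE),
    n_heme_without_sd = sum(rows$heme_reduction & !sd_pos, na.rm = TRUE)),
    class = "cohort_tally")
}

#' @export
print.cohort_tally <- function(x, ...) {
  pct <- function(f) if (is.na(f)) "undefined" else sprintf("%.1f%%", 100 * f)
  cat(sprintf("Animals: %d; SD (scattering change + EEG suppression): %d\n",
              x$n_total, x$n_sd))
  cat(sprintf("  long-lasting hypoxemia among SD: %d (%s)\n",
              x$n_hypoxemia_given_sd, pct(x$frac_hypoxemia_given_sd)))
  cat(sprintf("  heme aa3 reduction among SD:     %d (%s)\n",
              x$n_heme_given_sd, pct(x$frac_heme_given_sd)))
  if (x$n_hypoxemia_without_sd || x$n_heme_without_sd)
    cat(sprintf("  without SD: hypoxemia %d, heme %d\n",
                x$n_hypoxemia_without_sd, x$n_heme_without_sd))
  invisible(x)
}

#' Fluence calibration pairs
#'
#' Measured peak pressure and impulse of the laser-induced shock wave at each
#' laser fluence.
#'
#' @param fluence_J_cm2 positive laser fluences, J/cm2.
#' @param peak_pressure_MPa,impulse_Pa_s parallel measurement vectors.
#' @return a `calibration_pairs`.
#' @export
calibration_pairs <- function(fluence_J_cm2, peak_pressure_MPa, impulse_Pa_s) {
  if (length(fluence_J_cm2) != length(peak_pressure_MPa) ||
      length(fluence_J_cm2) != length(impulse_Pa_s))
    stop("calibration vectors must have equal length")
  if (any(fluence_J_cm2 <= 0)) stop("fluences must be positive")
  structure(data.frame(fluence_J_cm2 = fluence_J_cm2,
                       peak_pressure_MPa = peak_pressure_MPa,
                       impulse_Pa_s = impulse_Pa_s),
            class = c("calibration_pairs", "data.frame"))
}

#' Cohort-average shock-wave calibration
#'
#' The four fluence levels of the exposure cohort with their average peak
#' pressures and impulses.
#'
#' @return a [calibration_pairs()].
#' @export
lisw_calibration <- function() {
  calibration_pairs(c(0.75, 1.0, 1.25, 1.5),
                    c(63, 86, 104, 123),
                    c(9, 14, 19, 23))
}

#' Linear fluence calibration fit
#'
#' Ordinary least-squares line of peak pressure (or impulse) versus laser
#' fluence; peak pressure and impulse increase linearly with fluence.
#'
#' @param pairs a [calibration_pairs()].
#' @param target `"pressure"` or `"impulse"`.
#' @return a `calibration_fit`: `slope`, `intercept`, `r2`, `target`.
#' @export
fit_pressure_calibration <- function(pairs, target = c("pressure", "impulse")) {
  stopifnot(inherits(pairs, "calibration_pairs"))
  target <- match.arg(target)
  if (length(unique(pairs$fluence_J_cm2)) < 2)
    stop("degenerate design: at least 2 distinct fluences are required")
  y <- if (target == "pressure") pairs$peak_pressure_MPa else
    pairs$impulse_Pa_s
  fit <- stats::lm(y ~ fluence_J_cm2, data = pairs)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2, target = target),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  unit <- if (x$target == "pressure") "MPa cm2/J" else "Pa s cm2/J"
  cat(sprintf("%s calibration: slope %.1f %s, intercept %.1f, R^2 %.4f\n",
              x$target, x$slope, unit, x$intercept, x$r2))
  invisible(x)
}
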