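#' NIR image stack
#'
#' @param frames numeric array `time x height x width` of pixel intensities
#'   (8-16 bit scale).
#' @param frame_times_s strictly increasing frame times, seconds.
#' @param pixel_pitch_mm physical pixel size, mm.
#' @param origin_px `c(row, col)` of the shock-wave application site.
#' @return an `image_stack`.
#' @export
image_stack <- function(frames, frame_times_s, pixel_pitch_mm, origin_px) {
  frames <- unclass(frames)
  d <- dim(frames)
  if (length(d) != 3) stop("frames must be a time x height x width array")
  if (d[1] != length(frame_times_s))
    stop("frame_times_s must match the first array dimension")
  if (any(diff(frame_times_s) <= 0))
    stop("frame times must be strictly increasing")
  if (pixel_pitch_mm <= 0) stop("pixel pitch must be positive")
  if (length(origin_px) != 2 || any(origin_px < 1) ||
      origin_px[1] > d[2] || origin_px[2] > d[3])
    stop("origin_px must be a (row, col) pair within the frame")
  structure(list(frames = frames, frame_times_s = frame_times_s,
                 pixel_pitch_mm = pixel_pitch_mm, origin_px = origin_px),
            class = "image_stack")
}

#' Difference image stack
#'
#' Subtracts the reference frame (by default the frame immediately after
#' shock-wave application) from every frame, preserving signed values. This
#' is the contrast-enhancement step that exposes the propagating bright/dark
#' scattering wave.
#'
#' @param stack an [image_stack()].
#' @param reference_index index of the reference frame.
#' @return an `image_stack` of signed differences.
#' @export
difference_stack <- function(stack, reference_index = 1) {
  stopifnot(inherits(stack, "image_stack"))
  nt <- dim(stack$frames)[1]
  if (reference_index < 1 || reference_index > nt)
    stop("reference_index out of range")
  ref <- stack$frames[reference_index, , ]
  out <- stack$frames
  for (i in seq_len(nt)) out[i, , ] <- out[i, , ] - ref
  image_stack(out, stack$frame_times_s, stack$pixel_pitch_mm,
              stack$origin_px)
}

#' Track the expanding scattering-wave front
#'
#' Per frame, the positive part of the difference image is thresholded,
#' connected components smaller than `min_blob_px` pixels are discarded, and
#' the front radius is taken as the 95th percentile of the distances of the
#' remaining super-threshold pixels from the application site (robust to
#' ragged blob edges), converted to mm. Frames with no super-threshold pixels
#' are skipped and recorded.
#'
#' @param diff a difference [image_stack()].
#' @param threshold intensity threshold; default 3 times the pixel SD pooled
#'   over the first three difference frames.
#' @param min_blob_px minimum connected-component size in pixels.
#' @param radius_quantile quantile of pixel distances defining the front.
#' @return data frame `time_s`, `radius_mm` (class `front_samples`), with the
#'   skipped frame indices in attribute `skipped`.
#' @export
track_front <- function(diff, threshold = NULL, min_blob_px = 20,
                        radius_quantile = 0.95) {
  stopifnot(inherits(diff, "image_stack"))
  d <- dim(diff$frames)
  if (is.null(threshold)) {
    k <- seq_len(min(3, d[1]))
    threshold <- 3 * stats::sd(as.vector(diff$frames[k, , ]))
  }
  rows <- matrix(seq_len(d[2]), d[2], d[3])
  cols <- matrix(seq_len(d[3]), d[2], d[3], byrow = TRUE)
  dist_px <- sqrt((rows - diff$origin_px[1])^2 + (cols - diff$origin_px[2])^2)
  out_t <- out_r <- numeric(0)
  skipped <- integer(0)
  for (i in seq_len(d[1])) {
    mask <- diff$frames[i, , ] > threshold
    if (any(mask)) {
      lab <- EBImage::bwlabel(mask)
      sizes <- tabulate(lab[lab > 0])
      keep <- which(sizes >= min_blob_px)
      mask <- array(lab %in% keep, dim = dim(lab))
    }
    if (!any(mask)) {
      skipped <- c(skipped, i)
      next
    }
    r <- stats::quantile(dist_px[mask], radius_quantile, names = FALSE) *
      diff$pixel_pitch_mm
    out_t <- c(out_t, diff$frame_times_s[i])
    out_r <- c(out_r, r)
  }
  structure(data.frame(time_s = out_t, radius_mm = out_r),
            skipped = skipped, class = c("front_samples", "data.frame"))
}

#' Fit the front-propagation speed
#'
#' Ordinary least-squares line of front radius versus time; the speed is the
#' slope converted to mm/min.
#'
#' @param samples a data frame with `time_s` and `radius_mm` (at least 3
#'   rows), e.g. from [track_front()].
#' @return a `front_track`: `samples`, `fit_speed_mm_per_min`,
#'   `fit_intercept_mm`, `fit_r2`.
#' @export
fit_front_speed <- function(samples) {
  if (nrow(samples) < 3)
    stop("insufficient data: at least 3 front samples are required")
  fit <- stats::lm(radius_mm ~ time_s, data = samples)
  sst <- sum((samples$radius_mm - mean(samples$radius_mm))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(list(samples = samples,
                 fit_speed_mm_per_min = unname(stats::coef(fit)[2]) * 60,
                 fit_intercept_mm = unname(stats::coef(fit)[1]),
                 fit_r2 = r2),
            class = "front_track")
}

#' @export
print.front_track <- function(x, ...) {
  cat(sprintf(
    "Front track: %d samples, speed %.2f mm/min (intercept %.2f mm, R^2 %.3f)\n",
    nrow(x$samples), x$fit_speed_mm_per_min, x$fit_intercept_mm, x$fit_r2))
  invisible(x)
}

#' @export
coef.front_track <- function(object, ...) {
  c(speed_mm_per_min = object$fit_speed_mm_per_min,
    intercept_mm = object$fit_intercept_mm)
}

#' @export
plot.front_track <- function(x, ...) {
  graphics::plot(x$samples$time_s, x$samples$radius_mm,
                 xlab = "time (s)", ylab = "front radius (mm)", ...)
  graphics::abline(x$fit_intercept_mm, x$fit_speed_mm_per_min / 60)
  invisible(x)
}

#' Expansion speed from multichannel onset times
#'
#' Least-squares slope of channel distance versus onset time, in mm/min. With
#' two channels the slope equals the finite difference exactly. Channels with
#' missing onsets (`NA`) are dropped; at least two detected onsets are
#' required.
#'
#' @param channel_distances_mm distances of the fiber channels from the
#'   application site, mm.
#' @param onset_times_s per-channel onset (turning-point) times, seconds.
#' @return speed in mm/min.
#' @export
onset_regression <- function(channel_distances_mm, onset_times_s) {
  if (length(channel_distances_mm) != length(onset_times_s))
    stop("distances and onset times must have equal length")
  ok <- is.finite(channel_distances_mm) & is.finite(onset_times_s)
  if (sum(ok) < 2)
    stop("insufficient data: at least 2 channels with detected onsets")
  fit <- stats::lm(d ~ t, data = data.frame(d = channel_distances_mm[ok],
                                            t = onset_times_s[ok]))
  unname(stats::coef(fit)[2]) * 60
}

#' Hypoxemia expansion speed from multichannel oxygenation traces
#'
#' Detects the hyperoxemia-to-hypoxemia turning point on each normalized
#' channel trace and regresses channel distance on turning time.
#'
#' @param traces list of normalized oxygenation [optical_trace()] objects.
#' @param channel_distances_mm channel distances, mm.
#' @return list `speed_mm_per_min`, `onsets_s`.
#' @export
hypoxemia_expansion_speed <- function(traces, channel_distances_mm) {
  onsets <- vapply(traces, detect_turning_point, numeric(1))
  list(speed_mm_per_min = onset_regression(channel_distances_mm, onsets),
       onsets_s = onsets)
}

#' Write / read an image stack as multi-page TIFF with a JSON sidecar
#'
#' The TIFF stores the frames (scaled to `[0, 1]` 16-bit); the sidecar
#' carries `frame_times_s`, `pixel_pitch_mm`, `origin_px` and the intensity
#' scale.
#'
#' @param stack an [image_stack()].
#' @param tiff_path,json_path file paths; `json_path` defaults to
#'   `tiff_path` with extension `.json`.
#' @return `write_image_stack` the paths (invisibly); `read_image_stack` an
#'   `image_stack`.
#' @export
write_image_stack <- function(stack, tiff_path,
                              json_path = sub("\\.tiff?$", ".json",
                                              tiff_path)) {
  stopifnot(inherits(stack, "image_stack"))
  nt <- dim(stack$frames)[1]
  scale <- max(stack$frames, 1)
  pages <- lapply(seq_len(nt), function(i)
    pmin(pmax(stack$frames[i, , ] / scale, 0), 1))
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 16)
  jsonlite::write_json(
    list(frame_times_s = stack$frame_times_s,
         pixel_pitch_mm = stack$pixel_pitch_mm,
         origin_px = stack$origin_px, intensity_scale = scale),
    json_path, auto_unbox = FALSE, digits = NA)
  invisible(c(tiff_path, json_path))
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(tiff_path,
                             json_path = sub("\\.tiff?$", ".json",
                                             tiff_path)) {
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  frames <- array(0, dim = c(length(pages), dim(pages[[1]])[1:2]))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3) p <- p[, , 1]
    frames[i, , ] <- p * meta$intensity_scale
  }
  image_stack(frames, meta$frame_times_s, meta$pixel_pitch_mm,
              meta$origin_px)
}
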