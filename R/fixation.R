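# Dispersion/duration fixation detection from binocular gaze streams.
#
# A fixation is a maximal run of consecutive non-missing gaze samples in
# which every consecutive pair of retained samples lies less than
# `dispersion_px` apart (Euclidean), lasting at least `min_duration_ms`.
# Missing samples inside a run are disregarded when computing consecutive
# distances, but a non-missing gap longer than `max_gap_ms` terminates the
# run so that unrelated fixations separated by a long signal loss (e.g. a
# blink) are never merged.

#' Fixation detection parameters
#'
#' @param dispersion_px Maximum Euclidean distance, in screen pixels, between
#'   consecutive retained samples of one fixation (default 25; samples at
#'   exactly this distance break the run).
#' @param min_duration_ms Minimum fixation duration, last minus first
#'   timestamp of the run, inclusive (default 50 ms).
#' @param max_gap_ms Longest tolerated gap between consecutive non-missing
#'   samples before the run is split (default 75 ms, roughly 9 samples at
#'   120 Hz and below typical blink duration).
#' @return A `fixation_params` list.
#' @export
fixation_params <- function(dispersion_px = 25, min_duration_ms = 50,
                            max_gap_ms = 75) {
  vals <- c(dispersion_px = dispersion_px, min_duration_ms = min_duration_ms,
            max_gap_ms = max_gap_ms)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_("fixation parameters must be strictly positive")
  }
  structure(as.list(vals), class = "fixation_params")
}

#' Collapse a binocular stream to a single gaze position per sample
#'
#' When both eyes are valid the gaze position is the componentwise mean of
#' the two; when only one eye is valid that eye is used; when neither is, the
#' sample is missing.
#'
#' @param stream A `gaze_stream`.
#' @return Data frame `timestamp_ms`, `x`, `y` with one row per input sample
#'   (missing samples keep their timestamp with `NA` coordinates).
#' @export
merge_binocular <- function(stream) {
  s <- stream$samples
  has_l <- !is.na(s$left_x) & !is.na(s$left_y)
  has_r <- !is.na(s$right_x) & !is.na(s$right_y)
  x <- ifelse(has_l & has_r, (s$left_x + s$right_x) / 2,
              ifelse(has_l, s$left_x, s$right_x))
  y <- ifelse(has_l & has_r, (s$left_y + s$right_y) / 2,
              ifelse(has_l, s$left_y, s$right_y))
  data.frame(timestamp_ms = s$timestamp_ms, x = x, y = y)
}

#' Detect fixations in a merged gaze sequence
#'
#' Segments the sequence into maximal runs under the pairwise
#' dispersion rule (see [fixation_params()]) and keeps runs meeting the
#' duration criterion. Each fixation's centroid is the unweighted mean of its
#' member sample positions.
#'
#' @param points Data frame `timestamp_ms`, `x`, `y` as produced by
#'   [merge_binocular()]; `NA` coordinates mark missing samples. Timestamps
#'   must be strictly increasing.
#' @param params A [fixation_params()] list.
#' @return Data frame with one row per fixation: `start_ms`, `end_ms`,
#'   `duration_ms`, `x`, `y` (centroid), `n_samples`, in time order.
#' @examples
#' ts <- seq(0, by = 1000 / 120, length.out = 13)
#' pts <- data.frame(timestamp_ms = ts, x = 500, y = 500)
#' detect_fixations(pts)  # one 100-ms fixation at (500, 500)
#' @export
detect_fixations <- function(points, params = fixation_params()) {
  ts <- points$timestamp_ms
  if (any(!is.finite(ts))) stop_("timestamps must be finite")
  if (any(diff(ts) <= 0)) stop_("timestamps must be strictly increasing")
  keep <- !is.na(points$x) & !is.na(points$y)
  ts <- ts[keep]; x <- points$x[keep]; y <- points$y[keep]
  n <- length(ts)
  if (n == 0) return(empty_fixations())
  # run breaks: consecutive retained samples too far apart in space or time
  if (n > 1) {
    d <- sqrt(diff(x)^2 + diff(y)^2)
    brk <- d >= params$dispersion_px | diff(ts) > params$max_gap_ms
  } else {
    brk <- logical(0)
  }
  run <- cumsum(c(TRUE, brk))
  start <- tapply(ts, run, min)
  end <- tapply(ts, run, max)
  cx <- tapply(x, run, mean)
  cy <- tapply(y, run, mean)
  nsamp <- tabulate(run)
  dur <- end - start
  ok <- dur >= params$min_duration_ms & nsamp >= 2
  out <- data.frame(start_ms = as.numeric(start[ok]),
                    end_ms = as.numeric(end[ok]),
                    duration_ms = as.numeric(dur[ok]),
                    x = as.numeric(cx[ok]), y = as.numeric(cy[ok]),
                    n_samples = nsamp[ok])
  out[order(out$start_ms), , drop = FALSE]
}

empty_fixations <- function() {
  data.frame(start_ms = numeric(), end_ms = numeric(),
             duration_ms = numeric(), x = numeric(), y = numeric(),
             n_samples = integer())
}

#' Map screen-frame points into the image frame
#'
#' The display geometry is an affine scale-plus-offset: an image pixel `u`
#' appears on screen at `u * scale + offset`. This inverts it:
#' `(x - offset_x) / scale`. Points landing outside the image bounds are
#' flagged, never clamped.
#'
#' @param points Data frame with `x`, `y` in screen pixels (other columns are
#'   passed through).
#' @param scale Positive display magnification.
#' @param offset_x,offset_y Screen position of the image origin, pixels.
#' @param image_width,image_height Optional image dimensions; when given an
#'   `in_image` logical column is added (half-open bounds
#'   `[0, width) x [0, height)`).
#' @return `points` with `x`, `y` rewritten in image pixels.
#' @export
map_screen_to_image <- function(points, scale = 1, offset_x = 0, offset_y = 0,
                                image_width = NULL, image_height = NULL) {
  if (!is.finite(scale) || scale <= 0) stop_("display scale must be positive")
  points$x <- (points$x - offset_x) / scale
  points$y <- (points$y - offset_y) / scale
  if (!is.null(image_width) && !is.null(image_height)) {
    points$in_image <- !is.na(points$x) & !is.na(points$y) &
      points$x >= 0 & points$x < image_width &
      points$y >= 0 & points$y < image_height
  }
  points
}

#' Write a fixation table
#'
#' @param fixations A fixation data frame from [detect_fixations()].
#' @param participant_id,trial_id Identifiers written on every row.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_fixations <- function(fixations, participant_id, trial_id, path,
                            sep = "\t") {
  out <- data.frame(participant_id = participant_id, trial_id = trial_id,
                    start_ms = fmt_num(fixations$start_ms),
                    end_ms = fmt_num(fixations$end_ms),
                    centroid_x = fmt_num(fixations$x),
                    centroid_y = fmt_num(fixations$y),
                    n_samples = fixations$n_samples)
  write_tsv(out, path, sep)
  invisible(path)
}
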