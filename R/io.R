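# Readers and writers for the study's delimited tables: raw gaze streams,
# ground-truth polyp bounding boxes (ROIs), annotation marks and the trial
# manifest. All tables are tab-separated with one header line (comma
# available via `sep`); coordinates are 0-based pixels, origin top-left,
# x rightward, y downward. Bounding boxes are half-open:
# [x_min, x_max) x [y_min, y_max).

GAZE_COLS <- c("participant_id", "trial_id", "timestamp_ms",
               "left_x", "left_y", "left_valid",
               "right_x", "right_y", "right_valid")
ROI_COLS <- c("image_id", "polyp_id", "x_min", "y_min", "x_max", "y_max")
ROI_META_COLS <- c("size_mm", "paris", "location", "pathology")
MARK_COLS <- c("participant_id", "image_id", "x", "y")

read_table_checked <- function(path, required, sep = "\t") {
  if (!file.exists(path)) stop_("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", quote = "", fill = FALSE,
                          stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_("%s: missing required column(s): %s", path,
          paste(missing, collapse = ", "))
  }
  df
}

num_col <- function(df, col, path, allow_empty = FALSE) {
  raw <- df[[col]]
  empty <- !nzchar(trimws(raw))
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(out) & !empty)
  if (length(bad) > 0) {
    stop_("%s: column '%s' not numeric at data line %d (value '%s')",
          path, col, bad[1], raw[bad[1]])
  }
  if (!allow_empty && any(empty)) {
    stop_("%s: column '%s' empty at data line %d", path, col, which(empty)[1])
  }
  out
}

#' Read a raw binocular gaze stream
#'
#' Parses one trial's eye-tracker export: timestamped pixel coordinates for
#' each eye, with per-eye validity flags (1 = valid, 0 = invalid). Invalid
#' eyes yield missing points; a sample may have one eye, both, or neither.
#'
#' @param path Path to a gaze table (TSV by default) with columns
#'   `participant_id trial_id timestamp_ms left_x left_y left_valid right_x
#'   right_y right_valid`.
#' @param participant_id,trial_id Optional identifiers; when given, the file
#'   is filtered to this participant/trial and the identifiers are checked.
#' @param nominal_rate Nominal sampling rate in Hz (default 120).
#' @param sep Field separator, `"\t"` (default) or `","`.
#' @return A `gaze_stream`: a list with `participant_id`, `trial_id`,
#'   `nominal_rate` and a `samples` data frame (`timestamp_ms`, `left_x`,
#'   `left_y`, `right_x`, `right_y`; `NA` marks an absent eye), sorted by
#'   strictly increasing timestamp.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' s <- gaze_stream(data.frame(timestamp_ms = c(0, 8.333, 16.667),
#'                             left_x = 100, left_y = 200,
#'                             right_x = 110, right_y = 210),
#'                  participant_id = "p1", trial_id = "t1")
#' write_gaze_stream(s, f)
#' identical(read_gaze_stream(f), s)
#' @export
read_gaze_stream <- function(path, participant_id = NULL, trial_id = NULL,
                             nominal_rate = 120, sep = "\t") {
  df <- read_table_checked(path, GAZE_COLS, sep)
  if (!is.null(participant_id)) df <- df[df$participant_id == participant_id, ]
  if (!is.null(trial_id)) df <- df[df$trial_id == trial_id, ]
  if (nrow(df) == 0) stop_("%s: no gaze rows for the requested trial", path)
  if (length(unique(df$participant_id)) > 1 || length(unique(df$trial_id)) > 1) {
    stop_("%s: multiple participant/trial ids; pass participant_id and trial_id",
          path)
  }
  ts <- num_col(df, "timestamp_ms", path)
  lv <- num_col(df, "left_valid", path)
  rv <- num_col(df, "right_valid", path)
  if (!all(lv %in% c(0, 1)) || !all(rv %in% c(0, 1))) {
    stop_("%s: validity flags must be 0 or 1", path)
  }
  samples <- data.frame(
    timestamp_ms = ts,
    left_x  = ifelse(lv == 1, num_col(df, "left_x",  path, allow_empty = TRUE), NA_real_),
    left_y  = ifelse(lv == 1, num_col(df, "left_y",  path, allow_empty = TRUE), NA_real_),
    right_x = ifelse(rv == 1, num_col(df, "right_x", path, allow_empty = TRUE), NA_real_),
    right_y = ifelse(rv == 1, num_col(df, "right_y", path, allow_empty = TRUE), NA_real_)
  )
  if (any(lv == 1 & (is.na(samples$left_x) | is.na(samples$left_y))) ||
      any(rv == 1 & (is.na(samples$right_x) | is.na(samples$right_y)))) {
    stop_("%s: eye flagged valid but coordinates missing", path)
  }
  samples <- samples[order(samples$timestamp_ms), , drop = FALSE]
  rownames(samples) <- NULL
  if (anyDuplicated(samples$timestamp_ms)) {
    stop_("%s: duplicate timestamps (first at %s ms)", path,
          samples$timestamp_ms[duplicated(samples$timestamp_ms)][1])
  }
  gaze_stream(samples, participant_id = df$participant_id[1],
              trial_id = df$trial_id[1], nominal_rate = nominal_rate)
}

#' Construct a gaze stream in memory
#'
#' @param samples Data frame with `timestamp_ms`, `left_x`, `left_y`,
#'   `right_x`, `right_y` (`NA` = absent eye). Timestamps must be strictly
#'   increasing and finite.
#' @param participant_id,trial_id Identifiers attached to the stream.
#' @param nominal_rate Nominal sampling rate in Hz.
#' @return A `gaze_stream` object.
#' @export
gaze_stream <- function(samples, participant_id, trial_id, nominal_rate = 120) {
  need <- c("timestamp_ms", "left_x", "left_y", "right_x", "right_y")
  for (col in setdiff(need, names(samples))) samples[[col]] <- NA_real_
  samples <- samples[need]
  samples[] <- lapply(samples, as.numeric)
  ts <- samples$timestamp_ms
  if (any(!is.finite(ts))) stop_("gaze timestamps must be finite")
  if (any(diff(ts) <= 0)) {
    stop_("gaze timestamps must be strictly increasing (violation after %s ms)",
          ts[which(diff(ts) <= 0)[1]])
  }
  if (!is.numeric(nominal_rate) || nominal_rate <= 0) {
    stop_("nominal_rate must be positive")
  }
  rownames(samples) <- NULL
  structure(list(participant_id = as.character(participant_id),
                 trial_id = as.character(trial_id),
                 nominal_rate = as.numeric(nominal_rate),
                 samples = samples),
            class = "gaze_stream")
}

#' @export
print.gaze_stream <- function(x, ...) {
  n <- nrow(x$samples)
  span <- if (n > 0) diff(range(x$samples$timestamp_ms)) else 0
  cat(sprintf("<gaze_stream> participant %s, trial %s: %d samples over %.0f ms @ %g Hz\n",
              x$participant_id, x$trial_id, n, span, x$nominal_rate))
  invisible(x)
}

#' Write a gaze stream
#'
#' Inverse of [read_gaze_stream()]: absent eyes are written with empty
#' coordinate fields and a 0 validity flag.
#'
#' @param stream A `gaze_stream`.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_gaze_stream <- function(stream, path, sep = "\t") {
  s <- stream$samples
  lv <- as.integer(!is.na(s$left_x) & !is.na(s$left_y))
  rv <- as.integer(!is.na(s$right_x) & !is.na(s$right_y))
  out <- data.frame(
    participant_id = stream$participant_id,
    trial_id = stream$trial_id,
    timestamp_ms = fmt_num(s$timestamp_ms),
    left_x = fmt_num(ifelse(lv == 1, s$left_x, NA_real_)),
    left_y = fmt_num(ifelse(lv == 1, s$left_y, NA_real_)),
    left_valid = lv,
    right_x = fmt_num(ifelse(rv == 1, s$right_x, NA_real_)),
    right_y = fmt_num(ifelse(rv == 1, s$right_y, NA_real_)),
    right_valid = rv)
  write_tsv(out, path, sep)
  invisible(path)
}

write_tsv <- function(df, path, sep = "\t") {
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
}

#' Read a polyp region-of-interest table
#'
#' Each row is one ground-truth bounding box, drawn by experts around a polyp
#' in one image. Boxes are half-open pixel rectangles
#' `[x_min, x_max) x [y_min, y_max)` in the image frame. Optional lesion
#' metadata columns (`size_mm`, `paris`, `location`, `pathology`) are carried
#' through untouched.
#'
#' @param path Path to a TSV with columns
#'   `image_id polyp_id x_min y_min x_max y_max [size_mm paris location pathology]`.
#' @param sep Field separator.
#' @return Data frame of class `roi_table`, one row per (image, polyp).
#' @export
read_roi_table <- function(path, sep = "\t") {
  df <- read_table_checked(path, ROI_COLS, sep)
  out <- data.frame(image_id = df$image_id, polyp_id = df$polyp_id,
                    x_min = num_col(df, "x_min", path),
                    y_min = num_col(df, "y_min", path),
                    x_max = num_col(df, "x_max", path),
                    y_max = num_col(df, "y_max", path))
  for (col in intersect(ROI_META_COLS, names(df))) out[[col]] <- df[[col]]
  validate_rois(out, path)
}

validate_rois <- function(rois, origin = "roi table") {
  bad <- which(rois$x_min >= rois$x_max | rois$y_min >= rois$y_max)
  if (length(bad) > 0) {
    stop_("%s: degenerate bounding box for polyp '%s' (x_min >= x_max or y_min >= y_max)",
          origin, rois$polyp_id[bad[1]])
  }
  key <- paste(rois$image_id, rois$polyp_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop_("%s: duplicate (image_id, polyp_id): %s", origin,
          sub("\r", "/", key[duplicated(key)][1]))
  }
  rownames(rois) <- NULL
  class(rois) <- c("roi_table", "data.frame")
  rois
}

#' @rdname read_roi_table
#' @param rois An ROI table.
#' @export
write_roi_table <- function(rois, path, sep = "\t") {
  out <- as.data.frame(rois)
  for (col in c("x_min", "y_min", "x_max", "y_max")) {
    out[[col]] <- fmt_num(out[[col]])
  }
  write_tsv(out, path, sep)
  invisible(path)
}

#' Read annotation marks
#'
#' Marks are the cursor positions participants placed on areas suspicious for
#' polyps during the annotation phase, in image-frame pixels.
#'
#' @param path Path to a TSV with columns
#'   `participant_id image_id x y [mark_time_ms]`. An empty table (header
#'   only, or a zero-length file) yields zero marks.
#' @param sep Field separator.
#' @return Data frame with columns `participant_id`, `image_id`, `x`, `y`,
#'   `mark_time_ms` (`NA` when not recorded).
#' @export
read_marks <- function(path, sep = "\t") {
  if (!file.exists(path)) stop_("file not found: %s", path)
  if (file.size(path) == 0) return(empty_marks())
  df <- read_table_checked(path, MARK_COLS, sep)
  if (nrow(df) == 0) return(empty_marks())
  out <- data.frame(participant_id = df$participant_id,
                    image_id = df$image_id,
                    x = num_col(df, "x", path),
                    y = num_col(df, "y", path),
                    mark_time_ms = if ("mark_time_ms" %in% names(df)) {
                      num_col(df, "mark_time_ms", path, allow_empty = TRUE)
                    } else {
                      NA_real_
                    })
  rownames(out) <- NULL
  out
}

empty_marks <- function() {
  data.frame(participant_id = character(), image_id = character(),
             x = numeric(), y = numeric(), mark_time_ms = numeric())
}

#' @rdname read_marks
#' @param marks A marks data frame.
#' @export
write_marks <- function(marks, path, sep = "\t") {
  out <- marks
  out$x <- fmt_num(out$x)
  out$y <- fmt_num(out$y)
  if ("mark_time_ms" %in% names(out)) out$mark_time_ms <- fmt_num(out$mark_time_ms)
  write_tsv(out, path, sep)
  invisible(path)
}

#' Read or write a trial manifest
#'
#' The manifest is a YAML file tying a study together: one entry per trial
#' (participant, cohort group, image, image dimensions, gaze file and the
#' screen-to-image display geometry) plus the list of negative — polyp-free —
#' image identifiers.
#'
#' @param path Path to the manifest YAML.
#' @return A list with `trials` (data frame: `participant_id`, `group`,
#'   `trial_id`, `image_id`, `image_width`, `image_height`, `gaze_file`,
#'   `scale`, `offset_x`, `offset_y`) and `negative_images` (character).
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  if (is.null(m$trials) || length(m$trials) == 0) {
    stop_("%s: manifest lists no trials", path)
  }
  trials <- do.call(rbind, lapply(m$trials, function(tr) {
    data.frame(participant_id = as.character(tr$participant_id),
               group = as.character(tr$group),
               trial_id = as.character(tr$trial_id),
               image_id = as.character(tr$image_id),
               image_width = as.numeric(tr$image_width),
               image_height = as.numeric(tr$image_height),
               gaze_file = as.character(tr$gaze_file %||% NA_character_),
               scale = as.numeric(tr$scale %||% 1),
               offset_x = as.numeric(tr$offset_x %||% 0),
               offset_y = as.numeric(tr$offset_y %||% 0))
  }))
  if (any(!nzchar(trials$group))) stop_("%s: empty group label", path)
  list(trials = trials,
       negative_images = as.character(unlist(m$negative_images)))
}

#' @rdname read_manifest
#' @param manifest A manifest list as returned by [read_manifest()].
#' @export
write_manifest <- function(manifest, path) {
  trials <- lapply(seq_len(nrow(manifest$trials)), function(i) {
    as.list(manifest$trials[i, , drop = FALSE])
  })
  trials <- lapply(trials, function(tr) lapply(tr, unname))
  yaml::write_yaml(list(trials = trials,
                        negative_images = as.list(manifest$negative_images)),
                   path)
  invisible(path)
}
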