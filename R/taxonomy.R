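# Error taxonomy for participant-polyp encounters.
#
# A polyp is correctly detected when a participant placed an annotation mark
# inside its ground-truth bounding box. Missed polyps split into two
# mechanistically distinct errors: a gaze error (no fixation ever landed in
# the polyp region — the lesion was not observed) and a cognitive error (the
# participant fixated in the region but did not mark it — observed but not
# recognized).

OUTCOME_LEVELS <- c("CORRECT", "GAZE_ERROR", "COGNITIVE_ERROR")

#' Point-in-box hit test
#'
#' Boxes are half-open: a point on the minimum edge is inside, a point on the
#' maximum edge is outside, so adjacent boxes never double-count a point.
#'
#' @param x,y Point coordinates, image-frame pixels (vectorized).
#' @param roi A single-row ROI record with `x_min`, `y_min`, `x_max`, `y_max`.
#' @return Logical vector: `TRUE` where the point lies in
#'   `[x_min, x_max) x [y_min, y_max)`.
#' @export
point_in_roi <- function(x, y, roi) {
  !is.na(x) & !is.na(y) &
    x >= roi$x_min & x < roi$x_max &
    y >= roi$y_min & y < roi$y_max
}

#' Classify one encounter from its fixation and mark evidence
#'
#' A mark in the region dominates: `marked` implies a correct detection
#' regardless of gaze. Unmarked encounters are gaze errors when unfixated and
#' cognitive errors when fixated.
#'
#' @param fixated Logical: any fixation in the polyp region (vectorized).
#' @param marked Logical: any annotation mark in the polyp region.
#' @return Character vector over `"CORRECT"`, `"GAZE_ERROR"`,
#'   `"COGNITIVE_ERROR"`.
#' @export
classify_outcome <- function(fixated, marked) {
  ifelse(marked, "CORRECT",
         ifelse(fixated, "COGNITIVE_ERROR", "GAZE_ERROR"))
}

#' Evaluate one participant's trial against an image's ground truth
#'
#' For every ROI of the image, decides whether the participant fixated in it
#' (by default: any fixation centroid inside the box) and whether they marked
#' it (any annotation mark inside; multiple marks in one box count once), and
#' classifies the encounter with [classify_outcome()]. Marks falling in no
#' ROI are returned as false positives. Negative (polyp-free) images yield no
#' outcomes, only false positives.
#'
#' @param fixations Fixation data frame (image frame), from
#'   [detect_fixations()] after [map_screen_to_image()].
#' @param marks Marks data frame (image frame) for this participant/image.
#' @param rois ROI table rows for this image (zero rows for a negative
#'   image).
#' @param participant_id,group,image_id Identifiers stamped onto the results.
#' @param roi_hit `"centroid"` (default) tests fixation centroids against the
#'   box; `"any-sample"` additionally accepts fixations supplied with member
#'   sample coordinates in attribute `"samples"` (data frame `x`, `y`,
#'   `fixation`).
#' @return List with `outcomes` (one row per ROI: `participant_id`, `group`,
#'   `image_id`, `polyp_id`, `fixated`, `marked`, `outcome`) and
#'   `false_positives` (one row per off-target mark).
#' @export
evaluate_trial <- function(fixations, marks, rois, participant_id, group,
                           image_id, roi_hit = c("centroid", "any-sample")) {
  roi_hit <- match.arg(roi_hit)
  if (nrow(rois) > 0 && any(rois$image_id != image_id)) {
    stop_("ROI table rows for image '%s' handed to trial on image '%s'",
          rois$image_id[rois$image_id != image_id][1], image_id)
  }
  if (nrow(marks) > 0 && any(marks$image_id != image_id)) {
    stop_("marks for image '%s' handed to trial on image '%s'",
          marks$image_id[marks$image_id != image_id][1], image_id)
  }
  fx <- fixations$x
  fy <- fixations$y
  if (roi_hit == "any-sample" && !is.null(attr(fixations, "samples"))) {
    smp <- attr(fixations, "samples")
    fx <- c(fx, smp$x)
    fy <- c(fy, smp$y)
  }
  mark_in_any <- rep(FALSE, nrow(marks))
  outcomes <- NULL
  if (nrow(rois) > 0) {
    fixated <- logical(nrow(rois))
    marked <- logical(nrow(rois))
    for (i in seq_len(nrow(rois))) {
      roi <- rois[i, ]
      fixated[i] <- any(point_in_roi(fx, fy, roi))
      hit <- point_in_roi(marks$x, marks$y, roi)
      marked[i] <- any(hit)
      mark_in_any <- mark_in_any | hit
    }
    outcomes <- data.frame(participant_id = participant_id, group = group,
                           image_id = image_id, polyp_id = rois$polyp_id,
                           fixated = fixated, marked = marked,
                           outcome = classify_outcome(fixated, marked))
  } else {
    outcomes <- empty_outcomes()
  }
  fp <- marks[!mark_in_any, c("participant_id", "image_id", "x", "y"),
              drop = FALSE]
  rownames(fp) <- NULL
  rownames(outcomes) <- NULL
  list(outcomes = outcomes, false_positives = fp)
}

empty_outcomes <- function() {
  data.frame(participant_id = character(), group = character(),
             image_id = character(), polyp_id = character(),
             fixated = logical(), marked = logical(), outcome = character())
}

#' Write outcome and false-positive tables
#'
#' @param outcomes Outcome data frame (rows from [evaluate_trial()]).
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(outcomes, path, sep = "\t") {
  out <- outcomes
  out$fixated <- as.integer(out$fixated)
  out$marked <- as.integer(out$marked)
  write_tsv(out, path, sep)
  invisible(path)
}
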