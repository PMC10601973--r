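# Independent brute-force oracles and fixture builders. These deliberately
# re-derive results by naive enumeration, not by calling package internals.

# Exhaustive maximal-run fixation oracle: walk the retained samples with an
# explicit double loop, extending each run while every consecutive pair is
# closer than the dispersion threshold and no non-missing gap exceeds
# max_gap; keep runs meeting the duration rule.
oracle_fixations <- function(points, dispersion = 25, min_dur = 50,
                             max_gap = 75) {
  keep <- which(!is.na(points$x) & !is.na(points$y))
  ts <- points$timestamp_ms[keep]
  x <- points$x[keep]; y <- points$y[keep]
  n <- length(ts)
  runs <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n &&
           sqrt((x[j + 1] - x[j])^2 + (y[j + 1] - y[j])^2) < dispersion &&
           (ts[j + 1] - ts[j]) <= max_gap) {
      j <- j + 1L
    }
    runs[[length(runs) + 1L]] <- i:j
    i <- j + 1L
  }
  out <- lapply(runs, function(r) {
    if (length(r) >= 2 && (ts[max(r)] - ts[min(r)]) >= min_dur) {
      data.frame(start_ms = ts[min(r)], end_ms = ts[max(r)],
                 duration_ms = ts[max(r)] - ts[min(r)],
                 x = mean(x[r]), y = mean(y[r]), n_samples = length(r))
    }
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    data.frame(start_ms = numeric(), end_ms = numeric(),
               duration_ms = numeric(), x = numeric(), y = numeric(),
               n_samples = integer())
  } else {
    out
  }
}

# Random merged gaze sequence: clustered wandering with occasional large
# saccade-like jumps and missing stretches.
random_points <- function(n, missing_prob = 0.1, jump_prob = 0.08,
                          jitter = 8, dt = 1000 / 120) {
  ts <- cumsum(stats::runif(n, 0.5 * dt, 1.5 * dt))
  x <- numeric(n); y <- numeric(n)
  cx <- stats::runif(1, 0, 1920); cy <- stats::runif(1, 0, 1080)
  for (i in seq_len(n)) {
    if (stats::runif(1) < jump_prob) {
      cx <- stats::runif(1, 0, 1920); cy <- stats::runif(1, 0, 1080)
    }
    x[i] <- cx + stats::rnorm(1, 0, jitter)
    y[i] <- cy + stats::rnorm(1, 0, jitter)
  }
  miss <- stats::runif(n) < missing_prob
  x[miss] <- NA; y[miss] <- NA
  data.frame(timestamp_ms = ts, x = x, y = y)
}

# Two-sided Fisher p by direct hypergeometric enumeration over all tables
# with the observed margins.
oracle_fisher <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); N <- sum(m)
  xs <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- stats::dhyper(xs, c1, N - c1, r1)
  obs <- stats::dhyper(m[1, 1], c1, N - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Naive re-classification of one trial: double loop over ROIs and points.
oracle_outcomes <- function(fix_xy, mark_xy, rois) {
  out <- character(nrow(rois))
  for (i in seq_len(nrow(rois))) {
    r <- rois[i, ]
    inside <- function(p) p[1] >= r$x_min && p[1] < r$x_max &&
      p[2] >= r$y_min && p[2] < r$y_max
    fixated <- nrow(fix_xy) > 0 &&
      any(apply(fix_xy, 1, inside))
    marked <- nrow(mark_xy) > 0 && any(apply(mark_xy, 1, inside))
    out[i] <- if (marked) "CORRECT" else if (fixated) "COGNITIVE_ERROR" else "GAZE_ERROR"
  }
  out
}

# A regular 120-Hz sample grid at a fixed location.
const_points <- function(n, x, y, dt = 1000 / 120, t0 = 0) {
  data.frame(timestamp_ms = t0 + (seq_len(n) - 1) * dt, x = x, y = y)
}

tiny_rois <- function() {
  validate_gazerr_rois(data.frame(
    image_id = c("imgA", "imgA", "imgB"),
    polyp_id = c("p1", "p2", "p3"),
    x_min = c(100, 500, 0), y_min = c(200, 100, 0),
    x_max = c(300, 700, 50), y_max = c(400, 300, 50)))
}

# keep helper self-contained: re-tag the class the readers attach
validate_gazerr_rois <- function(df) {
  class(df) <- c("roi_table", "data.frame")
  df
}
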