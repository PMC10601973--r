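---
title: "Gaze and cognitive errors in lesion recognition: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze and cognitive errors in lesion recognition: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazerr)
```

## The problem

When an observer misses a lesion that is plainly inside the field of view,
two very different things may have happened: the lesion was never looked at,
or it was looked at and not recognized. Screen-based eye tracking can tell
these apart. gazerr implements that analysis for bounding-box perception
studies: participants freely view each image for a fixed time while a
tracker records both eyes, then mark suspicious areas with the cursor.
Every participant–polyp pair (an *encounter*) is classified as

* **correct detection** — a mark landed inside the polyp's ground-truth
  bounding box;
* **gaze error** — no mark, and no fixation ever fell inside the box (the
  lesion was not observed);
* **cognitive error** — no mark, but at least one fixation fell inside the
  box (observed but not recognized).

The three categories are exhaustive and mutually exclusive, and a mark
dominates gaze: a marked polyp is correct even if no fixation centroid
landed in the box, because detection is defined solely by the mark's
location.

## Fixation detection

Raw input is a 120-Hz stream of timestamped pixel positions per eye. The
two eyes are averaged componentwise; if only one eye is valid that eye is
used (discarding the sample would throw away data the averaging rule is
silent about); if neither is valid the sample is missing.

A fixation is a maximal run of consecutive non-missing samples in which
every consecutive pair of retained samples is less than
`dispersion_px = 25` pixels apart (Euclidean), with duration — last minus
first timestamp — of at least `min_duration_ms = 50`, inclusively. Three
choices here were genuinely open and are worth recording:

* **Pairwise distance, not window dispersion.** "Inter-sample distance"
  between *consecutive* samples is read literally as a chain criterion. The
  common I-DT alternative (max minus min of a sliding window under a
  threshold) segments differently; whether the original tracker
  post-processing used one or the other is not documentable, so the pairwise
  rule is the package's defined semantics and the oracle tests cover exactly
  it. The threshold is exclusive: a step of exactly 25 px breaks the run.
* **Inclusive duration.** A run spanning exactly 50.0 ms is a fixation.
  Some boundary had to be fixed deterministically; inclusive matches the
  reading "minimal duration 50 ms".
* **Missing data.** Missing samples are skipped when computing consecutive
  distances, but a non-missing gap longer than `max_gap_ms = 75` terminates
  the run. Unbounded bridging would happily merge two unrelated fixations
  across a blink; 75 ms is roughly nine samples at 120 Hz, below typical
  blink duration, and configurable.

Centroids are unweighted means of member sample positions. Hit testing
against boxes is half-open (`[x_min, x_max) × [y_min, y_max)`, 0-based
pixels, origin top-left), so adjacent boxes never double-count a point. By
default the *centroid* must fall inside the box for the encounter to count
as fixated; a single stray member sample is not "fixating in the polyp
region". The alternative any-sample rule is available as
`roi_hit = "any-sample"` since the original analysis is not explicit about
it.

## Statistics

All proportions are pooled within a cohort (sum of numerators over sum of
denominators); with equal per-participant denominators this equals the mean
per-participant value. Each proportion carries a two-sided exact
Clopper–Pearson interval from Beta quantiles: lower
`qbeta(α/2, k, n−k+1)` (0 at `k = 0`), upper `qbeta(1−α/2, k+1, n−k)`
(1 at `k = n`). These intervals are conservative: coverage is at least the
nominal level everywhere, which the suite confirms empirically at
`p ∈ {0.1, 0.5, 0.73}`, `n ∈ {65, 89}`.

Error *shares* divide each error type by the total number of errors, so the
two shares of a cohort always sum to one; with zero errors they are
reported as absent, not 0/0. Sensitivity divides correct detections by
encounter slots (participants × polyps). PPV is true-positive marks over
all marks, with multiple marks inside one box by one participant
deduplicated to a single true positive; this is the conventional
definition, adopted here explicitly because the source analyses kept their
PPV definitions in supplementary material.

Cohorts are compared on 2×2 tables (error mix: gaze vs cognitive counts;
sensitivity: correct vs missed) with Fisher's exact test by default —
χ², with or without Yates' correction, sits behind a flag. Report cells
render as `"73.0% [62.6–81.9] (65/89)"`: percentages to one decimal,
rounded half away from zero at the reporting layer only; all internal
arithmetic is full precision.

One numerical note on validation: the suite checks the χ² p-value against a
Monte-Carlo permutation null. That null is discrete, so the continuous χ²
p cannot agree with the raw permutation p to Monte-Carlo precision; the
comparison therefore uses the exact conditional mid-p (half weight on the
tie atom) on tables with expected counts around ten or more, with a small
explicit allowance (0.02) for the remaining continuity gap. Fisher's exact
p, by contrast, is checked for *exact* equality against direct
hypergeometric enumeration — exhaustively for every margin set with
N ≤ 30 (46,375 tables) and on a seeded random sample of margin sets up to
N = 60; the full sweep to N = 60 would add several minutes of pure
recomputation without changing what is being demonstrated.

## The synthetic study generator

Real study data of this kind are access-restricted, so the package ships a
generator that emulates the design end to end and carries per-encounter
ground-truth labels; every pipeline stage is validated against it.

The default configuration reproduces the study shape: 7 trainees and 4
medical students; 20 positive 1920×1080 images holding 25 polyps and 5
negative images; 12 s of viewing at 120 Hz. The per-encounter generative
model is two Bernoulli draws: with probability `p_fixate_polyp` a fixation
is planted inside the box; given that, with probability
`p_recognize_given_fixation` a mark is placed at the fixation centre. The
default probabilities are back-calculated from the observed Phase-1 rates
(trainees: sensitivity 49.1% with 27% of errors gaze-type gives
`p_fixate ≈ 0.863`, `p_recognize ≈ 0.569`; students: 35.0% and 44.6% give
`0.710` and `0.493`), and the false-mark intensities per negative image
(1.5 and 3.2) approximate the observed cohort PPVs. These are the study
conditions, not tuning knobs.

Scanpaths are built from planted fixations plus background fixations at
uniform-random locations strictly outside every box (rejection sampling),
with log-normal durations (median 250 ms, σ = 0.4 — a standard free-viewing
regime — floored at 80 ms so every planted fixation clears detection).
Consecutive fixation centres are kept at least `saccade_step = 75` px apart
(three dispersion thresholds) and connected by 1–2 intermediate samples, so
transitions always break the dispersion chain and can never themselves form
a fixation. Within-fixation jitter is isotropic Gaussian (σ = 4 px),
*recentred to zero mean* per fixation, a deliberately stronger guarantee
than truncation: the sample mean sits exactly on the planned centre, so a
planted centroid is inside its box by construction. Binocular disparity
(σ = 2 px per sample) is applied antisymmetrically — left eye `+d`, right
eye `−d` — so the binocular mean recovers the true gaze point; each eye
then drops out independently at `missing_rate = 0.02`. Boxes smaller than
four jitter sigmas per side are rejected with advice rather than silently
producing fixations that leak out of them.

Randomness is a single root seed with per-(group, participant, trial)
sub-streams derived by counter hashing, so a fixed seed yields
byte-identical files and adding a participant never perturbs anyone else's
data.

What the generator does *not* emulate: saliency-driven viewing (background
fixations are spatially uniform), centre bias, smooth pursuit, real blink
dynamics (dropout is i.i.d.), off-target marks on positive images (false
marks arise only on negative images), or inter-participant skill
variation beyond the cohort probabilities. Passing the recovery tests
therefore shows the pipeline is a faithful implementation of its own
definitions under realistic geometry and noise — not that those definitions
capture every property of human scanpaths.

## Problem sizes used in validation

The suite checks fixation detection against an independent exhaustive
maximal-run oracle on 500 random streams of up to 2,000 samples with
randomized jitter, jump rate and missingness; trial classification against
a naive double-loop oracle; and end-to-end parameter recovery on a study
scaled to 2,000 encounters (two cohorts of 40 participants over the 25
polyps) at `p_fixate = 0.7`, `p_recognize = 0.5`, where the recovered
outcome mix must fall within three binomial standard errors of the analytic
expectation (0.35 correct, 0.35 cognitive, 0.30 gaze) and agreement with
the planted labels must exceed 99%; with noise switched off, agreement is
exactly 100%. These sizes were chosen to make the binomial bands tight
enough to be informative while keeping the whole suite comfortably
re-runnable.

## Heat maps

Cumulative-fixation heat maps deposit one unit of mass per fixation as an
isotropic Gaussian, discretized exactly (CDF differences per pixel), so the
grid total counts fixations up to border truncation of under 1%. Duration
weighting exists behind a flag but the default is count-based, matching the
"more fixations" reading of such visualizations. The default kernel
σ = 25 px simply reuses the dispersion threshold; it is cosmetic, carries
no analytic weight, and the numeric grid is always written alongside the
PNG so nothing downstream ever parses pixels.

## Known limitations

* The pairwise-chain dispersion rule is one defensible reading; results at
  the margins (long slow drifts) can differ from window-dispersion I-DT.
* PPV uses the conventional pooled-mark definition described above; a
  per-polyp supplementary definition could differ.
* Gaze during the annotation phase is excluded from fixation analysis by
  design — the taxonomy concerns search-phase perception — so the package
  does not model mark-time re-inspection.
* The generator's spatial uniformity makes background fixations slightly
  more dispersed than human ones; do not use it to benchmark saliency
  models.
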