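# Outcome statistics: per-polyp sensitivity, error composition and PPV as
# binomial proportions with exact Clopper-Pearson confidence intervals, and
# 2x2 group comparisons by Fisher's exact or Pearson's chi-square test.

#' Exact Clopper-Pearson binomial confidence interval
#'
#' The two-sided exact interval from Beta quantiles: with `k` successes in
#' `n` trials and `alpha = 1 - level`, the lower bound is the `alpha/2`
#' quantile of `Beta(k, n - k + 1)` (0 when `k = 0`) and the upper bound the
#' `1 - alpha/2` quantile of `Beta(k + 1, n - k)` (1 when `k = n`). Coverage
#' is at least `level` for every true proportion (conservative).
#'
#' @param successes,trials Non-negative counts, `successes <= trials`,
#'   `trials >= 1` (vectorized).
#' @param level Confidence level in (0, 1), default 0.95.
#' @return A 2-column matrix with columns `lower`, `upper` (a named length-2
#'   vector for scalar input).
#' @examples
#' clopper_pearson(65, 89)   # 0.626 to 0.819
#' @export
clopper_pearson <- function(successes, trials, level = 0.95) {
  if (length(level) != 1 || !is.finite(level) || level <= 0 || level >= 1) {
    stop_("level must be in (0, 1)")
  }
  k <- successes; n <- trials
  if (any(!is.finite(k)) || any(!is.finite(n)) || any(k < 0) || any(n < 1) ||
      any(k > n) || any(k != round(k)) || any(n != round(n))) {
    stop_("need integer counts with 0 <= successes <= trials, trials >= 1")
  }
  a <- 1 - level
  lower <- ifelse(k == 0, 0, stats::qbeta(a / 2, k, n - k + 1))
  upper <- ifelse(k == n, 1, stats::qbeta(1 - a / 2, k + 1, n - k))
  if (length(k) == 1 && length(n) == 1) {
    c(lower = lower, upper = upper)
  } else {
    cbind(lower = lower, upper = upper)
  }
}

#' Binomial proportion with exact confidence interval
#'
#' @inheritParams clopper_pearson
#' @return A `proportion_estimate`: list with `successes`, `trials`,
#'   `proportion`, `ci_low`, `ci_high`, `level`.
#' @export
proportion_estimate <- function(successes, trials, level = 0.95) {
  ci <- clopper_pearson(successes, trials, level)
  structure(list(successes = as.integer(successes),
                 trials = as.integer(trials),
                 proportion = successes / trials,
                 ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                 level = level),
            class = "proportion_estimate")
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(format_prop_cell(x), "\n")
  invisible(x)
}

#' Format a proportion as a report cell
#'
#' Renders `"73.0% [62.6-81.9] (65/89)"`-style cells: percentage and exact
#' interval bounds to one decimal, rounded half away from zero.
#'
#' @param pe A [proportion_estimate()].
#' @return A character scalar.
#' @export
format_prop_cell <- function(pe) {
  f <- function(v) formatC(round_half_up(100 * v, 1), format = "f", digits = 1)
  sprintf("%s%% [%s–%s] (%d/%d)", f(pe$proportion), f(pe$ci_low),
          f(pe$ci_high), pe$successes, pe$trials)
}

as_2x2 <- function(t) {
  if (is.matrix(t)) {
    if (!all(dim(t) == c(2, 2))) stop_("need a 2x2 table")
    m <- t
  } else if (length(t) == 4) {
    m <- matrix(as.numeric(t), 2, 2, byrow = TRUE)
  } else {
    stop_("need a 2x2 table or a length-4 vector (a, b, c, d, row-wise)")
  }
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m))) {
    stop_("table entries must be non-negative integers")
  }
  if (sum(m) == 0) stop_("table must have at least one positive entry")
  m
}

#' Fisher's exact test for a 2x2 table, two-sided
#'
#' Two-sided p-value summing hypergeometric probabilities (margins fixed) of
#' every table no more probable than the observed one.
#'
#' @param t A 2x2 matrix of counts, or a length-4 vector `(a, b, c, d)` read
#'   row-wise (rows = groups, columns = outcome categories).
#' @return The p-value in (0, 1].
#' @examples
#' fisher_exact_two_sided(c(24, 65, 29, 36))
#' @export
fisher_exact_two_sided <- function(t) {
  m <- as_2x2(t)
  stats::fisher.test(m, alternative = "two.sided")$p.value
}

#' Pearson chi-square test for a 2x2 table
#'
#' @param t A 2x2 table as in [fisher_exact_two_sided()]; all margins must be
#'   positive.
#' @param yates Apply Yates' continuity correction (reduce `|O - E|` by 0.5
#'   before squaring). Default `FALSE`.
#' @return List with `statistic` (1 df) and `p_value`.
#' @export
chi_squared_2x2 <- function(t, yates = FALSE) {
  m <- as_2x2(t)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop_("chi-square test needs all row and column margins positive")
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = yates))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value))
}

#' Summarize one cohort's encounter outcomes
#'
#' Pools all of a group's participant-polyp encounters: per-polyp sensitivity
#' (correct detections over encounter slots), the split of recognition errors
#' into gaze and cognitive errors (denominator = total errors), and — when
#' mark data are supplied — positive predictive value, each with an exact
#' Clopper-Pearson interval. With zero errors the error shares are undefined
#' and returned as `NULL`, not 0/0.
#'
#' @param outcomes Outcome rows for one group (see [evaluate_trial()]).
#' @param n_participants,n_polyps Cohort design; `n_participants * n_polyps`
#'   must equal the number of encounter rows (conservation).
#' @param false_positives Optional false-positive mark rows; enables PPV.
#'   True-positive marks are deduplicated to one per marked encounter.
#' @param level Confidence level.
#' @return A `gazerr_summary` list: `group`, `n_participants`, `n_polyps`,
#'   `counts` (named: CORRECT, GAZE_ERROR, COGNITIVE_ERROR), `sensitivity`,
#'   `gaze_error_share`, `cognitive_error_share`, `ppv` (each a
#'   [proportion_estimate()] or `NULL`).
#' @export
summarize_group <- function(outcomes, n_participants, n_polyps,
                            false_positives = NULL, level = 0.95) {
  slots <- n_participants * n_polyps
  if (slots <= 0) stop_("group has zero encounter slots")
  if (nrow(outcomes) != slots) {
    stop_("outcome conservation violated: %d rows for %d participants x %d polyps = %d slots",
          nrow(outcomes), n_participants, n_polyps, slots)
  }
  if (!all(outcomes$outcome %in% OUTCOME_LEVELS)) {
    stop_("unknown outcome label: %s",
          setdiff(unique(outcomes$outcome), OUTCOME_LEVELS)[1])
  }
  counts <- vapply(OUTCOME_LEVELS, function(l) sum(outcomes$outcome == l), 0L)
  errors <- counts[["GAZE_ERROR"]] + counts[["COGNITIVE_ERROR"]]
  shares <- if (errors > 0) {
    list(gaze = proportion_estimate(counts[["GAZE_ERROR"]], errors, level),
         cognitive = proportion_estimate(counts[["COGNITIVE_ERROR"]], errors, level))
  } else {
    list(gaze = NULL, cognitive = NULL)
  }
  ppv <- NULL
  if (!is.null(false_positives)) {
    tp <- sum(outcomes$marked)
    n_marks <- tp + nrow(false_positives)
    if (n_marks > 0) ppv <- proportion_estimate(tp, n_marks, level)
  }
  structure(list(group = as.character(outcomes$group[1] %||% NA_character_),
                 n_participants = n_participants, n_polyps = n_polyps,
                 counts = counts,
                 sensitivity = proportion_estimate(counts[["CORRECT"]], slots, level),
                 gaze_error_share = shares$gaze,
                 cognitive_error_share = shares$cognitive,
                 ppv = ppv),
            class = "gazerr_summary")
}

#' @export
print.gazerr_summary <- function(x, ...) {
  cat(sprintf("<gazerr_summary> group '%s': %d participants x %d polyps\n",
              x$group, x$n_participants, x$n_polyps))
  cat("  sensitivity:     ", format_prop_cell(x$sensitivity), "\n")
  if (!is.null(x$gaze_error_share)) {
    cat("  gaze errors:     ", format_prop_cell(x$gaze_error_share), "\n")
    cat("  cognitive errors:", format_prop_cell(x$cognitive_error_share), "\n")
  } else {
    cat("  no recognition errors; error shares undefined\n")
  }
  if (!is.null(x$ppv)) cat("  PPV:             ", format_prop_cell(x$ppv), "\n")
  invisible(x)
}

#' Synthesize an outcome table from published counts
#'
#' Builds a minimal outcome table carrying given outcome totals, so cohort
#' summaries can be recomputed from printed counts (e.g. reproducing a
#' published error-composition table) through the same code path as raw data.
#'
#' @param group Group label.
#' @param n_correct,n_gaze,n_cognitive Outcome totals; must sum to
#'   `n_participants * n_polyps`.
#' @param n_participants,n_polyps Cohort design.
#' @return An outcome data frame accepted by [summarize_group()].
#' @export
outcomes_from_counts <- function(group, n_correct, n_gaze, n_cognitive,
                                 n_participants, n_polyps) {
  total <- n_correct + n_gaze + n_cognitive
  if (total != n_participants * n_polyps) {
    stop_("counts sum to %d but the design has %d encounter slots",
          total, n_participants * n_polyps)
  }
  outcome <- rep(OUTCOME_LEVELS, times = c(n_correct, n_gaze, n_cognitive))
  data.frame(participant_id = NA_character_, group = group,
             image_id = NA_character_,
             polyp_id = sprintf("slot%04d", seq_len(total)),
             fixated = outcome != "GAZE_ERROR",
             marked = outcome == "CORRECT",
             outcome = outcome)
}

#' Compose the cohort comparison report
#'
#' Assembles per-group and pooled rows of formatted proportion cells
#' (sensitivity, gaze- and cognitive-error shares, PPV when available) plus
#' pairwise between-group tests: the error mix (gaze vs cognitive) and the
#' sensitivity contrast on 2x2 tables.
#'
#' @param summaries List of [summarize_group()] results (>= 1).
#' @param test `"fisher"` (default), `"chi2"` or `"chi2-yates"`.
#' @param level Confidence level used for the pooled row.
#' @return A `gazerr_report`: list with `table` (data frame of formatted
#'   cells, one row per group plus a pooled row when there are >= 2 groups)
#'   and `comparisons` (data frame: `metric`, `groups`, `p_value`, `test`;
#'   empty for a single group).
#' @export
compose_report <- function(summaries, test = c("fisher", "chi2", "chi2-yates"),
                           level = 0.95) {
  test <- match.arg(test)
  if (length(summaries) < 1) stop_("need at least one group summary")
  cell <- function(pe) if (is.null(pe)) "" else format_prop_cell(pe)
  row_of <- function(s, label) {
    data.frame(group = label,
               sensitivity = cell(s$sensitivity),
               gaze_errors = cell(s$gaze_error_share),
               cognitive_errors = cell(s$cognitive_error_share),
               ppv = cell(s$ppv))
  }
  tab <- do.call(rbind, lapply(summaries, function(s) row_of(s, s$group)))
  comparisons <- data.frame(metric = character(), groups = character(),
                            p_value = numeric(), test = character())
  if (length(summaries) >= 2) {
    pooled_counts <- Reduce(`+`, lapply(summaries, `[[`, "counts"))
    pooled_slots <- sum(vapply(summaries,
                               function(s) s$n_participants * s$n_polyps, 0))
    pooled <- summarize_group(
      data.frame(participant_id = NA, group = "pooled", image_id = NA,
                 polyp_id = sprintf("s%05d", seq_len(pooled_slots)),
                 fixated = rep(OUTCOME_LEVELS != "GAZE_ERROR", pooled_counts),
                 marked = rep(OUTCOME_LEVELS == "CORRECT", pooled_counts),
                 outcome = rep(OUTCOME_LEVELS, pooled_counts)),
      n_participants = 1, n_polyps = pooled_slots, level = level)
    tab <- rbind(tab, row_of(pooled, "pooled"))
    run_test <- function(m) {
      switch(test,
             fisher = fisher_exact_two_sided(m),
             chi2 = chi_squared_2x2(m, yates = FALSE)$p_value,
             `chi2-yates` = chi_squared_2x2(m, yates = TRUE)$p_value)
    }
    for (i in seq_len(length(summaries) - 1)) {
      for (j in seq(i + 1, length(summaries))) {
        a <- summaries[[i]]; b <- summaries[[j]]
        pair <- sprintf("%s vs %s", a$group, b$group)
        if (!is.null(a$gaze_error_share) && !is.null(b$gaze_error_share)) {
          m <- rbind(c(a$counts[["GAZE_ERROR"]], a$counts[["COGNITIVE_ERROR"]]),
                     c(b$counts[["GAZE_ERROR"]], b$counts[["COGNITIVE_ERROR"]]))
          comparisons <- rbind(comparisons,
                               data.frame(metric = "error_mix", groups = pair,
                                          p_value = run_test(m), test = test))
        }
        m <- rbind(c(a$counts[["CORRECT"]],
                     a$n_participants * a$n_polyps - a$counts[["CORRECT"]]),
                   c(b$counts[["CORRECT"]],
                     b$n_participants * b$n_polyps - b$counts[["CORRECT"]]))
        comparisons <- rbind(comparisons,
                             data.frame(metric = "sensitivity", groups = pair,
                                        p_value = run_test(m), test = test))
      }
    }
  }
  rownames(tab) <- NULL
  structure(list(table = tab, comparisons = comparisons, level = level),
            class = "gazerr_report")
}

#' @export
print.gazerr_report <- function(x, ...) {
  cat("Recognition errors and per-polyp sensitivity by cohort\n\n")
  print(x$table, row.names = FALSE, right = FALSE)
  if (nrow(x$comparisons) > 0) {
    cat("\nPairwise comparisons\n")
    cmp <- x$comparisons
    cmp$p_value <- signif(cmp$p_value, 3)
    print(cmp, row.names = FALSE, right = FALSE)
  }
  invisible(x)
}

#' Write a report as TSV and plain text
#'
#' @param report A [compose_report()] result.
#' @param path_tsv,path_txt Output paths (either may be `NULL` to skip).
#' @return `report`, invisibly.
#' @export
write_report <- function(report, path_tsv = NULL, path_txt = NULL) {
  if (!is.null(path_tsv)) write_tsv(report$table, path_tsv)
  if (!is.null(path_txt)) {
    con <- file(path_txt, "w", encoding = "UTF-8")
    on.exit(close(con))
    sink(con)
    print(report)
    sink()
  }
  invisible(report)
}
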