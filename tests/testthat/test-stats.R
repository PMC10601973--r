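test_that("Clopper-Pearson intervals reproduce published error-share bounds", {
  expect_equal(round(clopper_pearson(65, 89), 3),
               c(lower = 0.626, upper = 0.819))
  expect_equal(round(clopper_pearson(24, 89), 3),
               c(lower = 0.181, upper = 0.374))
  # closed forms at the boundary counts
  ci0 <- clopper_pearson(0, 10)
  expect_equal(unname(ci0[1]), 0)
  expect_equal(unname(ci0[2]), 1 - 0.025^(1 / 10))
  ci_n <- clopper_pearson(10, 10)
  expect_equal(unname(ci_n[1]), 0.025^(1 / 10))
  expect_equal(unname(ci_n[2]), 1)
  expect_error(clopper_pearson(5, 4), "successes")
  expect_error(clopper_pearson(1, 10, level = 1), "level")
})

test_that("Clopper-Pearson duality and conservative coverage hold", {
  for (n in c(1, 2, 5, 17, 65, 89, 154, 200)) {
    k <- 0:n
    ci <- clopper_pearson(k, rep(n, n + 1))
    expect_equal(ci[, "lower"], 1 - rev(ci[, "upper"]), tolerance = 1e-12)
    expect_true(all(ci[, "lower"] <= k / n + 1e-12))
    expect_true(all(ci[, "upper"] >= k / n - 1e-12))
  }
  withr::local_seed(123)
  for (p in c(0.1, 0.5, 0.73)) {
    for (n in c(65, 89)) {
      k <- rbinom(10000, n, p)
      ci <- clopper_pearson(k, rep(n, length(k)))
      cover <- mean(ci[, "lower"] <= p & p <= ci[, "upper"])
      se <- sqrt(0.95 * 0.05 / 10000)
      expect_gte(cover, 0.95 - 3 * se)
    }
  }
})

test_that("Fisher two-sided p matches printed value and exhaustive enumeration", {
  expect_equal(fisher_exact_two_sided(c(24, 65, 29, 36)), 0.0264,
               tolerance = 0.002)
  expect_equal(fisher_exact_two_sided(c(5, 5, 5, 5)), 1.0)
  expect_equal(fisher_exact_two_sided(c(2, 0, 0, 2)), 1 / 3, tolerance = 1e-12)

  withr::local_seed(21)
  for (rep in 1:80) {
    m <- matrix(rpois(4, sample(1:8, 1)), 2)
    if (sum(m) == 0 || sum(m) > 60) next
    expect_equal(fisher_exact_two_sided(m), oracle_fisher(m),
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact_two_sided(c(-1, 2, 3, 4)), "non-negative")
})

test_that("chi-square statistic matches hand evaluation and a permutation null", {
  ct <- chi_squared_2x2(c(24, 65, 29, 36))
  # hand evaluation with margins 89/65 and 53/101
  e <- outer(c(89, 65), c(53, 101)) / 154
  o <- matrix(c(24, 65, 29, 36), 2, byrow = TRUE)
  expect_equal(ct$statistic, sum((o - e)^2 / e))
  expect_equal(round(ct$statistic, 2), 5.18)

  prop <- chi_squared_2x2(c(10, 20, 30, 60))
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p_value, 1)
  expect_error(chi_squared_2x2(c(0, 0, 3, 4)), "margin")

  # Monte-Carlo permutation null: the chi-square p approximates the exact
  # conditional mid-p (half weight on the tie atom). The null is discrete, so
  # beyond Monte-Carlo noise a continuity gap remains; 0.02 covers it at
  # expected counts of ten and up.
  withr::local_seed(6)
  B <- 20000
  for (m in list(matrix(c(14, 22, 28, 13), 2, byrow = TRUE),
                 matrix(c(25, 16, 12, 30), 2, byrow = TRUE))) {
    obs <- chi_squared_2x2(m)$statistic
    grp <- rep(1:2, times = rowSums(m))
    val <- rep(c(1, 2, 1, 2), times = as.vector(t(m)))
    stat <- replicate(B, {
      v <- sample(val)
      tab <- table(factor(grp, 1:2), factor(v, 1:2))
      e2 <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      sum((tab - e2)^2 / e2)
    })
    p_mc <- mean(stat > obs + 1e-9) + 0.5 * mean(abs(stat - obs) <= 1e-9)
    se <- sqrt(max(p_mc * (1 - p_mc), 0.01) / B)
    expect_lt(abs(p_mc - chi_squared_2x2(m)$p_value), 3 * se + 0.02)
  }
})

test_that("group summaries pool counts into sensitivity and error shares", {
  tr <- summarize_group(outcomes_from_counts("trainee", 86, 24, 65, 7, 25),
                        7, 25)
  expect_equal(tr$sensitivity$proportion, 86 / 175)
  expect_equal(format_prop_cell(tr$sensitivity), "49.1% [41.5–56.8] (86/175)")
  expect_equal(tr$gaze_error_share$proportion, 24 / 89)
  expect_equal(tr$cognitive_error_share$proportion, 65 / 89)
  expect_equal(tr$gaze_error_share$successes + tr$cognitive_error_share$successes,
               89)

  all_ok <- summarize_group(outcomes_from_counts("g", 20, 0, 0, 4, 5), 4, 5)
  expect_equal(all_ok$sensitivity$proportion, 1)
  expect_null(all_ok$gaze_error_share)
  expect_null(all_ok$cognitive_error_share)

  expect_error(summarize_group(outcomes_from_counts("g", 10, 5, 5, 4, 5), 4, 6),
               "conservation")
  expect_error(outcomes_from_counts("g", 10, 5, 5, 4, 4), "slots")
})

test_that("summaries compute PPV from deduplicated marks when available", {
  out <- outcomes_from_counts("g", 6, 2, 2, 2, 5)
  fp <- data.frame(participant_id = "a", image_id = "neg",
                   x = runif(4), y = runif(4))
  s <- summarize_group(out, 2, 5, false_positives = fp)
  expect_equal(s$ppv$successes, 6)   # one TP per marked encounter
  expect_equal(s$ppv$trials, 10)
  expect_equal(s$ppv$proportion, 0.6)
})

test_that("the composed report reproduces published cells and comparisons", {
  tr <- summarize_group(outcomes_from_counts("trainee", 86, 24, 65, 7, 25), 7, 25)
  st <- summarize_group(outcomes_from_counts("student", 35, 29, 36, 4, 25), 4, 25)
  rep <- compose_report(list(tr, st))
  tab <- rep$table
  expect_equal(tab$gaze_errors,
               c("27.0% [18.1–37.4] (24/89)", "44.6% [32.3–57.5] (29/65)",
                 "34.4% [27.0–42.5] (53/154)"))
  expect_equal(tab$cognitive_errors,
               c("73.0% [62.6–81.9] (65/89)", "55.4% [42.5–67.7] (36/65)",
                 "65.6% [57.5–73.0] (101/154)"))
  expect_equal(tab$sensitivity[1:2],
               c("49.1% [41.5–56.8] (86/175)", "35.0% [25.7–45.2] (35/100)"))
  mix <- rep$comparisons[rep$comparisons$metric == "error_mix", ]
  expect_equal(mix$p_value, fisher_exact_two_sided(c(24, 65, 29, 36)))

  single <- compose_report(list(tr))
  expect_equal(nrow(single$comparisons), 0)
  expect_equal(nrow(single$table), 1)  # no pooled row for one group

  chi <- compose_report(list(tr, st), test = "chi2")
  expect_equal(chi$comparisons$p_value[1],
               chi_squared_2x2(c(24, 65, 29, 36))$p_value)
})

test_that("error shares always sum to one when errors exist", {
  withr::local_seed(44)
  for (rep in 1:25) {
    slots <- sample(20:200, 1)
    g <- sample(0:(slots - 1), 1)
    c2 <- sample(0:(slots - g - 1), 1)
    if (g + c2 == 0) next
    s <- summarize_group(outcomes_from_counts("g", slots - g - c2, g, c2,
                                              1, slots), 1, slots)
    expect_equal(s$gaze_error_share$proportion +
                   s$cognitive_error_share$proportion, 1)
  }
})
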