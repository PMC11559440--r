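day_start <- function(d) as.POSIXct(paste(d, "00:00:00"), tz = "UTC")

test_that("split_days: total days, analysis-day threshold at exactly 5280 recordings", {
  full <- mk_series(rep("Lying", 5760), start = day_start("2019-03-01"))
  d <- split_days(full)
  expect_equal(nrow(d), 1L)
  expect_equal(d$hours_of_data, 24)
  expect_true(d$is_analysis_day)

  short <- mk_series(rep("Lying", 5279), start = day_start("2019-03-01"))
  expect_false(split_days(short)$is_analysis_day)
  exact <- mk_series(rep("Lying", 5280), start = day_start("2019-03-01"))
  expect_true(split_days(exact)$is_analysis_day)

  # a single recording at 23:59:45 is a total day but not an analysis day
  one <- mk_series("Lying", start = day_start("2019-03-01") + 86385)
  d1 <- split_days(one)
  expect_equal(nrow(d1), 1L)
  expect_false(d1$is_analysis_day)
  expect_equal(nrow(split_days(full[0])), 0L)
})

test_that("duration statistics: degenerate and hand-computed cases", {
  all_lying <- mk_series(rep("Lying", 5760), start = day_start("2019-03-01"))
  expect_equal(duration_stats(all_lying, "WD")[group == "Lying", hours], 24)
  expect_equal(duration_stats(all_lying, "DT")[group == "Lying", hours], 12)
  expect_equal(duration_stats(all_lying, "NT")[group == "Lying", hours], 12)
  expect_equal(duration_stats(all_lying, "WD")[group == "Upright", hours], 0)

  # two analysis days with Lying proportions 0.5 and 0.25 -> 24 * 0.375 = 9 h
  d1 <- c(rep("Lying", 2880), rep("Reclined", 2880))
  d2 <- c(rep("Lying", 1440), rep("Reclined", 4320))
  s <- rbind(mk_series(d1, start = day_start("2019-03-01")),
             mk_series(d2, start = day_start("2019-03-02")))
  expect_equal(duration_stats(s, "WD")[group == "Lying", hours], 9)

  # DT all Upright, NT all Lying
  diurnal <- full_day_series(function(ts) ifelse(posturekit:::in_daytime(ts),
                                                 "Upright", "Lying"))
  expect_equal(duration_stats(diurnal, "DT")[group == "Upright", hours], 12)
  expect_equal(duration_stats(diurnal, "NT")[group == "Upright", hours], 0)
  expect_equal(duration_stats(diurnal, "WD")[group == "Upright", hours], 12)
})

test_that("transition counting follows the 6-type physical-transition rule", {
  tc <- function(groups, gaps_after = integer(0)) {
    s <- mk_series(groups, gaps_after = gaps_after)
    transition_count(s$group, s$timestamp)
  }
  expect_equal(tc(c("Lying", "Reclined", "Upright")), 2L)
  expect_equal(tc(c("Lying", "Unknown", "Reclined")), 0L)
  expect_equal(tc(c("Lying", "UserDefined", "Reclined")), 0L)
  expect_equal(tc(rep("Lying", 10)), 0L)
  expect_equal(tc(c("Lying", "Reclined"), gaps_after = 1L), 0L)  # across a gap
})

test_that("transition count equals the brute-force pair scan on random series", {
  set.seed(99)
  for (rep in 1:30) {
    s <- random_series(200, gap_prob = 0.03)
    expect_equal(transition_count(s$group, s$timestamp),
                 brute_transitions(s$group, s$timestamp))
  }
})

test_that("FPT: transitions divided by actual hours, averaged over analysis days", {
  # complete day with 48 transitions -> 2 tph (49 alternating blocks)
  g <- rep(rep_len(c("Lying", "Reclined"), 49), times = c(rep(118, 48), 96))
  s <- mk_series(g, start = day_start("2019-03-01"))
  expect_equal(nrow(s), 5760L)
  expect_equal(fpt_stats(s, "WD")$fpt, 48 / 24)

  # 22-hour day (5280 recordings) with 11 transitions -> 0.5 tph
  g2 <- rep(c("Lying", "Reclined", "Lying", "Upright"), each = 440, times = 3)
  s2 <- mk_series(g2, start = day_start("2019-03-01"))
  expect_equal(nrow(s2), 5280L)
  expect_equal(transition_count(s2$group, s2$timestamp), 11L)
  expect_equal(fpt_stats(s2, "WD")$fpt, 11 / 22)

  # constant series -> 0 tph
  expect_equal(fpt_stats(mk_series(rep("Lying", 5760),
                                   start = day_start("2019-03-01")), "WD")$fpt, 0)
})

test_that("WD durations sum to 24 h and DT + NT = WD on complete days", {
  set.seed(5)
  s <- data.table::rbindlist(lapply(1:4, function(i) {
    g <- sample(posture_group_levels, 3 * 5760, replace = TRUE)
    mk_series(g, mrn = sprintf("P%d", i), start = day_start("2019-03-01"))
  }))
  sums <- patient_summaries(s)
  wd_cols <- paste0(posture_group_levels, "-WD")
  expect_equal(rowSums(as.matrix(sums[, wd_cols, with = FALSE])), rep(24, 4),
               ignore_attr = TRUE)
  for (g in posture_group_levels)
    expect_equal(sums[[paste0(g, "-WD")]],
                 sums[[paste0(g, "-DT")]] + sums[[paste0(g, "-NT")]])
  expect_equal(sums$`Rest-DT`, sums$`Lying-DT` + sums$`Reclined-DT`)
})

test_that("patients are retained iff they have an analysis day; retention shrinks with the threshold", {
  s <- rbind(mk_series(rep("Lying", 5760), mrn = "P1", start = day_start("2019-03-01")),
             mk_series(rep("Lying", 3000), mrn = "P2", start = day_start("2019-03-01")))
  expect_message(sums <- patient_summaries(s), "no analysis day")
  expect_equal(sums$mrn, "P1")
  expect_equal(attr(sums, "n_excluded_no_analysis_days"), 1L)
  expect_equal(sums$total_days, 1L)

  # threshold monotonicity: raising the threshold cannot grow the retained set
  set.seed(8)
  s2 <- data.table::rbindlist(lapply(1:6, function(i) {
    n <- sample(c(3000, 5300, 5760), 1)
    mk_series(rep("Lying", n), mrn = sprintf("P%d", i),
              start = day_start("2019-03-01"))
  }))
  retained <- sapply(c(12, 22, 23.9), function(th)
    nrow(suppressMessages(patient_summaries(s2, threshold_hours = th))))
  expect_true(all(diff(retained) <= 0))
})

test_that("quantity regression recovers exact fits and matches the normal equations", {
  s <- data.table::data.table(total_days = c(2, 5, 10, 20),
                              analysis_days = 0.74 * c(2, 5, 10, 20) - 1.14)
  fit <- quantity_regression(s)
  expect_equal(fit$intercept, -1.14, tolerance = 1e-10)
  expect_equal(fit$slope, 0.74, tolerance = 1e-10)

  ident <- data.table::data.table(total_days = 1:8, analysis_days = 1:8)
  fit2 <- quantity_regression(ident)
  expect_equal(fit2$slope, 1, tolerance = 1e-12)
  expect_equal(fit2$intercept, 0, tolerance = 1e-12)

  set.seed(21)
  x <- sample(1:30, 40, replace = TRUE)
  y <- pmax(0, 0.7 * x - 1 + rnorm(40))
  r <- quantity_regression(data.table::data.table(total_days = x, analysis_days = y))
  # closed-form OLS oracle
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  expect_equal(r$slope, beta, tolerance = 1e-12)
  expect_equal(r$intercept, alpha, tolerance = 1e-12)

  expect_error(quantity_regression(s[1]), "distinct total_days")
})

test_that("generated archetype daytime Upright weight is recovered in Upright-DT", {
  w <- 0.45
  a <- archetype_spec("uprighty", c(0.30, 0.20, w, 0.05), c(0.6, 0.2, 0.1, 0.1),
                      mean_bout_len = 20, noise_rate = 0)
  p <- generate_patient_series(a, 20, day_start("2019-03-01"), "P1", seed = 31)
  ser <- smooth_majority_vote(consolidate_recordings(p$recordings))
  sums <- patient_summaries(ser)
  expect_lt(abs(sums$`Upright-DT` - 12 * w), 0.5)
})
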