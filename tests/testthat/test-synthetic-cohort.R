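test_that("archetype_spec validates its invariants", {
  expect_error(archetype_spec("x", c(1, 0, 0), c(1, 0, 0, 0), 10), "4 nonnegative")
  expect_error(archetype_spec("x", c(0.5, 0.5, 0.1, 0), c(1, 0, 0, 0), 10),
               "summing to 1")
  expect_error(archetype_spec("x", c(1, 0, 0, 0), c(1, 0, 0, 0), 0.5), "mean_bout_len")
  expect_error(archetype_spec("x", c(1, 0, 0, 0), c(1, 0, 0, 0), 10,
                              noise_rate = 0.5), "noise_rate")
})

test_that("degenerate daytime weights force Upright for every daytime recording", {
  a <- archetype_spec("up", c(0, 0, 1, 0), c(1, 0, 0, 0), 30, noise_rate = 0)
  p <- generate_patient_series(a, 1, t0, "P1", seed = 5)
  ser <- consolidate_recordings(p$recordings)
  dt_rows <- posturekit:::in_daytime(ser$timestamp)
  expect_true(all(ser$group[dt_rows] == "Upright"))
})

test_that("nighttime Lying weight 1 yields exactly 12 h Lying-NT", {
  a <- archetype_spec("ly", c(0, 0, 1, 0), c(1, 0, 0, 0), 30, noise_rate = 0)
  p <- generate_patient_series(a, 1, t0, "P1", seed = 6)
  ser <- smooth_majority_vote(consolidate_recordings(p$recordings))
  sums <- patient_summaries(ser)
  expect_equal(sums$`Lying-NT`, 12)
  expect_equal(sums$`Upright-DT`, 12)
})

test_that("empirical daytime group proportions track the weights (LLN check)", {
  w <- c(Lying = 0.25, Reclined = 0.45, Upright = 0.25, Unknown = 0.05)
  a <- archetype_spec("mix", unname(w), c(0.7, 0.2, 0.05, 0.05),
                      mean_bout_len = 20, noise_rate = 0, perm_rate = 0,
                      long_perm_rate = 0)
  p <- generate_patient_series(a, 20, t0, "P1", seed = 12)
  ser <- consolidate_recordings(p$recordings)
  # oracle: direct tally of generated labels in the daytime window
  dt_rows <- ser[posturekit:::in_daytime(timestamp)]
  props <- table(factor(dt_rows$group, levels = names(w))) / nrow(dt_rows)
  expect_true(all(abs(as.numeric(props) - w) < 0.03))
})

test_that("recordings lie on the grid inside the admission window, with daily device changeover", {
  a <- default_archetypes()[["active"]]
  p <- generate_patient_series(a, 3, t0, "P7", seed = 2)
  expect_equal(nrow(p$recordings), 3 * 5760)
  expect_true(all(as.numeric(p$recordings$timestamp) %% 15 == 0))
  expect_true(all(p$recordings$timestamp >= p$admission$admit_time))
  expect_true(all(p$recordings$timestamp < p$admission$discharge_time))
  dev_by_day <- p$recordings[, data.table::uniqueN(device_serial),
                             by = .(date = as.Date(timestamp, tz = "UTC"))]
  expect_true(all(dev_by_day$V1 == 1))
  expect_equal(data.table::uniqueN(p$recordings$device_serial), 3L)
  expect_gt(data.table::uniqueN(p$recordings$file_id), 1L)
  # multi-code permutations appear at bout boundaries
  expect_gt(sum(grepl(" ", p$recordings$posture)), 0)
  expect_error(generate_patient_series(a, 1, t0 + 7), "grid")
})

test_that("overlap injection: identity at frac 0, collisions for the selected fraction", {
  cfg <- cohort_config(n_patients = 20, days_per_patient = 2,
                       frac_overlap_patients = 0, frac_inconsistent_patients = 0,
                       frac_incomplete_days = 0, seed = 3)
  cohort <- simulate_cohort(cfg)
  same <- inject_overlap(cohort, 0)
  expect_identical(same$recordings, cohort$recordings)
  expect_equal(sum(same$truth$flags$is_overlap_injected), 0L)

  set.seed(44)
  inj <- inject_overlap(cohort, 0.1)
  flags <- inj$truth$flags[is_overlap_injected == TRUE]
  expect_equal(data.table::uniqueN(flags$mrn), 2L)  # 10% of 20 patients
  # oracle: every flagged timestamp has >= 2 distinct recordings under the MRN
  counts <- inj$recordings[flags, on = c("mrn", "timestamp")
                           ][, .N, by = .(mrn, timestamp)]
  counts2 <- inj$recordings[counts[, .(mrn, timestamp)], on = c("mrn", "timestamp")
                            ][, .N, by = .(mrn, timestamp)]
  expect_true(all(counts2$N >= 2))
  # injected rows come from a different device and file
  vic <- flags$mrn[1]
  own_dev <- cohort$recordings[mrn == vic, unique(device_serial)]
  expect_false(any(flags[mrn == vic, device_serial] %in% own_dev))
})

test_that("overlap injection on a single-patient cohort is a configuration error", {
  cfg <- cohort_config(n_patients = 1, days_per_patient = 1,
                       frac_overlap_patients = 0, frac_inconsistent_patients = 0,
                       frac_incomplete_days = 0, seed = 1)
  one <- simulate_cohort(cfg)
  expect_error(inject_overlap(one, 0.5), ">= 2 patients")
})

test_that("inconsistency injection stays strictly outside the admission window", {
  cfg <- cohort_config(n_patients = 10, days_per_patient = 2,
                       frac_overlap_patients = 0, frac_inconsistent_patients = 0,
                       frac_incomplete_days = 0, seed = 9)
  cohort <- simulate_cohort(cfg)
  same <- inject_inconsistency(cohort, 0)
  expect_identical(same$recordings, cohort$recordings)

  set.seed(10)
  inj <- inject_inconsistency(cohort, 0.3, extension_hours = 4, side = "after")
  flags <- inj$truth$flags[is_out_of_window == TRUE]
  expect_equal(data.table::uniqueN(flags$mrn), 3L)
  # 4 h x 240 recordings/h strictly after discharge
  per_pat <- flags[, .N, by = mrn]
  expect_true(all(per_pat$N == 960L))
  j <- merge(flags, cohort$admissions, by = "mrn")
  expect_true(all(j$timestamp > j$discharge_time))
  set.seed(11)
  inj2 <- inject_inconsistency(cohort, 0.3)
  j2 <- merge(inj2$truth$flags[is_out_of_window == TRUE], cohort$admissions,
              by = "mrn")
  expect_true(all(j2$timestamp < j2$admit_time | j2$timestamp > j2$discharge_time))
})

test_that("write_cohort / read_cohort round trips field for field", {
  cfg <- cohort_config(n_patients = 3, days_per_patient = 1,
                       frac_overlap_patients = 0.34, frac_inconsistent_patients = 0.34,
                       frac_incomplete_days = 0.2, seed = 14)
  cohort <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_equal(as.data.frame(back$recordings), as.data.frame(cohort$recordings),
               ignore_attr = TRUE)
  expect_equal(as.data.frame(back$admissions), as.data.frame(cohort$admissions))
  key <- c("mrn", "file_id", "device_serial", "timestamp")
  a <- data.table::setorderv(data.table::copy(cohort$truth$flags), key)
  b <- data.table::setorderv(data.table::copy(back$truth$flags), key)
  expect_equal(as.data.frame(b), as.data.frame(a))
})

test_that("a complete 2-patient x 1-day cohort writes 2 x 5760 recording rows", {
  cfg <- cohort_config(n_patients = 2, days_per_patient = 1,
                       frac_overlap_patients = 0, frac_inconsistent_patients = 0,
                       frac_incomplete_days = 0, seed = 16)
  cohort <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  rec <- read_recordings(file.path(dir, "recordings.csv"))
  expect_equal(nrow(rec), 2L * 5760L)
})

test_that("smoother alteration rate matches the injected noise rate (±3 SE)", {
  rate <- 0.02
  a <- archetype_spec("noisy", c(0.4, 0.3, 0.2, 0.1), c(0.7, 0.15, 0.05, 0.1),
                      mean_bout_len = 40, noise_rate = rate)
  p <- generate_patient_series(a, 4, t0, "P1", seed = 18)  # 23040 timestamps
  ser <- consolidate_recordings(p$recordings)
  out <- smooth_majority_vote(ser)
  n_interior <- nrow(ser) - 2L
  altered <- sum(out$group != ser$group) / n_interior
  se <- sqrt(rate * (1 - rate) / n_interior)
  expect_lt(abs(altered - rate), 3 * se + 2 / a$mean_bout_len * rate)
})

test_that("cohort config validation and reproducibility", {
  expect_error(cohort_config(frac_overlap_patients = 1.5), "frac_overlap_patients")
  expect_error(cohort_config(archetype_mix = c(a = 0.5, b = 0.5)), "archetype_mix")
  cfg <- cohort_config(n_patients = 4, days_per_patient = c(1, 2), seed = 77)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_equal(as.data.frame(c1$recordings), as.data.frame(c2$recordings))
  expect_output(print(c1), "synthetic posture cohort")
})
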