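test_that("cohort generation is reproducible and emits every individual.day", {
  cfg <- cohort_config(n_individuals = 15, n_days = 3,
                       n_corrupted_days = 0, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)

  days <- unique(a$diary[c("participant_id", "date")])
  expect_equal(nrow(days), 15 * 3)
  expect_equal(nrow(a$truth), 15 * 3)
  # truth labels partition individual.days exactly
  expect_false(anyDuplicated(a$truth[c("participant_id", "day_index")]) > 0)
  expect_setequal(unique(a$truth$archetype), unique(a$participants$archetype))
})

test_that("timestamps are strictly increasing across the EOs of a day", {
  coh <- generate_cohort(cohort_config(n_individuals = 10, n_days = 2,
                                       n_corrupted_days = 0, seed = 5))
  v <- validate_days(coh$diary)
  expect_equal(nrow(v$excluded), 0)
  key <- paste(v$clean$participant_id, v$clean$date)
  for (k in unique(key)) {
    tm <- unique(v$clean$time_min[key == k])
    expect_true(all(diff(sort(tm)) >= 1))
  }
})

test_that("per-EO adjusted protein concentrates around the archetype mean", {
  # law-of-large-numbers check at ~10 000 EOs for the high-protein archetype
  cfg <- cohort_config(n_individuals = 500, n_days = 4,
                       archetype_mix = c(high = 1), n_corrupted_days = 0,
                       seed = 21)
  coh <- generate_cohort(cfg)
  proc <- process_diary(coh$diary, synthetic_composition())
  expect_gt(nrow(proc$eos), 9000)
  expect_lt(abs(mean(proc$eos$protein) - 19.0), 0.2)
  # and within 3 standard errors
  se <- sd(proc$eos$protein) / sqrt(nrow(proc$eos))
  expect_lt(abs(mean(proc$eos$protein) - 19.0), 3 * se + 0.05)
})

test_that("missing-time injection blanks exactly the requested days", {
  coh <- generate_cohort(cohort_config(n_individuals = 10, n_days = 4,
                                       n_corrupted_days = 0, seed = 8))
  d0 <- inject_missing_times(coh$diary, 0)
  expect_equal(nrow(attr(d0, "corrupted_days")), 0)
  attr(d0, "corrupted_days") <- NULL
  expect_identical(d0, coh$diary)

  d4 <- inject_missing_times(coh$diary, 4, seed = 2)
  corrupted <- attr(d4, "corrupted_days")
  expect_equal(nrow(corrupted), 4)
  v <- validate_days(d4)
  expect_equal(nrow(v$excluded), 4)
  expect_equal(length(unique(paste(v$clean$participant_id, v$clean$date))),
               36)

  all_gone <- inject_missing_times(coh$diary, 40, seed = 2)
  v2 <- validate_days(all_gone)
  expect_equal(nrow(v2$clean), 0)
  expect_length(to_series(build_eos(
    filter_low_protein_items(
      item_nutrients(v2$clean, synthetic_composition())))), 0)

  expect_error(inject_missing_times(coh$diary, 41), "exceeds")
})

test_that("empty composition or unknown food groups are configuration errors", {
  expect_error(generate_cohort(cohort_config(n_individuals = 2, n_days = 1),
                               composition = synthetic_composition()[0, ]),
               "empty")
  lonely <- synthetic_composition()
  lonely <- lonely[lonely$food_group == "fruit", ]
  expect_error(generate_cohort(cohort_config(n_individuals = 2, n_days = 1,
                                             n_corrupted_days = 0),
                               composition = lonely),
               "absent from the composition")
})

test_that("low-protein item injection produces sub-filter items", {
  cfg <- cohort_config(n_individuals = 10, n_days = 2, n_corrupted_days = 0,
                       seed = 31, low_protein_rate = 0.5)
  coh <- generate_cohort(cfg)
  v <- validate_days(coh$diary)
  items <- item_nutrients(v$clean, synthetic_composition())
  expect_gt(sum(items$protein_raw < 0.5), 0)
  cov <- coverage_report(items, filter_low_protein_items(items))
  expect_lt(cov$cohort_fraction, 1)
  expect_gt(cov$cohort_fraction, 0.9)
})
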