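comp1 <- mini_comp("a", 20)  # 20 g protein / 100 g, TID 1, no AAs

test_that("a day with any missing time record is excluded in full", {
  d <- rbind(diary_row(1, "2023-01-02", "08:00", "a", 50),
             diary_row(1, "2023-01-02", "12:00", "a", 50),
             diary_row(1, "2023-01-03", "08:00", "a", 50),
             diary_row(2, "2023-01-02", c("08:00", "09:00", NA, "12:00",
                                          "19:00"), "a", 10))
  v <- validate_days(d)
  expect_equal(nrow(v$excluded), 1)
  expect_equal(v$excluded$participant_id, "2")
  expect_equal(v$excluded$n_records, 5)
  expect_false(any(v$clean$participant_id == "2"))
  expect_equal(sum(v$clean$participant_id == "1"), 3)

  clean_only <- validate_days(d[1:3, ])
  expect_equal(nrow(clean_only$excluded), 0)
})

test_that("records sharing an exact timestamp form one eating occasion", {
  d <- rbind(diary_row(1, "2023-01-02", "08:00", "a", 50),   # 10 g
             diary_row(1, "2023-01-02", "08:00", "a", 25),   # 5 g
             diary_row(1, "2023-01-02", "08:01", "a", 25))   # 5 g
  eos <- build_eos(filter_low_protein_items(
    item_nutrients(validate_days(d)$clean, comp1)))
  expect_equal(nrow(eos), 2)
  expect_equal(eos$protein, c(15, 5))
  expect_equal(eos$item_count, c(2L, 1L))
  expect_equal(eos$time_min, c(480L, 481L))

  d2 <- rbind(diary_row(1, "2023-01-02", "12:30", "a", 40),
              diary_row(1, "2023-01-02", "12:30", "a", 60),
              diary_row(1, "2023-01-02", "18:00", "a", 150))
  eos2 <- build_eos(filter_low_protein_items(
    item_nutrients(validate_days(d2)$clean, comp1)))
  expect_equal(nrow(eos2), 2)
  expect_equal(eos2$protein, c(20, 30))
})

test_that("unresolvable food ids are reported by name", {
  d <- diary_row(1, "2023-01-02", "08:00", c("a", "mystery"), 50)
  expect_error(item_nutrients(validate_days(d)$clean, comp1), "mystery")
})

test_that("the 0.5 g item filter is strict and can empty an EO", {
  d <- rbind(diary_row(1, "2023-01-02", "08:00", "a", 2.45),  # 0.49 g
             diary_row(1, "2023-01-02", "09:00", "a", 2.50),  # 0.50 g
             diary_row(1, "2023-01-02", "10:00", "a", c(1.5, 1.0)))  # 0.3+0.2
  items <- item_nutrients(validate_days(d)$clean, comp1)
  kept <- filter_low_protein_items(items)
  expect_equal(kept$protein_raw, 0.5)
  eos <- build_eos(kept)
  expect_equal(nrow(eos), 1)        # 08:00 and 10:00 EOs removed entirely
  expect_equal(eos$time_min, 540L)
})

test_that("the filter can alternatively act on digestibility-adjusted protein", {
  comp_tid <- mini_comp("a", 20, tid_protein = 0.8)
  d <- diary_row(1, "2023-01-02", "08:00", "a", 2.75)  # raw 0.55, adj 0.44
  items <- item_nutrients(validate_days(d)$clean, comp_tid)
  expect_equal(nrow(filter_low_protein_items(items, on = "raw")), 1)
  expect_equal(nrow(filter_low_protein_items(items, on = "adjusted")), 0)
})

test_that("coverage reports retained protein fractions", {
  d <- rbind(diary_row(1, "2023-01-02", "08:00", "a", 50),
             diary_row(2, "2023-01-02", "08:00", "a", 50))
  items <- item_nutrients(validate_days(d)$clean, comp1)
  cov <- coverage_report(items, items)
  expect_equal(cov$cohort_fraction, 1)
  expect_equal(cov$min_participant_fraction, 1)

  pre <- items
  pre$protein_raw <- c(1000, 985)
  post <- pre[2, , drop = FALSE]
  expect_equal(coverage_report(pre, post)$cohort_fraction, 985 / 1985)

  zero <- items; zero$protein_raw <- 0
  cz <- coverage_report(zero, zero[0, ])
  expect_true(is.na(cz$cohort_fraction))
  expect_setequal(cz$undefined_participants, c("1", "2"))
})

test_that("series are one per retained individual.day, ordered by clock time", {
  d <- rbind(diary_row(1, "2023-01-02", "19:00", "a", 100),
             diary_row(1, "2023-01-02", "08:00", "a", 30),
             diary_row(1, "2023-01-02", "13:00", "a", 60),
             diary_row(1, "2023-01-05", "09:00", "a", 40),  # calendar gap
             diary_row(2, "2023-01-02", "10:00", "a", 55))
  eos <- build_eos(filter_low_protein_items(
    item_nutrients(validate_days(d)$clean, comp1)))
  ser <- to_series(eos)
  expect_length(ser, 3)
  expect_equal(ser[["1.1"]]$values, c(6, 12, 20))
  expect_equal(ser[["1.1"]]$times, c(480L, 780L, 1140L))
  expect_equal(ser[["1.2"]]$values, 8)    # day 2 despite the calendar gap
  expect_equal(ser[["2.1"]]$values, 11)
  expect_equal(dim(ser[["1.1"]]$iaa), c(3L, 7L))
})

test_that("daily protein is conserved from retained items to EO sums", {
  coh <- generate_cohort(cohort_config(n_individuals = 8, n_days = 3,
                                       n_corrupted_days = 0, seed = 14,
                                       low_protein_rate = 0.3))
  proc <- process_diary(coh$diary, synthetic_composition())
  day_items <- tapply(proc$items$protein,
                      paste(proc$items$participant_id, proc$items$date), sum)
  day_eos <- tapply(proc$eos$protein,
                    paste(proc$eos$participant_id, proc$eos$date), sum)
  expect_equal(day_eos[names(day_items)], day_items, tolerance = 1e-9)
})

test_that("adding a missing-time record never increases the series count", {
  coh <- generate_cohort(cohort_config(n_individuals = 6, n_days = 2,
                                       n_corrupted_days = 0, seed = 4))
  base_n <- length(to_series(process_diary(coh$diary,
                                           synthetic_composition())$eos))
  for (pid in c("1", "3", "6")) {
    d <- rbind(coh$diary,
               diary_row(pid, coh$diary$date[1], NA, "tofu_firm", 100))
    n <- length(to_series(process_diary(d, synthetic_composition())$eos))
    expect_lte(n, base_n)
  }
})
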