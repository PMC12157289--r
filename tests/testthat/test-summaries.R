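test_that("threshold flags use strict inequalities", {
  cfg <- threshold_config()
  f <- eo_threshold_flags(c(19, 20, 16.8, 25), 70, cfg)
  expect_equal(f$below_absolute, c(TRUE, FALSE, TRUE, FALSE))
  # 19/70 = 0.271 >= 0.24; 16.8/70 = 0.24 exactly -> not below under strict <
  expect_equal(f$below_relative, c(FALSE, FALSE, FALSE, FALSE))
  f2 <- eo_threshold_flags(c(14, 19), c(70, NA), cfg)
  expect_equal(f2$below_relative[1], TRUE)
  expect_true(is.na(f2$below_relative[2]))
  expect_error(eo_threshold_flags(10, 0, cfg), "positive")
})

make_eos <- function(protein, pid = "1", day = 1L, times = NULL) {
  n <- length(protein)
  iaa <- matrix(0.1, n, 7, dimnames = list(NULL, IAA_NAMES))
  out <- data.frame(participant_id = rep(pid, n),
                    date = "2023-01-02",
                    day_index = rep(day, n),
                    time_min = if (is.null(times))
                      seq(480L, by = 60L, length.out = n) else times,
                    item_count = 1L,
                    protein = protein, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(iaa))
}

test_that("single-cluster summaries compute EO-weighted means and pooled percentages", {
  eos <- make_eos(rep(10, 6))
  labels <- c("1.1" = 1L)
  parts <- data.frame(participant_id = "1", sex = "F",
                      body_weight_kg = 70, stringsAsFactors = FALSE)
  rep1 <- cluster_summary(labels, eos, parts)
  tab <- rep1$cluster_table
  expect_equal(tab$mean_protein_g, 10)
  expect_equal(tab$pct_eo_below_absolute, 100)
  expect_equal(tab$n_eos, 6)
  expect_equal(tab$mean_eos_per_day, 6)
  expect_equal(tab$mean_total_iaa_g, 0.7)
  expect_equal(tab$mean_daily_protein_g_per_kg, 60 / 70)
  expect_equal(rep1$individual_table$pct_individuals_below_absolute, 100)
  expect_error(cluster_summary(integer(0), eos, parts), "empty label")
})

test_that("percent-below is monotone in the absolute threshold and books every EO", {
  eos <- rbind(make_eos(c(5, 12, 25), pid = "1"),
               make_eos(c(18, 30), pid = "2"))
  labels <- c("1.1" = 1L, "2.1" = 2L)
  r20 <- cluster_summary(labels, eos, NULL, threshold_config())
  r10 <- cluster_summary(labels, eos, NULL,
                         threshold_config(absolute_per_eo = 10))
  expect_true(all(r10$cluster_table$pct_eo_below_absolute <=
                    r20$cluster_table$pct_eo_below_absolute))
  expect_equal(sum(r20$cluster_table$n_eos), nrow(eos))
  expect_true(all(r20$cluster_table$pct_eo_below_absolute >= 0 &
                    r20$cluster_table$pct_eo_below_absolute <= 100))
  # without participants the weight-relative metrics are missing, not fake
  expect_true(all(is.na(r20$cluster_table$pct_eo_below_relative)))
})

test_that("food-group contributions sum to 100 and fold small groups into Others", {
  items <- data.frame(
    participant_id = "1", date = "2023-01-02", time_min = c(480L, 720L, 900L),
    food_id = c("x", "y", "z"),
    food_group = c("legumes and pulses", "grains and pasta", "fruit"),
    amount_g = 100, protein_raw = c(60, 35.3, 4.7),
    stringsAsFactors = FALSE)
  for (nm in NUTRIENT_NAMES) items[[nm]] <- c(60, 35.3, 4.7)
  labels <- c("1.1" = 1L)
  contrib <- foodgroup_contribution(items, labels)
  expect_true(all(abs(tapply(contrib$pct,
                             paste(contrib$cluster, contrib$nutrient),
                             sum) - 100) < 1e-6))
  expect_true("Others" %in% contrib$food_group)   # fruit at 4.7% < 5%
  expect_false("fruit" %in% contrib$food_group)
  expect_true("grains and pasta" %in% contrib$food_group)

  solo <- items[1, ]
  c1 <- foodgroup_contribution(solo, labels)
  expect_true(all(c1$pct == 100))

  two <- items[1:2, ]
  two$protein <- c(60, 40); two$protein_raw <- c(60, 40)
  c2 <- foodgroup_contribution(two, labels)
  p <- c2[c2$nutrient == "protein", ]
  expect_equal(sort(p$pct), c(40, 60))

  bad <- items; bad$food_group[2] <- ""
  expect_error(foodgroup_contribution(bad, labels), "food_group")
})

test_that("hourly profiles bin EOs into 24 intervals with NA for empty cells", {
  eos <- make_eos(c(8, 12, 20, 6),
                  times = c(0L, 750L, 750L + 0L, 1439L))
  eos$time_min <- c(0L, 1110L, 750L, 1439L)   # 00:00, 18:30, 12:30, 23:59
  labels <- c("1.1" = 1L)
  arr <- hourly_profile(eos, labels)
  expect_equal(dim(arr), c(1L, 24L, 8L))
  expect_equal(arr["1", "0", "protein"], 8)
  expect_equal(arr["1", "18", "protein"], 12)
  expect_equal(arr["1", "12", "protein"], 20)
  expect_equal(arr["1", "23", "protein"], 6)
  expect_true(is.na(arr["1", "3", "protein"]))

  two <- make_eos(c(8, 12), times = c(745L, 755L))  # both in bin 12
  arr2 <- hourly_profile(two, labels)
  expect_equal(arr2["1", "12", "protein"], 10)
})

test_that("cluster report carries KW and Dunn comparisons across clusters", {
  eos <- rbind(make_eos(c(5, 6, 7, 5.5), pid = "1"),
               make_eos(c(18, 20, 22, 19), pid = "2"))
  labels <- c("1.1" = 1L, "2.1" = 2L)
  parts <- data.frame(participant_id = c("1", "2"), sex = c("F", "M"),
                      body_weight_kg = c(60, 80), bmi = c(22, 25),
                      body_fat_pct = c(31, 24), stringsAsFactors = FALSE)
  rep2 <- cluster_summary(labels, eos, parts)
  expect_false(is.null(rep2$tests$protein_per_eo))
  expect_equal(nrow(rep2$tests$protein_per_eo$dunn), 1)
  expect_lt(rep2$tests$protein_per_eo$kw$p, 0.05)
  expect_output(print(rep2), "Kruskal-Wallis")
})
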