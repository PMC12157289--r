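# Synthetic vegan-cohort generator.
#
# Emulates a food-diary study: each individual follows one latent meal-pattern
# archetype (grazing / moderate / high-protein-infrequent); per day the number
# of eating occasions (EOs) is 1 + Poisson(mean - 1); per EO a target protein
# amount is drawn from a truncated-at-zero normal and realised as 1-3 food
# items sampled from the archetype's food-group weights. Timestamps are drawn
# uniformly in the archetype's eating window, sorted, and de-duplicated with
# minute-level jitter so that EO identity is controlled by distinct times.

#' Specify a meal-pattern archetype
#'
#' @param label Archetype name.
#' @param eo_per_day_mean Mean number of eating occasions per day (> 0).
#' @param protein_per_eo_mean Mean digestibility-adjusted protein per EO, g
#'   (the quantity the analysis sums per EO, hence what cluster-level
#'   calibration targets refer to).
#' @param protein_per_eo_sd Within-archetype sd of protein per EO, g.
#' @param foodgroup_weights Named sampling probabilities over food groups;
#'   must sum to 1.
#' @param start_hour,end_hour Eating window, clock hours with
#'   \code{0 <= start_hour < end_hour <= 24}.
#' @return Object of class \code{archetype_spec}.
#' @export
archetype_spec <- function(label, eo_per_day_mean, protein_per_eo_mean,
                           protein_per_eo_sd, foodgroup_weights,
                           start_hour = 7, end_hour = 22) {
  stopifnot(eo_per_day_mean > 0, protein_per_eo_mean > 0,
            protein_per_eo_sd >= 0,
            start_hour >= 0, start_hour < end_hour, end_hour <= 24)
  if (is.null(names(foodgroup_weights)) || any(foodgroup_weights < 0))
    stop("foodgroup_weights must be a named nonnegative vector")
  if (abs(sum(foodgroup_weights) - 1) > 1e-8)
    stop("foodgroup_weights must sum to 1")
  structure(list(label = label,
                 eo_per_day_mean = eo_per_day_mean,
                 protein_per_eo_mean = protein_per_eo_mean,
                 protein_per_eo_sd = protein_per_eo_sd,
                 foodgroup_weights = foodgroup_weights,
                 start_hour = start_hour, end_hour = end_hour),
            class = "archetype_spec")
}

#' Default meal-pattern archetypes
#'
#' Three archetypes calibrated to the per-cluster statistics the pipeline is
#' designed to recover: a low-protein frequent "grazing" pattern (6.5 g/EO,
#' 6.5 EOs/day), a moderate pattern (11.4 g/EO, 5.2 EOs/day) and a
#' high-protein infrequent pattern (19.0 g/EO, 5.0 EOs/day). The
#' within-archetype protein sd (not identified by cluster-level summaries) is
#' 2 g throughout. Food-group weights shift from grain-dominated (grazing)
#' towards legume-dominated (high).
#'
#' @return Named list of three [archetype_spec()] objects.
#' @export
default_archetypes <- function() {
  list(
    grazing = archetype_spec(
      "grazing", eo_per_day_mean = 6.5,
      protein_per_eo_mean = 6.5, protein_per_eo_sd = 2,
      foodgroup_weights = c("grains and pasta" = 0.40,
                            "legumes and pulses" = 0.15,
                            "nuts and seeds" = 0.15,
                            "vegetables" = 0.10,
                            "plant-based beverages" = 0.10,
                            "fruit" = 0.08,
                            "savoury sauces and condiments" = 0.02),
      start_hour = 7, end_hour = 22),
    moderate = archetype_spec(
      "moderate", eo_per_day_mean = 5.2,
      protein_per_eo_mean = 11.4, protein_per_eo_sd = 2,
      foodgroup_weights = c("legumes and pulses" = 0.35,
                            "grains and pasta" = 0.30,
                            "nuts and seeds" = 0.12,
                            "vegetables" = 0.08,
                            "plant-based beverages" = 0.08,
                            "fruit" = 0.05,
                            "savoury sauces and condiments" = 0.02),
      start_hour = 7, end_hour = 21),
    high = archetype_spec(
      "high", eo_per_day_mean = 5.0,
      protein_per_eo_mean = 19.0, protein_per_eo_sd = 2,
      foodgroup_weights = c("legumes and pulses" = 0.55,
                            "grains and pasta" = 0.20,
                            "nuts and seeds" = 0.10,
                            "vegetables" = 0.06,
                            "plant-based beverages" = 0.05,
                            "fruit" = 0.03,
                            "savoury sauces and condiments" = 0.01),
      start_hour = 8, end_hour = 20)
  )
}

#' Synthetic plant-food composition table
#'
#' A small built-in table of common vegan foods with protein content,
#' amino-acid profiles (mg per g protein) and true-ileal-digestibility
#' coefficients. All values are synthetic: they are plausible magnitudes for
#' plant foods (legume profiles rich in lysine, cereal profiles rich in
#' sulphur amino acids, TID around 0.75-0.95), not measurements from any
#' reference database.
#'
#' @return Validated composition data frame (one row per food).
#' @export
synthetic_composition <- function() {
  # food_id, group, protein g/100g, then trp thr leu lys met cys his (mg/g
  # protein), then TID for protein and the same seven AAs.
  rows <- list(
    list("lentils_cooked",  "legumes and pulses", 9.0,
         c(9, 36, 72, 69, 8, 13, 28),  c(0.84, 0.80, 0.85, 0.86, 0.85, 0.82, 0.76, 0.86)),
    list("chickpeas_cooked","legumes and pulses", 8.9,
         c(10, 37, 71, 67, 13, 14, 27), c(0.83, 0.81, 0.84, 0.85, 0.84, 0.83, 0.75, 0.85)),
    list("tofu_firm",       "legumes and pulses", 14.0,
         c(12, 41, 77, 62, 13, 14, 26), c(0.92, 0.90, 0.91, 0.93, 0.92, 0.92, 0.85, 0.93)),
    list("tempeh",          "legumes and pulses", 19.0,
         c(11, 40, 78, 56, 12, 13, 27), c(0.90, 0.88, 0.89, 0.91, 0.90, 0.90, 0.83, 0.91)),
    list("soy_mince",       "legumes and pulses", 16.0,
         c(12, 40, 79, 63, 13, 13, 26), c(0.91, 0.89, 0.90, 0.92, 0.91, 0.91, 0.84, 0.92)),
    list("bread_wholemeal", "grains and pasta",   9.5,
         c(11, 29, 68, 27, 16, 22, 23), c(0.87, 0.85, 0.86, 0.88, 0.77, 0.88, 0.84, 0.88)),
    list("oats_rolled",     "grains and pasta",   13.0,
         c(13, 33, 74, 40, 18, 25, 24), c(0.88, 0.86, 0.87, 0.89, 0.80, 0.89, 0.85, 0.89)),
    list("pasta_cooked",    "grains and pasta",   5.5,
         c(12, 28, 70, 22, 16, 20, 22), c(0.89, 0.87, 0.88, 0.90, 0.78, 0.90, 0.86, 0.90)),
    list("rice_brown_cooked","grains and pasta",  2.6,
         c(12, 36, 82, 38, 22, 13, 25), c(0.85, 0.83, 0.84, 0.86, 0.76, 0.86, 0.82, 0.86)),
    list("peanut_butter",   "nuts and seeds",     25.0,
         c(10, 27, 64, 35, 12, 13, 25), c(0.86, 0.84, 0.85, 0.87, 0.80, 0.86, 0.82, 0.87)),
    list("almonds",         "nuts and seeds",     21.0,
         c(9, 28, 68, 28, 9, 14, 26),  c(0.84, 0.82, 0.83, 0.85, 0.78, 0.84, 0.80, 0.85)),
    list("broccoli",        "vegetables",         2.8,
         c(12, 39, 57, 56, 15, 12, 20), c(0.78, 0.76, 0.77, 0.79, 0.78, 0.78, 0.72, 0.79)),
    list("spinach",         "vegetables",         2.9,
         c(14, 42, 76, 60, 18, 12, 22), c(0.76, 0.74, 0.75, 0.77, 0.76, 0.76, 0.70, 0.77)),
    list("soy_beverage",    "plant-based beverages", 3.3,
         c(12, 40, 76, 61, 13, 13, 26), c(0.93, 0.91, 0.92, 0.94, 0.93, 0.93, 0.86, 0.94)),
    list("oat_beverage",    "plant-based beverages", 1.0,
         c(13, 33, 73, 40, 18, 24, 24), c(0.88, 0.86, 0.87, 0.89, 0.80, 0.89, 0.85, 0.89)),
    list("banana",          "fruit",              1.1,
         c(11, 34, 72, 55, 20, 18, 90), c(0.80, 0.78, 0.79, 0.81, 0.80, 0.80, 0.74, 0.81)),
    list("hummus_spread",   "savoury sauces and condiments", 7.9,
         c(10, 37, 70, 66, 13, 14, 26), c(0.82, 0.80, 0.83, 0.84, 0.83, 0.82, 0.74, 0.84))
  )
  df <- data.frame(
    food_id = vapply(rows, `[[`, "", 1L),
    food_group = vapply(rows, `[[`, "", 2L),
    protein_per_100g = vapply(rows, `[[`, 0, 3L),
    stringsAsFactors = FALSE
  )
  aa <- t(vapply(rows, `[[`, numeric(7), 4L))
  colnames(aa) <- paste0("aa_", IAA_NAMES, "_mg_per_g_protein")
  tid <- t(vapply(rows, `[[`, numeric(8), 5L))
  colnames(tid) <- c("tid_protein", paste0("tid_", IAA_NAMES))
  validate_composition(cbind(df, aa, tid))
}

#' Cohort-generation configuration
#'
#' @param n_individuals,n_days Cohort dimensions.
#' @param archetype_mix Named proportions over archetype labels, summing to 1.
#' @param n_corrupted_days Number of individual.days whose time records are
#'   blanked by [inject_missing_times()].
#' @param seed Integer seed; identical configurations reproduce identical
#'   cohorts.
#' @param low_protein_rate Probability that an EO additionally carries one
#'   very small item (< 0.5 g protein), to exercise the low-protein item
#'   filter. Default 0.
#' @param min_item_protein_g Minimum protein per generated item, g; keeps
#'   regular items above the 0.5 g analysis filter.
#' @param max_items_per_eo Maximum number of items drawn per EO.
#' @param start_date First diary date.
#' @return Object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_individuals = 193, n_days = 4,
                          archetype_mix = c(grazing = 0.384,
                                            moderate = 0.459,
                                            high = 0.157),
                          n_corrupted_days = 6, seed = 1L,
                          low_protein_rate = 0,
                          min_item_protein_g = 0.6,
                          max_items_per_eo = 3L,
                          start_date = as.Date("2023-03-06")) {
  stopifnot(n_individuals >= 1, n_days >= 1, n_corrupted_days >= 0,
            n_corrupted_days <= n_individuals * n_days,
            low_protein_rate >= 0, low_protein_rate <= 1,
            min_item_protein_g > 0, max_items_per_eo >= 1)
  if (is.null(names(archetype_mix)) || any(archetype_mix < 0))
    stop("archetype_mix must be a named nonnegative vector")
  if (abs(sum(archetype_mix) - 1) > 1e-8)
    stop("archetype_mix must sum to 1")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_days = as.integer(n_days),
                 archetype_mix = archetype_mix,
                 n_corrupted_days = as.integer(n_corrupted_days),
                 seed = as.integer(seed),
                 low_protein_rate = low_protein_rate,
                 min_item_protein_g = min_item_protein_g,
                 max_items_per_eo = as.integer(max_items_per_eo),
                 start_date = start_date),
            class = "cohort_config")
}

# Truncated-at-zero normal draw (rejection; falls back to a tiny positive
# value if mean/sd make acceptance hopeless).
rnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(mean, .Machine$double.eps), n))
  out <- rnorm(n, mean, sd)
  for (i in seq_len(200)) {
    bad <- out <= 0
    if (!any(bad)) break
    out[bad] <- rnorm(sum(bad), mean, sd)
  }
  out[out <= 0] <- .Machine$double.eps
  out
}

# Uniform minute draws in [start_hour, end_hour), sorted, collisions resolved
# by +1 minute jitter inside the window.
draw_eo_minutes <- function(n, start_hour, end_hour) {
  lo <- as.integer(start_hour * 60)
  hi <- as.integer(end_hour * 60) - 1L  # inclusive upper minute
  if (hi - lo + 1L < n)                 # saturated window: all minutes distinct
    return(sort(sample(seq(lo, hi), min(n, hi - lo + 1L))))
  m <- sort(as.integer(floor(runif(n, lo, hi + 1))))
  repeat {
    dup <- which(duplicated(m))
    if (!length(dup)) break
    m[dup] <- pmin(m[dup] + 1L, hi)
    m <- sort(m)
    if (max(table(m)) > 1 && all(m[duplicated(m)] == hi)) {
      # pushed against the window edge; fall back to distinct sampling
      m <- sort(sample(seq(lo, hi), n))
      break
    }
  }
  m
}

minutes_to_hhmm <- function(m) {
  sprintf("%02d:%02d", m %/% 60L, m %% 60L)
}

#' Generate a synthetic cohort
#'
#' Draws participants, assigns each one archetype, and writes a timestamped
#' food diary per participant-day. Per EO, a target protein amount (truncated
#' normal around the archetype mean) is realised by 1-3 items sampled from the
#' archetype's food-group weights, with item amounts scaled so item protein
#' sums to the target. Deterministic given \code{config$seed}.
#'
#' @param config [cohort_config()].
#' @param archetypes Named list of [archetype_spec()]; names must cover
#'   \code{config$archetype_mix}.
#' @param composition Composition table the items are drawn from.
#' @return List with elements \code{participants} (id, sex, body_weight_kg,
#'   bmi, body_fat_pct, archetype), \code{diary} (participant_id, date, time,
#'   food_id, amount_g) and \code{truth} (participant_id, day_index,
#'   archetype) — the latent label of every individual.day.
#' @export
generate_cohort <- function(config = cohort_config(),
                            archetypes = default_archetypes(),
                            composition = synthetic_composition()) {
  if (is.null(composition) || nrow(composition) == 0L)
    stop("configuration error: composition table is empty")
  validate_composition(composition)
  labels <- names(config$archetype_mix)
  missing_arch <- setdiff(labels, names(archetypes))
  if (length(missing_arch))
    stop("archetype_mix references unknown archetype(s): ",
         paste(missing_arch, collapse = ", "))
  for (a in archetypes[labels]) {
    unknown_groups <- setdiff(names(a$foodgroup_weights),
                              unique(composition$food_group))
    if (length(unknown_groups))
      stop("configuration error: archetype '", a$label,
           "' samples food group(s) absent from the composition table: ",
           paste(unknown_groups, collapse = ", "))
  }

  set.seed(config$seed)
  n <- config$n_individuals
  assigned <- sample(labels, n, replace = TRUE, prob = config$archetype_mix)

  # Participants. Body fat declines with archetype protein level so that the
  # body-composition contrasts the summaries module tests for are present.
  sex <- ifelse(runif(n) < 0.731, "F", "M")
  bw <- ifelse(sex == "F", rnorm(n, 65, 9), rnorm(n, 80, 11))
  bw <- pmax(bw, 42)
  bmi <- pmin(pmax(rnorm(n, 24, 3), 17), 40)
  pmeans <- vapply(archetypes[assigned],
                   function(a) a$protein_per_eo_mean, 0)
  bf <- pmin(pmax(rnorm(n, 36.5 - 0.58 * pmeans, 7), 8), 55)
  participants <- data.frame(
    participant_id = as.character(seq_len(n)),
    sex = sex,
    body_weight_kg = round(bw, 1),
    bmi = round(bmi, 1),
    body_fat_pct = round(bf, 1),
    archetype = assigned,
    stringsAsFactors = FALSE
  )

  group_rows <- split(seq_len(nrow(composition)), composition$food_group)
  diary <- vector("list", n * config$n_days)
  truth <- data.frame(
    participant_id = rep(as.character(seq_len(n)), each = config$n_days),
    day_index = rep(seq_len(config$n_days), times = n),
    archetype = rep(assigned, each = config$n_days),
    stringsAsFactors = FALSE
  )

  rec_idx <- 0L
  for (i in seq_len(n)) {
    a <- archetypes[[assigned[i]]]
    for (d in seq_len(config$n_days)) {
      n_eo <- 1L + rpois(1L, a$eo_per_day_mean - 1)
      mins <- draw_eo_minutes(n_eo, a$start_hour, a$end_hour)
      n_eo <- length(mins)
      targets <- rnorm_pos(n_eo, a$protein_per_eo_mean, a$protein_per_eo_sd)
      day_rows <- vector("list", n_eo)
      for (e in seq_len(n_eo)) {
        target <- targets[e]
        k <- sample.int(config$max_items_per_eo, 1L)
        k <- max(1L, min(k, floor(target / config$min_item_protein_g)))
        w <- runif(k)
        slack <- target - k * config$min_item_protein_g
        item_protein <- config$min_item_protein_g + slack * w / sum(w)
        grp <- sample(names(a$foodgroup_weights), k, replace = TRUE,
                      prob = a$foodgroup_weights)
        rows <- vapply(grp, function(g) {
          cand <- group_rows[[g]]
          cand[sample.int(length(cand), 1L)]
        }, 0L)
        # targets are calibrated on digestibility-adjusted protein (the
        # quantity the analysis sums per EO), so amounts are inflated by
        # 1 / TID(protein)
        amount <- item_protein /
          (composition$protein_per_100g[rows] *
             composition$tid_protein[rows]) * 100
        food <- composition$food_id[rows]
        if (config$low_protein_rate > 0 &&
            runif(1) < config$low_protein_rate) {
          extra_p <- runif(1, 0.05, 0.45)
          r <- sample.int(nrow(composition), 1L)
          food <- c(food, composition$food_id[r])
          amount <- c(amount, extra_p / composition$protein_per_100g[r] * 100)
        }
        day_rows[[e]] <- data.frame(
          participant_id = as.character(i),
          date = as.character(config$start_date + (d - 1L)),
          time = minutes_to_hhmm(rep(mins[e], length(food))),
          food_id = food,
          amount_g = round(amount, 2),
          stringsAsFactors = FALSE
        )
      }
      rec_idx <- rec_idx + 1L
      diary[[rec_idx]] <- do.call(rbind, day_rows)
    }
  }
  diary <- do.call(rbind, diary)
  rownames(diary) <- NULL
  list(participants = participants, diary = diary, truth = truth)
}

#' Blank the time records of selected individual.days
#'
#' Emulates diaries whose clock times could not be recovered: exactly
#' \code{n_corrupted_days} distinct (participant, date) days have every time
#' field set to missing, which makes the day-validation stage drop them in
#' full.
#'
#' @param diary Diary data frame (participant_id, date, time, food_id,
#'   amount_g).
#' @param n_corrupted_days Number of distinct individual.days to corrupt.
#' @param seed Optional integer seed for the day selection.
#' @return The diary with blanked times; attribute \code{"corrupted_days"}
#'   holds a data frame of the affected (participant_id, date) pairs.
#' @export
inject_missing_times <- function(diary, n_corrupted_days, seed = NULL) {
  days <- unique(diary[c("participant_id", "date")])
  if (n_corrupted_days > nrow(days))
    stop("n_corrupted_days exceeds the number of distinct individual.days")
  if (n_corrupted_days == 0L) {
    attr(diary, "corrupted_days") <-
      days[0, , drop = FALSE]
    return(diary)
  }
  if (!is.null(seed)) set.seed(seed)
  pick <- days[sample.int(nrow(days), n_corrupted_days), , drop = FALSE]
  key <- paste(diary$participant_id, diary$date, sep = "\r")
  hit <- key %in% paste(pick$participant_id, pick$date, sep = "\r")
  diary$time[hit] <- NA_character_
  rownames(pick) <- NULL
  attr(diary, "corrupted_days") <- pick
  diary
}

#' Generate a cohort and corrupt time records in one call
#'
#' Convenience wrapper: [generate_cohort()] followed by
#' [inject_missing_times()] with \code{config$n_corrupted_days} (day selection
#' seeded from \code{config$seed}).
#'
#' @inheritParams generate_cohort
#' @return As [generate_cohort()], with the diary corrupted and carrying the
#'   \code{"corrupted_days"} attribute.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            archetypes = default_archetypes(),
                            composition = synthetic_composition()) {
  out <- generate_cohort(config, archetypes, composition)
  out$diary <- inject_missing_times(out$diary, config$n_corrupted_days,
                                    seed = config$seed + 104729L)
  out
}

#' Write a synthetic cohort to CSV files
#'
#' Writes \code{diary.csv}, \code{participants.csv}, \code{composition.csv}
#' and \code{truth_labels.csv} into \code{dir}.
#'
#' @param cohort Result of [generate_cohort()] or [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param composition Composition table to write alongside.
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir, composition = synthetic_composition()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("diary.csv", "participants.csv",
                            "composition.csv", "truth_labels.csv"))
  write.csv(cohort$diary, paths[1], row.names = FALSE, na = "")
  write.csv(cohort$participants, paths[2], row.names = FALSE)
  write.csv(composition, paths[3], row.names = FALSE)
  write.csv(cohort$truth, paths[4], row.names = FALSE)
  invisible(paths)
}
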