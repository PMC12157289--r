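# Diary cleaning and eating-occasion construction.
#
# An eating occasion (EO) is the set of diary records sharing one exact
# (participant, date, clock time); the EO's nutrients are the sum of its
# retained items' TID-adjusted nutrient vectors. A participant-day with any
# unresolvable (missing) time is excluded in full, since its EO sequence
# cannot be ordered. Each retained participant-day becomes one ordered
# protein series ("individual.day"), the unit object of the clustering.

parse_hhmm <- function(x) {
  ok <- !is.na(x) & grepl("^([01][0-9]|2[0-3]):[0-5][0-9]$", x)
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer(substr(x[ok], 1, 2)) * 60L +
    as.integer(substr(x[ok], 4, 5))
  out
}

day_key <- function(participant_id, date) paste(participant_id, date, sep = "\r")

#' Read a food diary from CSV
#'
#' Expects columns \code{participant_id, date, time, food_id, amount_g};
#' blank times are read as missing.
#'
#' @param path CSV path.
#' @return Diary data frame.
#' @export
read_diary <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(participant_id = "character",
                               food_id = "character"))
  need <- c("participant_id", "date", "time", "food_id", "amount_g")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("diary is missing column(s): ", paste(missing_cols, collapse = ", "))
  d$time[!is.na(d$time) & d$time == ""] <- NA_character_
  if (any(d$amount_g < 0, na.rm = TRUE)) stop("amount_g must be nonnegative")
  d
}

#' Read a participant table from CSV
#'
#' Expects at least \code{participant_id, sex, body_weight_kg}; optional
#' \code{bmi} and \code{body_fat_pct}.
#'
#' @param path CSV path.
#' @return Participant data frame.
#' @export
read_participants <- function(path) {
  p <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(participant_id = "character"))
  need <- c("participant_id", "sex", "body_weight_kg")
  missing_cols <- setdiff(need, names(p))
  if (length(missing_cols))
    stop("participant table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  p
}

#' Exclude participant-days with missing time records
#'
#' Any individual.day containing at least one record whose time is missing or
#' unparseable is dropped in full; partial days cannot be ordered into an EO
#' sequence.
#'
#' @param records Diary data frame.
#' @return List: \code{clean} (records of fully-timed days, with an added
#'   \code{time_min} column of minutes since midnight) and \code{excluded}
#'   (one row per dropped day: participant_id, date, n_records, reason).
#' @export
validate_days <- function(records) {
  time_min <- parse_hhmm(records$time)
  key <- day_key(records$participant_id, records$date)
  bad_days <- unique(key[is.na(time_min)])
  drop <- key %in% bad_days
  excluded <- data.frame(participant_id = character(0), date = character(0),
                         n_records = integer(0), reason = character(0),
                         stringsAsFactors = FALSE)
  if (length(bad_days)) {
    sub <- records[drop, c("participant_id", "date")]
    agg <- aggregate(list(n_records = rep(1L, nrow(sub))),
                     by = sub, FUN = sum)
    agg$reason <- "missing or unparseable time record"
    excluded <- agg[order(agg$participant_id, agg$date), ]
    rownames(excluded) <- NULL
  }
  clean <- records[!drop, , drop = FALSE]
  clean$time_min <- time_min[!drop]
  rownames(clean) <- NULL
  list(clean = clean, excluded = excluded)
}

#' Per-item nutrient table
#'
#' Resolves every record's food in the composition table and computes the
#' item's raw and TID-adjusted nutrient vectors.
#'
#' @param records Clean diary records (from [validate_days()]; must carry
#'   \code{time_min}).
#' @param composition Validated composition table.
#' @return Data frame: record identifiers, \code{food_group},
#'   \code{protein_raw}, and adjusted columns \code{protein} plus one per IAA
#'   (all g).
#' @export
item_nutrients <- function(records, composition) {
  validate_composition(composition)
  idx <- match(records$food_id, composition$food_id)
  if (anyNA(idx))
    stop("unresolvable food_id(s): ",
         paste(sort(unique(records$food_id[is.na(idx)])), collapse = ", "))
  comp <- composition[idx, , drop = FALSE]
  protein_raw <- comp$protein_per_100g * records$amount_g / 100
  aa_mg <- as.matrix(comp[paste0("aa_", IAA_NAMES, "_mg_per_g_protein")])
  raw_iaa <- aa_mg * protein_raw / 1000
  tid_p <- comp$tid_protein
  tid_aa <- as.matrix(comp[paste0("tid_", IAA_NAMES)])
  adj <- cbind(protein = protein_raw * tid_p, raw_iaa * tid_aa)
  colnames(adj) <- NUTRIENT_NAMES
  out <- data.frame(participant_id = records$participant_id,
                    date = records$date,
                    time_min = records$time_min,
                    food_id = records$food_id,
                    food_group = comp$food_group,
                    amount_g = records$amount_g,
                    protein_raw = protein_raw,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(adj))
}

#' Drop items below the per-EO protein filter
#'
#' Items contributing less than \code{threshold} grams of protein within
#' their EO are excluded before summation (strict \code{<}; an item at
#' exactly the threshold is retained). By default the filter is applied to
#' digestibility-unadjusted item protein; set \code{on = "adjusted"} to
#' filter on utilisable protein instead.
#'
#' @param items Item table from [item_nutrients()].
#' @param threshold Grams of protein, default 0.5.
#' @param on \code{"raw"} (default) or \code{"adjusted"}.
#' @return The retained rows of \code{items}.
#' @export
filter_low_protein_items <- function(items, threshold = 0.5,
                                     on = c("raw", "adjusted")) {
  on <- match.arg(on)
  p <- if (on == "raw") items$protein_raw else items$protein
  out <- items[p >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Protein coverage retained by the item filter
#'
#' @param pre_items,post_items Item tables before and after filtering, over
#'   the same record universe.
#' @param on Protein column the coverage is measured on (default raw).
#' @return List: \code{cohort_fraction} (retained share of total cohort
#'   protein), \code{per_participant} (data frame of per-participant
#'   fractions) and \code{min_participant_fraction}. Participants with zero
#'   pre-filter protein get \code{NA} coverage and are flagged.
#' @export
coverage_report <- function(pre_items, post_items,
                            on = c("raw", "adjusted")) {
  on <- match.arg(on)
  col <- if (on == "raw") "protein_raw" else "protein"
  pre_tot <- sum(pre_items[[col]])
  post_tot <- sum(post_items[[col]])
  cohort <- if (pre_tot > 0) post_tot / pre_tot else NA_real_
  pre_by <- tapply(pre_items[[col]], pre_items$participant_id, sum)
  post_by <- tapply(post_items[[col]], post_items$participant_id, sum)
  ids <- names(pre_by)
  frac <- as.numeric(post_by[ids]) / as.numeric(pre_by)
  frac[is.na(frac) & !(ids %in% post_items$participant_id)] <-
    ifelse(as.numeric(pre_by)[is.na(frac) &
                                !(ids %in% post_items$participant_id)] > 0,
           0, NA_real_)
  frac[as.numeric(pre_by) == 0] <- NA_real_
  per <- data.frame(participant_id = ids, retained_fraction = frac,
                    stringsAsFactors = FALSE)
  list(cohort_fraction = cohort,
       per_participant = per,
       min_participant_fraction =
         if (all(is.na(frac))) NA_real_ else min(frac, na.rm = TRUE),
       undefined_participants = ids[is.na(frac)])
}

#' Build eating occasions from retained items
#'
#' Items sharing an exact (participant, date, time) form one EO; their
#' adjusted nutrient vectors are summed. EOs whose items were all filtered
#' away do not appear. Days are indexed 1-based per participant in date
#' order; calendar gaps do not renumber days.
#'
#' @param items Retained item table (see [filter_low_protein_items()]).
#' @return EO data frame: participant_id, date, day_index, time_min,
#'   item_count, protein and one column per IAA (g), ordered by participant,
#'   day and clock time.
#' @export
build_eos <- function(items) {
  if (nrow(items) == 0L) {
    out <- data.frame(participant_id = character(0), date = character(0),
                      day_index = integer(0), time_min = integer(0),
                      item_count = integer(0), stringsAsFactors = FALSE)
    for (nm in NUTRIENT_NAMES) out[[nm]] <- numeric(0)
    return(out)
  }
  key <- paste(items$participant_id, items$date,
               sprintf("%04d", items$time_min), sep = "\r")
  nut <- rowsum(as.matrix(items[NUTRIENT_NAMES]), key)
  cnt <- rowsum(rep(1L, nrow(items)), key)
  parts <- do.call(rbind, strsplit(rownames(nut), "\r", fixed = TRUE))
  eos <- data.frame(participant_id = parts[, 1], date = parts[, 2],
                    time_min = as.integer(parts[, 3]),
                    item_count = as.integer(cnt),
                    stringsAsFactors = FALSE)
  eos <- cbind(eos, as.data.frame(nut, row.names = FALSE))
  # day_index: rank of date among the participant's distinct dates
  eos$day_index <- NA_integer_
  for (pid in unique(eos$participant_id)) {
    sel <- eos$participant_id == pid
    dates <- sort(unique(eos$date[sel]))
    eos$day_index[sel] <- match(eos$date[sel], dates)
  }
  eos <- eos[order(eos$participant_id, eos$day_index, eos$time_min), ]
  rownames(eos) <- NULL
  eos[c("participant_id", "date", "day_index", "time_min", "item_count",
        NUTRIENT_NAMES)]
}

#' Full diary-to-EO pipeline stage
#'
#' Convenience composition of [validate_days()], [item_nutrients()],
#' [filter_low_protein_items()], [coverage_report()] and [build_eos()].
#'
#' @param records Raw diary records.
#' @param composition Validated composition table.
#' @param min_item_protein Item filter threshold in g (default 0.5).
#' @param filter_on \code{"raw"} or \code{"adjusted"} item protein.
#' @return List: \code{eos}, \code{items} (retained), \code{items_pre}
#'   (pre-filter), \code{coverage}, \code{excluded_days}.
#' @export
process_diary <- function(records, composition, min_item_protein = 0.5,
                          filter_on = c("raw", "adjusted")) {
  filter_on <- match.arg(filter_on)
  v <- validate_days(records)
  items_pre <- item_nutrients(v$clean, composition)
  items <- filter_low_protein_items(items_pre, min_item_protein, filter_on)
  list(eos = build_eos(items),
       items = items,
       items_pre = items_pre,
       coverage = coverage_report(items_pre, items),
       excluded_days = v$excluded)
}

#' Encode eating occasions as per-day intake series
#'
#' One series per retained individual.day: the ordered vector of per-EO
#' protein amounts, with clock times and per-EO IAA vectors carried
#' alongside. Series are labelled \code{"<participant>.<day>"}.
#'
#' @param eos EO data frame from [build_eos()].
#' @return List of class \code{intake_series_set}; each element has
#'   \code{series_id}, \code{participant_id}, \code{day_index},
#'   \code{values} (protein g per EO), \code{times} (minutes since 00:00,
#'   strictly increasing) and \code{iaa} (EO x 7 matrix, g).
#' @export
to_series <- function(eos) {
  if (nrow(eos) == 0L)
    return(structure(list(), class = "intake_series_set"))
  f <- factor(paste0(eos$participant_id, ".", eos$day_index),
              levels = unique(paste0(eos$participant_id, ".", eos$day_index)))
  out <- lapply(split(seq_len(nrow(eos)), f), function(ix) {
    sub <- eos[ix, , drop = FALSE]
    stopifnot(!is.unsorted(sub$time_min, strictly = TRUE))
    list(series_id = paste0(sub$participant_id[1], ".", sub$day_index[1]),
         participant_id = sub$participant_id[1],
         day_index = sub$day_index[1],
         values = sub$protein,
         times = sub$time_min,
         iaa = as.matrix(sub[IAA_NAMES]))
  })
  names(out) <- vapply(out, `[[`, "", "series_id")
  structure(out, class = "intake_series_set")
}

#' @export
print.intake_series_set <- function(x, ...) {
  cat("Intake series set:", length(x), "individual.days\n")
  if (length(x)) {
    len <- vapply(x, function(s) length(s$values), 0L)
    cat("  EOs per day: min", min(len), "median", stats::median(len),
        "max", max(len), "\n")
  }
  invisible(x)
}
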