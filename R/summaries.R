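# Per-cluster protein-adequacy statistics, food-group contributions, hourly
# temporal profiles and nonparametric cluster comparisons.

#' Protein-adequacy thresholds
#'
#' Defaults: 20 g protein per eating occasion (absolute) and 0.24 g/kg body
#' weight per EO (relative) — the lowest per-meal amounts reported to
#' stimulate muscle protein synthesis — and the Australia/NZ Estimated
#' Average Requirement for daily protein, 0.68 g/kg/d (male) and 0.60 g/kg/d
#' (female).
#'
#' @param absolute_per_eo g per EO.
#' @param relative_per_eo g per kg body weight per EO.
#' @param ear_male,ear_female g per kg body weight per day.
#' @return Object of class \code{threshold_config}.
#' @export
threshold_config <- function(absolute_per_eo = 20, relative_per_eo = 0.24,
                             ear_male = 0.68, ear_female = 0.60) {
  stopifnot(absolute_per_eo > 0, relative_per_eo > 0,
            ear_male > 0, ear_female > 0)
  structure(list(absolute_per_eo = absolute_per_eo,
                 relative_per_eo = relative_per_eo,
                 ear_male = ear_male, ear_female = ear_female),
            class = "threshold_config")
}

#' Flag eating occasions against the per-EO thresholds
#'
#' "Below" is a strict inequality throughout: an EO at exactly the threshold
#' is not below it. A missing body weight leaves the relative flag missing.
#'
#' @param protein Per-EO protein, g (vectorised).
#' @param body_weight Body weight, kg (scalar or vector; may be NA).
#' @param cfg [threshold_config()].
#' @return Data frame: \code{below_absolute}, \code{below_relative}.
#' @export
eo_threshold_flags <- function(protein, body_weight,
                               cfg = threshold_config()) {
  if (any(!is.na(body_weight) & body_weight <= 0))
    stop("body_weight must be positive")
  data.frame(below_absolute = protein < cfg$absolute_per_eo,
             below_relative = ifelse(is.na(body_weight), NA,
                                     protein / body_weight <
                                       cfg$relative_per_eo))
}

# Map each EO row to its series cluster via the "<participant>.<day>" key.
eo_cluster_labels <- function(eos, labels) {
  key <- paste0(eos$participant_id, ".", eos$day_index)
  miss <- setdiff(unique(key), names(labels))
  if (length(miss))
    stop("labels do not cover individual.day(s): ",
         paste(head(miss, 5), collapse = ", "))
  unname(labels[key])
}

#' Per-cluster adequacy report
#'
#' Per-EO means are EO-weighted (every retained EO counts once); percentages
#' below thresholds are computed over all EOs pooled within a cluster, with a
#' secondary per-individual view (each individual's mean EO protein within
#' the cluster against the same thresholds). Daily protein per kg body
#' weight is compared with the sex-specific EAR. Kruskal-Wallis and
#' Bonferroni-adjusted Dunn tests compare protein per EO, total IAA per EO
#' and body composition across clusters.
#'
#' @param labels Named integer vector: cluster per series_id
#'   (\code{"<participant>.<day>"}).
#' @param eos EO data frame ([build_eos()]).
#' @param participants Participant table (participant_id, sex,
#'   body_weight_kg, optionally bmi, body_fat_pct); may be NULL, which
#'   leaves weight-relative metrics missing.
#' @param thresholds [threshold_config()].
#' @return Object of class \code{cluster_report}: \code{cluster_table},
#'   \code{individual_table}, \code{tests} (KW + Dunn per metric),
#'   \code{thresholds}, \code{n_eos_total}.
#' @export
cluster_summary <- function(labels, eos, participants = NULL,
                            thresholds = threshold_config()) {
  if (!length(labels)) stop("empty label set")
  if (nrow(eos) == 0L) stop("no eating occasions to summarise")
  cl <- eo_cluster_labels(eos, labels)
  clusters <- sort(unique(as.vector(labels)))

  bw <- bmi <- bf <- sex <- NULL
  if (!is.null(participants)) {
    ix <- match(eos$participant_id, participants$participant_id)
    bw <- participants$body_weight_kg[ix]
    sex <- participants$sex[ix]
    if ("bmi" %in% names(participants)) bmi <- participants$bmi[ix]
    if ("body_fat_pct" %in% names(participants))
      bf <- participants$body_fat_pct[ix]
  }
  flags <- eo_threshold_flags(eos$protein,
                              if (is.null(bw)) NA_real_ else bw, thresholds)
  total_iaa <- rowSums(as.matrix(eos[IAA_NAMES]))
  series_key <- paste0(eos$participant_id, ".", eos$day_index)

  # daily totals per individual.day for EOs/day and EAR comparison
  day_protein <- tapply(eos$protein, series_key, sum)
  day_n_eo <- tapply(rep(1L, nrow(eos)), series_key, sum)
  day_cluster <- unname(labels[names(day_protein)])
  day_pid <- sub("\\.[0-9]+$", "", names(day_protein))
  if (!is.null(participants)) {
    dix <- match(day_pid, participants$participant_id)
    day_bw <- participants$body_weight_kg[dix]
    day_sex <- participants$sex[dix]
    day_ear <- ifelse(day_sex == "M", thresholds$ear_male,
                      thresholds$ear_female)
    day_gkg <- as.numeric(day_protein) / day_bw
  } else {
    day_gkg <- rep(NA_real_, length(day_protein))
    day_ear <- rep(NA_real_, length(day_protein))
  }

  rows <- lapply(clusters, function(g) {
    sel <- cl == g
    dsel <- day_cluster == g
    n_eo <- sum(sel)
    if (n_eo == 0L) return(NULL)
    rel <- flags$below_relative[sel]
    gkg_eo <- if (is.null(bw)) NA_real_ else
      mean((eos$protein / bw)[sel], na.rm = TRUE)
    data.frame(
      cluster = g,
      n_series = sum(dsel),
      n_eos = n_eo,
      mean_protein_g = mean(eos$protein[sel]),
      sd_protein_g = sd(eos$protein[sel]),
      mean_protein_g_per_kg = gkg_eo,
      pct_eo_below_absolute = 100 * mean(flags$below_absolute[sel]),
      pct_eo_below_relative =
        if (all(is.na(rel))) NA_real_ else 100 * mean(rel, na.rm = TRUE),
      mean_total_iaa_g = mean(total_iaa[sel]),
      mean_eos_per_day = mean(as.numeric(day_n_eo)[dsel]),
      mean_daily_protein_g_per_kg = mean(day_gkg[dsel], na.rm = TRUE),
      pct_days_below_ear =
        if (all(is.na(day_gkg[dsel]))) NA_real_ else
          100 * mean(day_gkg[dsel] < day_ear[dsel], na.rm = TRUE),
      mean_bmi = if (is.null(bmi)) NA_real_ else mean(bmi[sel], na.rm = TRUE),
      mean_body_fat_pct =
        if (is.null(bf)) NA_real_ else mean(bf[sel], na.rm = TRUE)
    )
  })
  cluster_table <- do.call(rbind, rows)
  dropped <- setdiff(clusters, cluster_table$cluster)
  if (length(dropped))
    warning("cluster(s) with zero EOs excluded: ",
            paste(dropped, collapse = ", "))

  # secondary per-individual metric: mean EO protein per individual within
  # each cluster, compared to the same thresholds
  ind_key <- paste(cl, eos$participant_id, sep = "\r")
  ind_mean <- tapply(eos$protein, ind_key, mean)
  ind_parts <- do.call(rbind, strsplit(names(ind_mean), "\r", fixed = TRUE))
  ind_bw <- if (is.null(participants)) NA_real_ else
    participants$body_weight_kg[match(ind_parts[, 2],
                                      participants$participant_id)]
  ind_flags <- eo_threshold_flags(as.numeric(ind_mean), ind_bw, thresholds)
  individual_table <- do.call(rbind, lapply(clusters, function(g) {
    sel <- ind_parts[, 1] == as.character(g)
    if (!any(sel)) return(NULL)
    rel <- ind_flags$below_relative[sel]
    data.frame(
      cluster = g,
      n_individuals = sum(sel),
      pct_individuals_below_absolute =
        100 * mean(ind_flags$below_absolute[sel]),
      pct_individuals_below_relative =
        if (all(is.na(rel))) NA_real_ else 100 * mean(rel, na.rm = TRUE))
  }))

  metric_tests <- function(x, by) {
    groups <- split(x, by)
    groups <- groups[vapply(groups, function(v) sum(!is.na(v)) > 0, TRUE)]
    if (length(groups) < 2L) return(NULL)
    groups <- lapply(groups, function(v) v[!is.na(v)])
    list(kw = kruskal_wallis(groups), dunn = dunn_test(groups))
  }
  tests <- list(protein_per_eo = metric_tests(eos$protein, cl),
                total_iaa_per_eo = metric_tests(total_iaa, cl))
  if (!is.null(bmi)) tests$bmi <- metric_tests(bmi, cl)
  if (!is.null(bf)) tests$body_fat_pct <- metric_tests(bf, cl)

  structure(list(cluster_table = cluster_table,
                 individual_table = individual_table,
                 tests = tests,
                 thresholds = thresholds,
                 n_eos_total = nrow(eos)),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, digits = 3, ...) {
  cat("Cluster adequacy report (", x$n_eos_total, " EOs)\n", sep = "")
  print(format(x$cluster_table, digits = digits), row.names = FALSE)
  cat("\nKruskal-Wallis p-values:\n")
  for (nm in names(x$tests)) {
    t <- x$tests[[nm]]
    if (is.null(t)) next
    cat(sprintf("  %-18s H = %s, p = %s%s\n", nm,
                format(t$kw$H, digits = digits),
                format(t$kw$p, digits = digits),
                if (!is.na(t$kw$p) && t$kw$p < 0.05) " *" else ""))
  }
  invisible(x)
}

#' Food-group contribution to protein and IAA intake per cluster
#'
#' For every cluster and nutrient (protein and each tracked IAA), the
#' percentage of the cluster's total intake contributed by each food group.
#' Groups contributing less than 5\% of the cluster's protein are folded
#' into an "Others" bucket (for every nutrient). Percentages per
#' (cluster, nutrient) sum to 100.
#'
#' @param items Retained item table (see [process_diary()]), annotated with
#'   \code{food_group}.
#' @param labels Named cluster labels per series_id.
#' @param others_below Protein-share threshold for the bucket, default 5 (%).
#' @return Long data frame: \code{cluster}, \code{nutrient},
#'   \code{food_group}, \code{grams}, \code{pct}.
#' @export
foodgroup_contribution <- function(items, labels, others_below = 5) {
  if (any(is.na(items$food_group) | items$food_group == ""))
    stop("items must carry food_group annotations")
  # day_index from the same date-ranking rule as build_eos
  items$day_index <- NA_integer_
  for (pid in unique(items$participant_id)) {
    sel <- items$participant_id == pid
    dates <- sort(unique(items$date[sel]))
    items$day_index[sel] <- match(items$date[sel], dates)
  }
  cl <- eo_cluster_labels(items, labels)
  out <- list()
  for (g in sort(unique(as.vector(labels)))) {
    sub <- items[cl == g, , drop = FALSE]
    if (!nrow(sub)) next
    tot <- rowsum(as.matrix(sub[NUTRIENT_NAMES]), sub$food_group)
    protein_pct <- 100 * tot[, "protein"] / sum(tot[, "protein"])
    bucket <- ifelse(protein_pct < others_below, "Others",
                     rownames(tot))
    tot <- rowsum(tot, bucket)
    pct <- 100 * sweep(tot, 2, colSums(tot), "/")
    for (nm in colnames(tot)) {
      out[[length(out) + 1L]] <- data.frame(
        cluster = g, nutrient = nm, food_group = rownames(tot),
        grams = tot[, nm], pct = pct[, nm], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hourly intake profile per cluster
#'
#' Bins EOs into 24 hourly intervals (bin \eqn{h} holds EOs with
#' \eqn{h \le} time-in-hours \eqn{< h + 1}) and reports the mean per-EO
#' intake of each nutrient within every (cluster, hour) cell. Cells with no
#' EOs are \code{NA}, not zero.
#'
#' @param eos EO data frame.
#' @param labels Named cluster labels per series_id.
#' @return 3-d array \code{[cluster, hour, nutrient]} with dimnames; hours
#'   are \code{"0" ... "23"}.
#' @export
hourly_profile <- function(eos, labels) {
  cl <- eo_cluster_labels(eos, labels)
  clusters <- sort(unique(as.vector(labels)))
  hour <- eos$time_min %/% 60L
  arr <- array(NA_real_,
               dim = c(length(clusters), 24L, length(NUTRIENT_NAMES)),
               dimnames = list(cluster = as.character(clusters),
                               hour = as.character(0:23),
                               nutrient = NUTRIENT_NAMES))
  for (gi in seq_along(clusters)) {
    sel <- cl == clusters[gi]
    if (!any(sel)) next
    for (h in sort(unique(hour[sel]))) {
      cell <- sel & hour == h
      arr[gi, h + 1L, ] <- colMeans(as.matrix(eos[cell, NUTRIENT_NAMES,
                                                  drop = FALSE]))
    }
  }
  arr
}
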