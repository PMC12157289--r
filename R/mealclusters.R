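# Central fitting function: diary -> eating occasions -> protein series ->
# normalised DTW dissimilarities -> Ward.D2 tree -> k clusters, with
# silhouette and MDS diagnostics attached.

#' Cluster daily protein intake patterns
#'
#' Runs the full analysis on a timestamped food diary: excludes days with
#' missing time records, computes digestibility-adjusted nutrients per item,
#' drops items under the low-protein filter, sums nutrients per eating
#' occasion, encodes each retained individual.day as an ordered per-EO
#' protein series, compares all series with length-normalised dynamic time
#' warping, clusters the dissimilarity matrix with Ward.D2 agglomeration and
#' cuts the tree at \code{k}. Cluster numbers are assigned by increasing
#' mean protein per EO (cluster 1 = lowest; ties broken by cluster size), so
#' the numbering is comparable across data sets.
#'
#' @param diary Diary data frame (participant_id, date, time, food_id,
#'   amount_g) or path to its CSV.
#' @param composition Composition table or path ([read_composition()]).
#' @param participants Optional participant table or path; required for all
#'   body-weight-relative statistics.
#' @param k Number of clusters (default 3).
#' @param thresholds [threshold_config()] used by [summary.meal_clusters()].
#' @param min_item_protein Low-protein item filter, g (default 0.5).
#' @param filter_on Apply the item filter to \code{"raw"} (default) or
#'   \code{"adjusted"} item protein.
#' @param method Linkage variant, \code{"ward.D2"} (default) or
#'   \code{"ward.D"}.
#' @param mds_dims Dimensions of the MDS embedding (default 2).
#' @return Object of class \code{meal_clusters} with components
#'   \code{labels} (cluster per series_id), \code{series}, \code{dm}
#'   (dissimilarity matrix), \code{tree}, \code{silhouette}, \code{mds},
#'   \code{eos}, \code{items}, \code{coverage}, \code{excluded_days},
#'   \code{participants}, \code{k}, \code{thresholds}.
#' @seealso [summary.meal_clusters()], [plot.meal_clusters()],
#'   [scan_k()], [run_pipeline()]
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_config(n_individuals = 12, n_days = 2,
#'                                      n_corrupted_days = 0, seed = 7))
#' fit <- meal_clusters(coh$diary, synthetic_composition(),
#'                      coh$participants, k = 3)
#' fit
meal_clusters <- function(diary, composition, participants = NULL, k = 3,
                          thresholds = threshold_config(),
                          min_item_protein = 0.5,
                          filter_on = c("raw", "adjusted"),
                          method = c("ward.D2", "ward.D"),
                          mds_dims = 2) {
  filter_on <- match.arg(filter_on)
  method <- match.arg(method)
  if (is.character(diary)) diary <- read_diary(diary)
  if (is.character(composition)) composition <- read_composition(composition)
  if (is.character(participants))
    participants <- read_participants(participants)
  if (k < 1) stop("k must be at least 1")

  proc <- process_diary(diary, composition, min_item_protein, filter_on)
  series <- to_series(proc$eos)
  if (length(series) < 2L)
    stop("fewer than 2 retained individual.days; nothing to cluster")
  dm <- distance_matrix(series)
  tree <- ward_linkage(dm, method)
  raw_labels <- cut_tree(tree, k)

  # semantic renumbering: increasing mean protein per EO, ties by size
  eo_raw <- raw_labels[paste0(proc$eos$participant_id, ".",
                              proc$eos$day_index)]
  mean_p <- tapply(proc$eos$protein, eo_raw, mean)
  sizes <- table(raw_labels)
  ids <- as.integer(names(mean_p))
  ord <- ids[order(mean_p, as.integer(sizes[names(mean_p)]))]
  labels <- match(raw_labels, ord)
  names(labels) <- names(raw_labels)

  sil <- if (k >= 2) avg_silhouette(dm, labels) else NULL
  mds <- classical_mds(dm, dims = mds_dims)

  structure(list(call = match.call(), k = k, labels = labels,
                 series = series, dm = dm, tree = tree,
                 silhouette = sil, mds = mds,
                 eos = proc$eos, items = proc$items,
                 items_pre = proc$items_pre,
                 coverage = proc$coverage,
                 excluded_days = proc$excluded_days,
                 participants = participants,
                 thresholds = thresholds,
                 method = method),
            class = "meal_clusters")
}

#' @export
print.meal_clusters <- function(x, ...) {
  cat("Meal-pattern clustering (normalised DTW +", x$method, "linkage)\n")
  cat("  individual.days:", length(x$series),
      "   excluded days:", nrow(x$excluded_days), "\n")
  cat("  k =", x$k, " cluster sizes:",
      paste(table(x$labels), collapse = " / "), "\n")
  if (!is.null(x$silhouette))
    cat("  mean silhouette width:",
        format(x$silhouette$mean_width, digits = 3), "\n")
  if (!is.null(x$coverage$cohort_fraction))
    cat("  protein retained by item filter:",
        sprintf("%.1f%%", 100 * x$coverage$cohort_fraction), "\n")
  cat("  MDS variance fractions:",
      paste(sprintf("%.1f%%", 100 * x$mds$variance_fraction),
            collapse = ", "), "\n")
  invisible(x)
}

#' Summarise a meal-pattern clustering
#'
#' Builds the per-cluster adequacy report ([cluster_summary()]) from the
#' fitted object.
#'
#' @param object A \code{meal_clusters} fit.
#' @param ... Unused.
#' @return A \code{cluster_report}.
#' @export
summary.meal_clusters <- function(object, ...) {
  cluster_summary(object$labels, object$eos, object$participants,
                  object$thresholds)
}

#' Plot a meal-pattern clustering
#'
#' Scatter of the 2-D MDS embedding coloured by cluster, axis labels carrying
#' the per-dimension variance fractions.
#'
#' @param x A \code{meal_clusters} fit.
#' @param ... Passed to \code{plot.default}.
#' @export
plot.meal_clusters <- function(x, ...) {
  co <- x$mds$coordinates
  vf <- x$mds$variance_fraction
  cols <- grDevices::hcl.colors(max(x$labels), "Dark 3")
  graphics::plot(co[, 1], co[, 2], col = cols[x$labels],
                 pch = 19, cex = 0.6,
                 xlab = sprintf("Dim 1 (%.1f%%)", 100 * vf[1]),
                 ylab = if (ncol(co) >= 2)
                   sprintf("Dim 2 (%.1f%%)", 100 * vf[2]) else "",
                 ...)
  graphics::legend("topright", legend = paste("cluster", seq_len(max(x$labels))),
                   col = cols, pch = 19, bty = "n", cex = 0.8)
  invisible(x)
}

#' Silhouette scan over candidate k for a fitted object
#'
#' @param fit A \code{meal_clusters} fit.
#' @param k_range Candidate cluster counts (default 2:8).
#' @return Data frame from [silhouette_scan()].
#' @export
scan_k <- function(fit, k_range = 2:8) {
  silhouette_scan(fit$dm, fit$tree, k_range)
}
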