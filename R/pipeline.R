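# End-to-end orchestration: read the three CSVs, fit, write every artifact
# with checksums. The pipeline is a pure function of (inputs, config), so a
# rerun on identical inputs reproduces identical artifacts.

#' Pipeline configuration
#'
#' @param diary,composition,participants Paths to the three input CSVs
#'   (participants may be NULL).
#' @param out_dir Output directory.
#' @param k Number of clusters (default 3).
#' @param k_scan Candidate cluster counts for the silhouette scan.
#' @param thresholds [threshold_config()].
#' @param min_item_protein,filter_on Item filter settings (see
#'   [meal_clusters()]).
#' @param method Linkage variant.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(diary, composition, participants = NULL,
                            out_dir = "mealdtw-output", k = 3,
                            k_scan = 2:6,
                            thresholds = threshold_config(),
                            min_item_protein = 0.5,
                            filter_on = "raw",
                            method = "ward.D2") {
  stopifnot(k >= 2)
  structure(list(diary = diary, composition = composition,
                 participants = participants, out_dir = out_dir,
                 k = k, k_scan = k_scan, thresholds = thresholds,
                 min_item_protein = min_item_protein,
                 filter_on = filter_on, method = method),
            class = "pipeline_config")
}

write_csv_artifact <- function(df, path) {
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

#' Run the full analysis pipeline and write its artifacts
#'
#' Stages: day validation, EO construction, low-protein filtering, series
#' encoding, DTW dissimilarity matrix, Ward linkage, cut at \code{k},
#' silhouette scan, MDS, per-cluster summaries and tests. Every artifact is
#' written under \code{cfg$out_dir} and listed, with MD5 checksums and
#' record counts, in \code{manifest.json}.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the fitted \code{meal_clusters} object,
#'   the manifest, and the artifact paths.
#' @export
run_pipeline <- function(cfg) {
  for (p in c(cfg$diary, cfg$composition, cfg$participants)) {
    if (!file.exists(p))
      stop("configuration error: input file not found: ", p)
  }
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)

  fit <- meal_clusters(cfg$diary, cfg$composition, cfg$participants,
                       k = cfg$k, thresholds = cfg$thresholds,
                       min_item_protein = cfg$min_item_protein,
                       filter_on = cfg$filter_on, method = cfg$method)
  report <- summary(fit)
  scan <- scan_k(fit, cfg$k_scan)
  contrib <- foodgroup_contribution(fit$items, fit$labels)
  hourly <- hourly_profile(fit$eos, fit$labels)

  out <- function(f) file.path(cfg$out_dir, f)
  paths <- character(0)

  dm_df <- data.frame(series_id = rownames(fit$dm), fit$dm,
                      check.names = FALSE)
  paths["distance_matrix"] <- write_csv_artifact(dm_df, out("distance_matrix.csv"))
  paths["linkage"] <- write_csv_artifact(
    data.frame(step = seq_along(fit$tree$height),
               member_a = fit$tree$merge[, 1],
               member_b = fit$tree$merge[, 2],
               height = fit$tree$height,
               new_size = fit$tree$merge_sizes),
    out("linkage.csv"))
  paths["labels"] <- write_csv_artifact(
    data.frame(series_id = names(fit$labels), cluster = fit$labels),
    out("labels.csv"))
  paths["silhouette"] <- write_csv_artifact(scan, out("silhouette_scan.csv"))
  emb <- data.frame(series_id = rownames(fit$mds$coordinates),
                    fit$mds$coordinates)
  paths["embedding"] <- write_csv_artifact(emb, out("embedding.csv"))
  jsonlite::write_json(
    list(eigenvalues = fit$mds$eigenvalues,
         variance_fraction = fit$mds$variance_fraction,
         n_negative = fit$mds$n_negative),
    out("mds_eigenvalues.json"), digits = NA, auto_unbox = FALSE)
  paths["mds_eigenvalues"] <- out("mds_eigenvalues.json")
  paths["eo_table"] <- write_csv_artifact(fit$eos, out("eo_table.csv"))
  paths["excluded_days"] <- write_csv_artifact(fit$excluded_days,
                                               out("excluded_days.csv"))
  paths["cluster_summary"] <- write_csv_artifact(report$cluster_table,
                                                 out("cluster_summary.csv"))
  paths["individual_summary"] <- write_csv_artifact(
    report$individual_table, out("individual_summary.csv"))
  paths["foodgroup_contribution"] <- write_csv_artifact(
    contrib, out("foodgroup_contribution.csv"))
  hourly_long <- expand.grid(cluster = dimnames(hourly)$cluster,
                             hour = dimnames(hourly)$hour,
                             nutrient = dimnames(hourly)$nutrient,
                             stringsAsFactors = FALSE)
  hourly_long$mean_g <- as.vector(hourly)
  paths["hourly_profile"] <- write_csv_artifact(hourly_long,
                                                out("hourly_profile.csv"))
  kw_rows <- do.call(rbind, lapply(names(report$tests), function(nm) {
    t <- report$tests[[nm]]
    if (is.null(t)) return(NULL)
    data.frame(metric = nm, H = t$kw$H, df = t$kw$df, p = t$kw$p,
               significant = !is.na(t$kw$p) & t$kw$p < 0.05)
  }))
  paths["tests_kw"] <- write_csv_artifact(kw_rows, out("tests_kw.csv"))
  dunn_rows <- do.call(rbind, lapply(names(report$tests), function(nm) {
    t <- report$tests[[nm]]
    if (is.null(t)) return(NULL)
    cbind(metric = nm, t$dunn)
  }))
  paths["tests_dunn"] <- write_csv_artifact(dunn_rows, out("tests_dunn.csv"))
  jsonlite::write_json(
    list(cohort_fraction = fit$coverage$cohort_fraction,
         min_participant_fraction = fit$coverage$min_participant_fraction),
    out("coverage.json"), digits = NA, auto_unbox = TRUE)
  paths["coverage"] <- out("coverage.json")

  manifest <- list(
    artifacts = lapply(seq_along(paths), function(i)
      list(name = names(paths)[i],
           file = basename(paths[[i]]),
           md5 = unname(tools::md5sum(paths[[i]])))),
    record_counts = list(
      diary_records = nrow(read_diary(cfg$diary)),
      excluded_days = nrow(fit$excluded_days),
      retained_series = length(fit$series),
      retained_eos = nrow(fit$eos),
      k = cfg$k),
    config = list(k = cfg$k, k_scan = cfg$k_scan,
                  min_item_protein = cfg$min_item_protein,
                  filter_on = cfg$filter_on, method = cfg$method)
  )
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths["manifest"] <- out("manifest.json")

  message("pipeline: ", length(fit$series), " series, ",
          nrow(fit$eos), " EOs, k = ", cfg$k)
  invisible(list(fit = fit, manifest = manifest, paths = paths))
}
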