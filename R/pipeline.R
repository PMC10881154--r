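#' Run the full quantification pipeline on a data bundle
#'
#' Orchestrates every stage over in-memory tables (as produced by
#' [simulate_study()] or assembled from the readers): per-condition
#' orientation-bin summaries and randomization scores, morphometry,
#' tumor-cohort summaries with between-genotype comparisons, and
#' live-imaging track classification. Results carry a manifest with the
#' seed, a configuration fingerprint and the package version so reruns are
#' reproducible.
#'
#' @param data list with any subset of: `angle_samples` (named list of
#'   [angle_sample()]), `tissue` (`counts` + `geometry`), `cohorts`
#'   (`tumors` + `mice`), `tracks` + `frames`.
#' @param seed integer seed for the Monte-Carlo stages.
#' @param n_reps null repetitions for the randomization score.
#' @param ks_mode KS p-value mode, `"exact"` or `"asymptotic"`.
#' @param planar_threshold live-imaging planar criterion, degrees.
#' @param out_dir optional directory; when given, tidy CSV / JSON outputs
#'   and the manifest are written there.
#' @return list with elements `bin_summaries`, `randomization`,
#'   `morphometry`, `cohort`, `tracks` and `manifest`.
#' @export
run_pipeline <- function(data, seed = 1, n_reps = 10000,
                         ks_mode = c("exact", "asymptotic"),
                         planar_threshold = 20, out_dir = NULL) {
  ks_mode <- match.arg(ks_mode)
  result <- list()
  notices <- character()

  if (!is.null(data$angle_samples)) {
    result$bin_summaries <- lapply(data$angle_samples, distribution_summary)
    result$randomization <- lapply(data$angle_samples, function(s)
      randomization_score(s, randomization_config(n_reps = n_reps, seed = seed,
                                                  ks_mode = ks_mode)))
  }

  if (!is.null(data$tissue)) {
    result$morphometry <- aggregate_morphometry(data$tissue$counts, data$tissue$geometry)
  }

  if (!is.null(data$cohorts)) {
    result$cohort <- list(summary = cohort_summary(data$cohorts$tumors, data$cohorts$mice))
    genos <- unique(data$cohorts$mice$genotype)
    if (length(genos) >= 2) {
      tt <- data$cohorts$tumors
      mm <- data$cohorts$mice
      burdens <- lapply(genos[1:2], function(g) {
        ids <- mm$mouse_id[mm$genotype == g]
        vapply(ids, function(id) burden(tt$volume_mm3[tt$mouse_id == id]), 0)
      })
      result$cohort$comparison <- c(list(genotypes = genos[1:2]),
                                    compare_groups(burdens[[1]], burdens[[2]]))
      s <- result$cohort$summary
      hi <- which.max(s$mean_burden_mm3); lo <- which.min(s$mean_burden_mm3)
      if (hi != lo && s$mean_burden_mm3[lo] > 0)
        result$cohort$burden_fold <- list(
          numerator = s$genotype[hi], denominator = s$genotype[lo],
          fold = fold_change(s$mean_burden_mm3[hi], s$mean_burden_mm3[lo]))
    } else {
      notices <- c(notices, "single-genotype cohort: between-group comparison skipped")
    }
  }

  if (!is.null(data$tracks)) {
    cl <- classify_tracks(data$tracks, data$frames, planar_threshold = planar_threshold)
    result$tracks <- list(
      classified = cl,
      resolution_table = table(cl$resolution),
      reintegration_table = table(cl$reintegration, useNA = "no"))
  }

  cfg <- list(seed = seed, n_reps = n_reps, ks_mode = ks_mode,
              planar_threshold = planar_threshold,
              bin_boundaries = c(30, 60))
  result$manifest <- list(
    package = "epispindle",
    version = as.character(utils::packageVersion("epispindle")),
    seed = seed, config = cfg,
    config_hash = fnv1a_hash(jsonlite::toJSON(cfg, auto_unbox = TRUE)),
    stages = names(result), notices = notices)
  for (msg in notices) message(msg)

  if (!is.null(out_dir)) {
    if (!is.null(result$bin_summaries)) {
      write_json_summary(lapply(result$bin_summaries, unclass),
                         file.path(out_dir, "bin_summaries.json"))
      write_json_summary(lapply(result$randomization, function(r)
        unclass(r)[c("condition", "score_pct", "n_reps", "null_size", "seed", "ks_mode_used")]),
        file.path(out_dir, "randomization_scores.json"))
    }
    if (!is.null(result$morphometry)) {
      write_table(result$morphometry$per_animal, file.path(out_dir, "morphometry_per_animal.csv"))
      write_table(result$morphometry$per_condition, file.path(out_dir, "morphometry_per_condition.csv"))
    }
    if (!is.null(result$cohort))
      write_table(result$cohort$summary, file.path(out_dir, "cohort_summary.csv"))
    if (!is.null(result$tracks))
      write_table(result$tracks$classified, file.path(out_dir, "track_classes.csv"))
    write_json_summary(result$manifest, file.path(out_dir, "manifest.json"))
  }
  result
}
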