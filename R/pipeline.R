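#' Pipeline configuration
#'
#' Bundles the per-stage options of [run_pipeline()]: the cohort to
#' simulate, gesture detection, sEMG band and per-sample-averaged feature
#' set, POC hysteresis, RANOVA adjustment, distance algorithms and input
#' scale, and the classification protocol.
#'
#' @param cohort A [cohort_config()].
#' @param gesture A [gesture_params()].
#' @param band sEMG analysis band (Hz).
#' @param per_sample Per-sample-average the extensive features.
#' @param hysteresis POC hysteresis (m).
#' @param ranova_adjust Multiple-testing adjustment across features
#'   (`"none"` or a [stats::p.adjust] method).
#' @param distance_algorithms Algorithms to run
#'   (subset of `c("euclidean", "mahalanobis")`).
#' @param distance_normalized Use min-max-normalised features for the
#'   distance maps (default FALSE: raw values).
#' @param fraction Top-distance selection fraction.
#' @param folds Cross-validation folds.
#' @param seed Seed for fold splits and learner randomness (the cohort has
#'   its own seed in `cohort`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            gesture = gesture_params(),
                            band = c(10, 95),
                            per_sample = TRUE,
                            hysteresis = 0.02,
                            ranova_adjust = "none",
                            distance_algorithms = c("euclidean", "mahalanobis"),
                            fraction = 0.15,
                            folds = 5,
                            distance_normalized = FALSE,
                            seed = cohort$seed) {
  validate_cohort_config(cohort)
  abort_if(!all(distance_algorithms %in% c("euclidean", "mahalanobis")),
           "unknown distance algorithm", "endoskill_config_error")
  structure(list(cohort = cohort, gesture = gesture, band = band,
                 per_sample = per_sample, hysteresis = hysteresis,
                 ranova_adjust = ranova_adjust,
                 distance_algorithms = distance_algorithms,
                 distance_normalized = distance_normalized,
                 fraction = fraction, folds = folds, seed = seed),
            class = "pipeline_config")
}

#' Run the full evaluation pipeline
#'
#' Simulate, exclude the corrupted participants, segment, extract
#' features, run the session RANOVA, build the distance maps, select the
#' top-distance features and cross-validate the learner roster — writing
#' every tabular artifact as CSV and every summary as JSON under
#' `out_dir`, with a manifest of seeds and record counts. Reruns with the
#' same configuration are bit-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @return Invisibly, a list with `cohort`, `tables` (raw feature tables),
#'   `ranova`, `boxplots`, `maps`, `selection`, `report`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()

  cohort <- simulate_cohort(config$cohort)
  n_total <- nrow(cohort$truth)
  cohort <- exclude_participants(cohort)
  n_removed <- attr(cohort, "n_removed")

  tables <- build_feature_tables(cohort, params = config$gesture,
                                 band = config$band,
                                 per_sample = config$per_sample,
                                 hysteresis = config$hysteresis)
  ranova <- lapply(tables, ranova_table, adjust = config$ranova_adjust)
  boxplots <- lapply(ranova, neglog10_summary)
  maps <- lapply(tables, function(tb)
    lapply(stats::setNames(nm = config$distance_algorithms),
           function(alg) build_distance_maps(tb, alg,
                                             config$distance_normalized)))
  selection <- lapply(maps, function(m)
    select_top_distance(m[[1]], config$fraction))
  report <- classification_report(tables,
                                  maps = lapply(maps, `[[`, 1),
                                  fraction = config$fraction,
                                  folds = config$folds, seed = config$seed)

  manifest <- list(
    package_version = as.character(utils::packageVersion("endoskill")),
    cohort_seed = config$cohort$seed,
    cv_seed = config$seed,
    n_attempts_simulated = n_total,
    n_attempts_excluded = n_removed,
    n_attempts_analysed = sum(vapply(tables, nrow, integer(1))),
    excluded_participants = nrow(cohort$participants),
    distance_algorithms = config$distance_algorithms,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  result <- list(cohort = cohort, tables = tables, ranova = ranova,
                 boxplots = boxplots, maps = maps, selection = selection,
                 report = report, manifest = manifest)
  if (!is.null(out_dir)) write_artifacts(result, out_dir)
  invisible(result)
}

write_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (ex in names(result$tables)) {
    write_feature_table(result$tables[[ex]],
                        file.path(out_dir, paste0("features_", ex, ".csv")))
    utils::write.csv(result$ranova[[ex]],
                     file.path(out_dir, paste0("ranova_", ex, ".csv")),
                     row.names = FALSE)
    bp <- result$boxplots[[ex]]
    jsonlite::write_json(
      list(ticks = as.list(bp$ticks),
           summaries = bp$summaries),
      file.path(out_dir, paste0("boxplots_", ex, ".json")),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (alg in names(result$maps[[ex]])) {
      m <- result$maps[[ex]][[alg]]
      utils::write.csv(m$full,
                       file.path(out_dir,
                                 paste0("distance_full_", alg, "_", ex, ".csv")))
      utils::write.csv(m$reduced,
                       file.path(out_dir,
                                 paste0("distance_reduced_", alg, "_", ex, ".csv")))
    }
  }
  jsonlite::write_json(result$selection,
                       file.path(out_dir, "selection.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  utils::write.csv(result$report, file.path(out_dir, "classification.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Write / read one recording as plain-text artifacts
#'
#' One directory per recording: per-stream CSV tables (timestamp +
#' channels) and a JSON metadata sidecar, so captures can be inspected or
#' re-imported without the generator.
#'
#' @param recording An `mm_recording`.
#' @param dir Directory to create/read.
#' @return `write_recording()` returns `dir` invisibly; `read_recording()`
#'   an `mm_recording`.
#' @export
write_recording <- function(recording, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(t = recording$semg$t, recording$semg$x,
                              check.names = FALSE),
                   file.path(dir, "semg.csv"), row.names = FALSE)
  utils::write.csv(data.frame(t = recording$orientation$t,
                              recording$orientation$x, check.names = FALSE),
                   file.path(dir, "orientation.csv"), row.names = FALSE)
  sk <- recording$skeleton
  flat <- do.call(cbind, lapply(body_part_names(), function(p) {
    m <- sk$x[, , p]
    colnames(m) <- paste0(p, ".", c("x", "y", "z"))
    m
  }))
  utils::write.csv(data.frame(t = sk$t, flat, check.names = FALSE),
                   file.path(dir, "skeleton.csv"), row.names = FALSE)
  jsonlite::write_json(c(recording$meta,
                         list(truth = recording$truth)),
                       file.path(dir, "meta.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  semg <- utils::read.csv(file.path(dir, "semg.csv"), check.names = FALSE)
  ori <- utils::read.csv(file.path(dir, "orientation.csv"),
                         check.names = FALSE)
  sk <- utils::read.csv(file.path(dir, "skeleton.csv"), check.names = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  x <- array(NA_real_, c(nrow(sk), 3, length(body_part_names())),
             dimnames = list(NULL, c("x", "y", "z"), body_part_names()))
  for (p in body_part_names())
    x[, , p] <- as.matrix(sk[, paste0(p, ".", c("x", "y", "z"))])
  truth <- tibble::as_tibble(meta$truth)
  meta$truth <- NULL
  rec <- list(
    semg = list(t = semg$t, x = as.matrix(semg[, -1])),
    orientation = list(t = ori$t, x = as.matrix(ori[, -1])),
    skeleton = list(t = sk$t, x = x),
    meta = meta,
    truth = truth
  )
  class(rec) <- "mm_recording"
  rec
}
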