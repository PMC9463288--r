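#' Assemble the feature vector of one attempt
#'
#' Computes all 13 sEMG features for each of the 8 channels, the 7
#' motion-analysis parameters for each of the 8 body parts (the 160
#' canonical metrics), plus the 4 orientation features carried as optional
#' extras. Degenerate streams yield flagged missing entries (with a
#' warning) rather than an error.
#'
#' @param segment An `attempt_segment` from [split_attempts()].
#' @param band sEMG analysis band in Hz (default `c(10, 95)`).
#' @param per_sample Per-sample-average the extensive features (`V_SSC`,
#'   `V_ZC`, `V_WFL` and the AUCs); default TRUE.
#' @param abs_range Report `f_Range` unsigned (default FALSE).
#' @param hysteresis POC hysteresis in metres (default 0.02).
#' @return Named numeric vector of length 164: [canonical_metrics()] then
#'   [imu_feature_names()].
#' @export
assemble_features <- function(segment, band = c(10, 95), per_sample = TRUE,
                              abs_range = FALSE, hysteresis = 0.02) {
  stopifnot(inherits(segment, "attempt_segment"))
  rate <- 1 / median(diff(segment$semg$t))

  emg <- matrix(NA_real_, 13, 8,
                dimnames = list(emg_feature_names(), paste0("ch", 1:8)))
  for (ch in 1:8) {
    emg[, ch] <- tryCatch(
      emg_channel_features(segment$semg$x[, ch], rate, band,
                           per_sample = per_sample, abs_range = abs_range),
      endoskill_feature_error = function(e) {
        warning("sEMG channel ", ch, " degenerate: ", conditionMessage(e),
                call. = FALSE)
        rep(NA_real_, 13)
      })
  }
  emg_vec <- as.vector(t(emg))
  names(emg_vec) <- as.vector(t(outer(rownames(emg), colnames(emg),
                                      function(f, c) paste0(f, "@", c))))

  mot <- tryCatch(
    motion_features(segment$skeleton, hysteresis = hysteresis),
    endoskill_feature_error = function(e) {
      warning("skeleton slice degenerate: ", conditionMessage(e), call. = FALSE)
      stats::setNames(rep(NA_real_,
                          length(map_feature_names()) * length(body_part_names())),
                      as.vector(t(outer(map_feature_names(), body_part_names(),
                                        function(f, p) paste0(f, "@", p)))))
    })

  f_max_mean <- mean(emg["f_Max", ], na.rm = TRUE)
  if (!is.finite(f_max_mean)) f_max_mean <- 0
  o <- segment$orientation$x
  imu <- if (nrow(o) >= 2)
    imu_features(o[, "roll"], o[, "pitch"], o[, "yaw"],
                 f_max_mean, per_sample = per_sample)
  else {
    warning("orientation slice degenerate", call. = FALSE)
    stats::setNames(rep(NA_real_, 4), imu_feature_names())
  }

  out <- c(emg_vec, mot, imu)
  out[all_metrics()]
}

#' Build per-exercise feature tables for a cohort
#'
#' Segments every recording, assembles each attempt's feature vector, and
#' returns one table per exercise: rows are attempts annotated with
#' participant, endoscope, exercise, attempt index (1-9), duration and
#' abort flag; columns are the 160 canonical metrics plus the 4 optional
#' orientation metrics.
#'
#' @inheritParams assemble_features
#' @inheritParams segment_cohort
#' @return Named list of tibbles (`exercise1`, `exercise2`, ...), each of
#'   class `feature_table`.
#' @export
build_feature_tables <- function(cohort, params = gesture_params(),
                                 band = c(10, 95), per_sample = TRUE,
                                 abs_range = FALSE, hysteresis = 0.02) {
  segs <- segment_cohort(cohort, params = params)
  rows <- lapply(segs, function(s) {
    v <- assemble_features(s, band = band, per_sample = per_sample,
                           abs_range = abs_range, hysteresis = hysteresis)
    c(list(participant = s$meta$participant,
           endoscope = s$meta$endoscope,
           exercise = s$meta$exercise,
           attempt = s$attempt,
           duration_s = s$duration_s,
           aborted = s$aborted),
      as.list(v))
  })
  tbl <- dplyr::bind_rows(rows)
  out <- lapply(split(tbl, tbl$exercise), function(x) {
    x <- tibble::as_tibble(x)
    class(x) <- c("feature_table", class(x))
    x
  })
  names(out) <- paste0("exercise", names(out))
  out
}

metric_columns <- function(tbl) intersect(all_metrics(), names(tbl))

#' Min-max normalise a feature table
#'
#' Per metric column, over all attempts of all participants within the
#' exercise, maps values to `(x - min) / (max - min)` in [0, 1]. Constant
#' columns map to 0.5. Normalising twice equals normalising once (up to
#' the constant-column rule).
#'
#' @param tbl A `feature_table` (one exercise).
#' @return The table with metric columns normalised.
#' @export
normalize_minmax <- function(tbl) {
  abort_if(nrow(tbl) < 2, "need at least 2 rows", "endoskill_table_error")
  for (m in metric_columns(tbl)) {
    v <- tbl[[m]]
    rng <- range(v, na.rm = TRUE)
    tbl[[m]] <- if (diff(rng) > 0) (v - rng[1]) / diff(rng)
                else rep(0.5, length(v))
  }
  tbl
}

#' Mean-impute missing metric values
#'
#' Replaces missing entries of each metric column by the column mean
#' within the exercise x endoscope group (preserving group means); any
#' value still missing (a group with no finite entries) falls back to the
#' overall column mean, then to 0.
#'
#' @param tbl A `feature_table`.
#' @return The table with no missing metric values.
#' @export
impute_features <- function(tbl) {
  for (m in metric_columns(tbl)) {
    v <- tbl[[m]]
    if (!anyNA(v)) next
    for (g in unique(tbl$endoscope)) {
      i <- tbl$endoscope == g
      gm <- mean(v[i], na.rm = TRUE)
      v[i & is.na(v)] <- gm
    }
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    v[is.na(v)] <- 0
    tbl[[m]] <- v
  }
  tbl
}

#' Write / read a feature table as CSV with a column dictionary
#'
#' The CSV holds one row per attempt; a JSON sidecar records the canonical
#' column layout so the table round-trips.
#'
#' @param tbl A `feature_table`.
#' @param path CSV path; the dictionary is written next to it as
#'   `<path>.dict.json`.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the `feature_table`.
#' @export
write_feature_table <- function(tbl, path) {
  utils::write.csv(tbl, path, row.names = FALSE)
  dict <- list(metadata = setdiff(names(tbl), metric_columns(tbl)),
               metrics = metric_columns(tbl),
               canonical = intersect(names(tbl), canonical_metrics()))
  jsonlite::write_json(dict, paste0(path, ".dict.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  x <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  class(x) <- c("feature_table", class(x))
  x
}
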