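#' Distance-based feature selection
#'
#' Retains a canonical metric if any cell in its row of the full distance
#' map reaches the upper `fraction` of the map's distance values, i.e. is
#' at least `(1 - fraction)` times the maximum cell. With `fraction = 1`
#' every feature is retained (threshold zero under positive distances);
#' an empty selection falls back, with a warning, to all features.
#'
#' @param map A `distance_map` from [build_distance_maps()].
#' @param fraction Upper distance fraction (default 0.15).
#' @return Character vector of retained canonical metric names.
#' @export
select_top_distance <- function(map, fraction = 0.15) {
  stopifnot(inherits(map, "distance_map"))
  abort_if(fraction <= 0 || fraction > 1, "fraction must be in (0, 1]",
           "endoskill_classify_error")
  m <- map$full
  mx <- suppressWarnings(max(m, na.rm = TRUE))
  keep <- if (is.finite(mx)) {
    thr <- (1 - fraction) * mx
    rownames(m)[apply(m, 1, function(r) any(r >= thr, na.rm = TRUE))]
  } else character(0)
  if (!length(keep)) {
    warning("empty top-distance selection; falling back to all features",
            call. = FALSE)
    keep <- rownames(m)
  }
  keep
}

# stratified fold assignment, identical across learners for a given seed
stratified_folds <- function(y, folds, seed) {
  assign <- integer(length(y))
  withr::with_seed(seed, {
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

# participant-grouped folds: all attempts of a participant share a fold,
# participants stratified by class
grouped_folds <- function(y, participant, folds, seed) {
  assign <- integer(length(y))
  withr::with_seed(seed, {
    for (lv in levels(y)) {
      parts <- sample(unique(participant[y == lv]))
      pf <- rep_len(seq_len(folds), length(parts))
      for (i in seq_along(parts))
        assign[participant == parts[i]] <- pf[i]
    }
  })
  assign
}

#' Cross-validated endoscope classification accuracy
#'
#' Stratified k-fold cross-validation of one learner predicting the
#' endoscope mode (2D vs 3D) from normalised features. The fold split is
#' fixed by the seed and is identical for every learner trained on the
#' same table with the same seed; learners with internal randomness are
#' seeded per fold, so the same seed and table give identical accuracies.
#'
#' @param tbl A normalised `feature_table` (one exercise) with both
#'   classes.
#' @param spec A [learner_spec()] (or a family name).
#' @param metrics Feature columns to use; default all canonical metrics
#'   present.
#' @param folds Number of folds (default 5).
#' @param seed Integer seed controlling the fold split and any learner
#'   randomness.
#' @param group_by_participant Keep all attempts of a participant in one
#'   fold (default FALSE, the row-wise protocol). The grouped split is the
#'   statistically safer choice whenever features carry a participant
#'   signature, since the endoscope label is a participant-level property.
#' @return Accuracy in percent (mean over folds).
#' @export
train_eval <- function(tbl, spec, metrics = NULL, folds = 5, seed = 1,
                       group_by_participant = FALSE) {
  if (is.character(spec)) spec <- learner_spec(spec)
  y <- factor(tbl$endoscope, levels = c("2D", "3D"))
  abort_if(nlevels(droplevels(y)) < 2,
           "both endoscope classes must be present",
           "endoskill_classify_error")
  abort_if(any(table(y) < folds),
           "need at least `folds` rows per class", "endoskill_classify_error")
  metrics <- metrics %||% intersect(canonical_metrics(), names(tbl))
  X <- as.matrix(tbl[, metrics, drop = FALSE])
  abort_if(anyNA(X), "features must be complete (impute first)",
           "endoskill_classify_error")

  fold_of <- if (group_by_participant)
    grouped_folds(y, tbl$participant, folds, seed)
  else stratified_folds(y, folds, seed)
  acc <- vapply(seq_len(folds), function(f) {
    tr <- fold_of != f
    model <- withr::with_seed(seed + 1000L * f,
                              fit_learner(spec, X[tr, , drop = FALSE], y[tr]))
    pred <- withr::with_seed(seed + 1000L * f + 1L,
                             model(X[!tr, , drop = FALSE]))
    mean(pred == y[!tr])
  }, numeric(1))
  100 * mean(acc)
}

#' Classification report over exercises, learners and feature sets
#'
#' Evaluates the full learner roster per exercise with all features and
#' with the top-distance subset, mirroring the alternating all/15% layout
#' of endoscope-classification accuracy tables, and flags the best
#' accuracy per exercise x feature-set column.
#'
#' @param tables Named list of `feature_table`s (one per exercise), raw
#'   scale; they are min-max normalised internally.
#' @param maps Optional named list of `distance_map`s aligned with
#'   `tables` (built from the raw tables when omitted).
#' @param roster Named list of [learner_spec()]s (default the full
#'   roster).
#' @param fraction Top-distance selection fraction (default 0.15).
#' @param folds,seed Cross-validation controls.
#' @return A `classification_report` tibble: `exercise`, `learner`,
#'   `feature_set` (`all`/`top15`), `n_features`, `accuracy` (percent),
#'   `best` (flag, per exercise x feature-set).
#' @export
classification_report <- function(tables, maps = NULL,
                                  roster = learner_roster(),
                                  fraction = 0.15, folds = 5, seed = 1) {
  if (is.null(maps))
    maps <- lapply(tables, build_distance_maps, algorithm = "euclidean")
  rows <- list()
  for (ex in names(tables)) {
    tbl <- impute_features(tables[[ex]])
    norm <- normalize_minmax(tbl)
    sel <- select_top_distance(maps[[ex]], fraction)
    sets <- list(all = intersect(canonical_metrics(), names(tbl)),
                 top15 = sel)
    for (ln in names(roster)) {
      for (fs in names(sets)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          exercise = ex, learner = ln, feature_set = fs,
          n_features = length(sets[[fs]]),
          accuracy = train_eval(norm, roster[[ln]], metrics = sets[[fs]],
                                folds = folds, seed = seed))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$best <- FALSE
  for (ex in unique(out$exercise)) {
    for (fs in unique(out$feature_set)) {
      i <- which(out$exercise == ex & out$feature_set == fs)
      out$best[i[which.max(out$accuracy[i])]] <- TRUE
    }
  }
  class(out) <- c("classification_report", class(out))
  out
}
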