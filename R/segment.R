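#' Sync-gesture detection parameters
#'
#' The attempt boundaries are marked by deliberate raises of the right
#' hand: its Y position exceeds a running-median baseline by at least
#' `height_threshold` for at least `min_hold_s`. Detection reports the
#' midpoint of each supra-threshold excursion.
#'
#' @param height_threshold Metres above the running baseline (default 0.25).
#' @param min_hold_s Minimum excursion duration in seconds (default 1).
#' @param baseline_window_s Running-median window in seconds (default 15).
#' @return A `gesture_params` list.
#' @export
gesture_params <- function(height_threshold = 0.25,
                           min_hold_s = 1,
                           baseline_window_s = 15) {
  abort_if(height_threshold <= 0 || min_hold_s <= 0 || baseline_window_s <= 0,
           "all gesture parameters must be positive", "endoskill_config_error")
  structure(list(height_threshold = height_threshold,
                 min_hold_s = min_hold_s,
                 baseline_window_s = baseline_window_s),
            class = "gesture_params")
}

#' Detect sync gestures in a Y-position series
#'
#' Scans a timestamped vertical-position series for contiguous excursions
#' above a running-median baseline, keeping those that exceed the height
#' threshold for at least the minimum hold time, and returns one timestamp
#' per excursion (the interval midpoint), strictly increasing.
#'
#' @param time Timestamps in seconds (strictly increasing, regular).
#' @param y Y positions (metres), same length as `time`.
#' @param params A [gesture_params()].
#' @return Numeric vector of gesture timestamps (possibly empty).
#' @export
detect_sync_gestures <- function(time, y, params = gesture_params()) {
  stopifnot(length(time) == length(y), length(time) >= 2)
  dt <- median(diff(time))
  k <- max(3L, round(params$baseline_window_s / dt))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (length(y) %% 2L == 1L) length(y) else length(y) - 1L)
  baseline <- runmed(y, k, endrule = "median")
  above <- (y - baseline) >= params$height_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values &
                  (time[ends] - time[starts]) >= params$min_hold_s)
  if (!length(keep)) return(numeric(0))
  (time[starts[keep]] + time[ends[keep]]) / 2
}

#' Split a recording into attempt segments
#'
#' Pairs consecutive gesture timestamps ((1,2), (3,4), ...) and extracts,
#' for every stream, the samples strictly between each pair, on the shared
#' clock and at each stream's native rate. An attempt spanning the 90 s
#' limit is truncated at 90 s and flagged aborted (as is any attempt whose
#' span comes within detection jitter, 0.1 s, of the limit).
#'
#' @param recording An `mm_recording`.
#' @param gestures Strictly increasing gesture timestamps; even count
#'   (>= 2) required. Defaults to detection on the right hand's Y series.
#' @param params Gesture parameters used when `gestures` is missing.
#' @param abort_limit_s Abort rule limit in seconds (default 90).
#' @return A list of `attempt_segment` objects, each with elements `semg`,
#'   `orientation`, `skeleton` (stream slices), `t_start`, `t_end`,
#'   `attempt_index` (within the recording), `duration_s`, `aborted`, `meta`.
#' @export
split_attempts <- function(recording, gestures = NULL,
                           params = gesture_params(), abort_limit_s = 90) {
  stopifnot(inherits(recording, "mm_recording"))
  if (is.null(gestures)) {
    sk <- recording$skeleton
    gestures <- detect_sync_gestures(sk$t, sk$x[, "y", "hand_r"], params)
  }
  label <- paste0(recording$meta$participant, "/ex", recording$meta$exercise,
                  "/file", recording$meta$file)
  abort_if(length(gestures) < 2,
           paste0("fewer than 2 sync gestures found in recording ", label),
           "endoskill_segmentation_error")
  abort_if(length(gestures) %% 2L != 0L,
           paste0("odd number of sync gestures (unpaired raise) in recording ",
                  label),
           "endoskill_segmentation_error")
  abort_if(is.unsorted(gestures, strictly = TRUE),
           "gesture timestamps must be strictly increasing",
           "endoskill_segmentation_error")

  n_seg <- length(gestures) %/% 2L
  lapply(seq_len(n_seg), function(a) {
    t0 <- gestures[2L * a - 1L]
    t1 <- gestures[2L * a]
    aborted <- (t1 - t0) >= (abort_limit_s - 0.1)
    if (t1 - t0 > abort_limit_s) t1 <- t0 + abort_limit_s
    seg <- list(
      semg = slice_stream(recording$semg, t0, t1),
      orientation = slice_stream(recording$orientation, t0, t1),
      skeleton = slice_skeleton(recording$skeleton, t0, t1),
      t_start = t0, t_end = t1,
      attempt_index = a,
      duration_s = t1 - t0,
      aborted = aborted,
      meta = recording$meta
    )
    class(seg) <- "attempt_segment"
    seg
  })
}

slice_stream <- function(stream, t0, t1) {
  i <- which(stream$t > t0 & stream$t < t1)
  list(t = stream$t[i], x = stream$x[i, , drop = FALSE])
}

slice_skeleton <- function(stream, t0, t1) {
  i <- which(stream$t > t0 & stream$t < t1)
  list(t = stream$t[i], x = stream$x[i, , , drop = FALSE])
}

#' Segment a whole cohort
#'
#' Applies [split_attempts()] to every recording and returns a flat list of
#' segments with global attempt indices (1-9) attached: three recordings of
#' three attempts per participant and exercise yield nine data sequences.
#'
#' @inheritParams split_attempts
#' @param cohort An `mm_cohort`.
#' @param boundaries Optional manual-boundary override: a data frame with
#'   columns `participant`, `exercise`, `file`, `t_start`, `t_end` (one row
#'   per attempt, in order), used instead of gesture detection for the
#'   recordings it covers.
#' @return List of `attempt_segment`s; each carries `attempt` (global 1-9
#'   index) in addition to its within-recording `attempt_index`.
#' @export
segment_cohort <- function(cohort, params = gesture_params(),
                           boundaries = NULL, abort_limit_s = 90) {
  stopifnot(inherits(cohort, "mm_cohort"))
  napf <- cohort$config$attempts_per_file
  out <- list()
  for (rec in cohort$recordings) {
    g <- NULL
    if (!is.null(boundaries)) {
      b <- boundaries[boundaries$participant == rec$meta$participant &
                        boundaries$exercise == rec$meta$exercise &
                        boundaries$file == rec$meta$file, , drop = FALSE]
      if (nrow(b) > 0)
        g <- as.vector(t(as.matrix(b[, c("t_start", "t_end")])))
    }
    segs <- split_attempts(rec, gestures = g, params = params,
                           abort_limit_s = abort_limit_s)
    for (s in segs) {
      s$attempt <- (rec$meta$file - 1L) * napf + s$attempt_index
      out[[length(out) + 1L]] <- s
    }
  }
  out
}
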