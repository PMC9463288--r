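#' Distance travelled and average speed of a body part
#'
#' `Trace` is the sum of Euclidean step lengths of the 3-D track;
#' `Velocity` is `Trace` divided by the track's time span.
#'
#' @param positions T x 3 matrix of coordinates (metres).
#' @param timestamps Timestamps in seconds, length T (>= 2), increasing.
#' @return Named numeric: `Trace`, `Velocity`.
#' @export
trace_and_velocity <- function(positions, timestamps) {
  stopifnot(nrow(positions) == length(timestamps))
  abort_if(nrow(positions) < 2, "need at least 2 samples",
           "endoskill_feature_error")
  span <- timestamps[length(timestamps)] - timestamps[1]
  abort_if(span <= 0, "zero track duration", "endoskill_feature_error")
  trace <- sum(sqrt(rowSums(diff(positions)^2)))
  c(Trace = trace, Velocity = trace / span)
}

#' Vertical direction reversals (POC)
#'
#' Counts reversals of vertical (Y) movement direction, debounced by a
#' hysteresis: a reversal is counted only once the track has moved at
#' least `hysteresis` metres in the new vertical direction, so jitter
#' below the hysteresis on a flat track counts nothing.
#'
#' @param y Vertical positions (metres), >= 3 samples.
#' @param hysteresis Debounce displacement in metres (default 0.02).
#' @return Integer count of reversals.
#' @export
poc <- function(y, hysteresis = 0.02) {
  abort_if(length(y) < 3, "need at least 3 samples", "endoskill_feature_error")
  direction <- 0L   # unknown until the first move beyond hysteresis
  hi <- y[1]; lo <- y[1]
  extreme <- y[1]   # running extreme in the current direction
  count <- 0L
  for (v in y[-1]) {
    if (direction == 0L) {
      if (v > hi) hi <- v
      if (v < lo) lo <- v
      if (v - lo >= hysteresis) { direction <- 1L; extreme <- v }
      else if (hi - v >= hysteresis) { direction <- -1L; extreme <- v }
    } else if (direction == 1L) {
      if (v > extreme) extreme <- v
      else if (extreme - v >= hysteresis) {
        count <- count + 1L; direction <- -1L; extreme <- v
      }
    } else {
      if (v < extreme) extreme <- v
      else if (v - extreme >= hysteresis) {
        count <- count + 1L; direction <- 1L; extreme <- v
      }
    }
  }
  count
}

#' Segment angles against the body axis
#'
#' Per frame, the angle (degrees, in [0, 180]) between the limb-segment
#' vector (part position minus parent position) and the body axis, then
#' mean, max, min and range over frames. Frames with a degenerate
#' (zero-length) segment vector or axis are skipped; if all frames are
#' degenerate the features are `NA`.
#'
#' @param positions T x 3 part coordinates.
#' @param parent_positions T x 3 parent-joint coordinates (time-aligned).
#' @param axis T x 3 body-axis vectors per frame (or a single length-3
#'   vector recycled to all frames).
#' @return Named numeric: `Angle_Mean`, `Angle_Max`, `Angle_Min`,
#'   `Angle_Range`.
#' @export
segment_angles <- function(positions, parent_positions, axis) {
  stopifnot(nrow(positions) == nrow(parent_positions))
  if (is.null(dim(axis)))
    axis <- matrix(axis, nrow(positions), 3, byrow = TRUE)
  seg <- positions - parent_positions
  ns <- sqrt(rowSums(seg^2))
  na <- sqrt(rowSums(axis^2))
  ok <- ns > 0 & na > 0
  if (!any(ok))
    return(c(Angle_Mean = NA_real_, Angle_Max = NA_real_,
             Angle_Min = NA_real_, Angle_Range = NA_real_))
  cosang <- rowSums(seg[ok, , drop = FALSE] * axis[ok, , drop = FALSE]) /
    (ns[ok] * na[ok])
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  c(Angle_Mean = mean(ang), Angle_Max = max(ang),
    Angle_Min = min(ang), Angle_Range = max(ang) - min(ang))
}

# parent joint of each body part; spine_shoulders uses a synthetic
# shoulder-line vector, handled separately
motion_parent <- c(head = "spine_shoulders",
                   elbow_l = "spine_shoulders", wrist_l = "elbow_l",
                   hand_l = "wrist_l",
                   elbow_r = "spine_shoulders", wrist_r = "elbow_r",
                   hand_r = "wrist_r")

#' All 7 motion-analysis parameters for every body part
#'
#' Computes POC, Trace, Velocity and the four angle summaries for each of
#' the 8 tracked body parts of a skeleton slice. The body axis is the
#' spine-to-head direction per frame (global vertical when degenerate).
#' Limb segments run child-to-parent (hand to wrist, wrist to elbow, elbow
#' to shoulder centre, head to shoulder centre); the shoulder-centre part
#' itself uses a horizontal shoulder-line vector.
#'
#' @param skeleton A skeleton slice: list with `t` (timestamps) and `x`
#'   (T x 3 x 8 array, parts in [body_part_names()] order).
#' @param hysteresis POC hysteresis in metres (default 0.02).
#' @return Named numeric vector of 56 metrics `map@part`.
#' @export
motion_features <- function(skeleton, hysteresis = 0.02) {
  x <- skeleton$x
  ts <- skeleton$t
  abort_if(dim(x)[1] < 3, "skeleton slice too short", "endoskill_feature_error")
  axis <- x[, , "head"] - x[, , "spine_shoulders"]
  deg <- sqrt(rowSums(axis^2)) == 0
  if (any(deg)) axis[deg, ] <- matrix(c(0, 1, 0), sum(deg), 3, byrow = TRUE)

  out <- numeric(0)
  for (part in body_part_names()) {
    pos <- x[, , part]
    tv <- trace_and_velocity(pos, ts)
    pc <- poc(pos[, "y"], hysteresis)
    if (part == "spine_shoulders") {
      # shoulder line: horizontal unit vector orthogonal to the body axis
      sl <- cbind(axis[, 3], 0, -axis[, 1])
      flat <- sqrt(rowSums(sl^2)) == 0
      if (any(flat)) sl[flat, ] <- matrix(c(1, 0, 0), sum(flat), 3, byrow = TRUE)
      ang <- segment_angles(sl, matrix(0, nrow(sl), 3), axis)
    } else {
      ang <- segment_angles(pos, x[, , motion_parent[[part]]], axis)
    }
    v <- c(POC = pc, tv, ang)
    names(v) <- paste0(c("POC", "Trace", "Velocity", "Angle_Mean",
                         "Angle_Max", "Angle_Min", "Angle_Range"), "@", part)
    out <- c(out, v)
  }
  out
}
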