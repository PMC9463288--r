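#' Cohort configuration
#'
#' Defines the study conditions emulated by [simulate_cohort()]: 15
#' volunteers split 7 (2D endoscope) / 8 (3D endoscope), three exercises,
#' nine attempts each recorded continuously in files of three attempts, a
#' 90 s abort rule per attempt, and the two injectable ground-truth effects
#' the downstream analysis is designed to detect: a multiplicative sEMG
#' amplitude factor for the 2D group and a per-attempt fractional decrease
#' of right hand/wrist speed (a learning trend).
#'
#' @param n_participants Number of volunteers (default 15).
#' @param n_excluded Number of participants whose data the generator marks
#'   as corrupted, to be dropped with [exclude_participants()] (default 3).
#' @param exercises Number of exercises (default 3).
#' @param attempts_per_exercise Attempts per exercise (default 9).
#' @param attempts_per_file Attempts recorded continuously per file
#'   (default 3).
#' @param group_split Named integer vector of participants per endoscope
#'   mode; must sum to `n_participants` (default `c("2D" = 7, "3D" = 8)`).
#' @param emg_rate,imu_rate,skeleton_rate Sampling rates in samples/s for
#'   the sEMG armband (200), its orientation sensor (50) and the skeleton
#'   tracker (30).
#' @param attempt_duration_s List with `meanlog`, `sdlog` (log-normal
#'   parameters of the attempt duration in seconds; the default has its
#'   mode at 45 s) and `cap` (hard abort limit, 90 s).
#' @param effect_amplitude Multiplicative sEMG amplitude factor applied to
#'   the 2D group (>= 1; 1 = null). Default 1.5, the documented strong
#'   effect size.
#' @param effect_trend Fractional decrease of right hand/wrist mean speed
#'   per attempt (0 = null). Default 0.05.
#' @param noise_sd Scale factor on all stream noise levels (default 1).
#' @param seed Integer seed; every stream is reproducible under it.
#' @return A `cohort_config` object (a validated list).
#' @export
cohort_config <- function(n_participants = 15L,
                          n_excluded = 3L,
                          exercises = 3L,
                          attempts_per_exercise = 9L,
                          attempts_per_file = 3L,
                          group_split = c("2D" = 7L, "3D" = 8L),
                          emg_rate = 200,
                          imu_rate = 50,
                          skeleton_rate = 30,
                          attempt_duration_s = list(meanlog = log(45) + 0.09,
                                                    sdlog = 0.3,
                                                    cap = 90),
                          effect_amplitude = 1.5,
                          effect_trend = 0.05,
                          noise_sd = 1,
                          seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_excluded = as.integer(n_excluded),
    exercises = as.integer(exercises),
    attempts_per_exercise = as.integer(attempts_per_exercise),
    attempts_per_file = as.integer(attempts_per_file),
    group_split = group_split,
    emg_rate = emg_rate,
    imu_rate = imu_rate,
    skeleton_rate = skeleton_rate,
    attempt_duration_s = attempt_duration_s,
    effect_amplitude = effect_amplitude,
    effect_trend = effect_trend,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  abort_if(cfg$n_participants < 1, "need at least one participant",
           "endoskill_config_error")
  abort_if(any(c(cfg$emg_rate, cfg$imu_rate, cfg$skeleton_rate) <= 0),
           "all sampling rates must be positive", "endoskill_config_error")
  abort_if(!identical(sort(names(cfg$group_split)), c("2D", "3D")),
           "group_split must be named with modes '2D' and '3D'",
           "endoskill_config_error")
  abort_if(sum(cfg$group_split) != cfg$n_participants,
           "group_split must sum to n_participants", "endoskill_config_error")
  abort_if(cfg$n_excluded < 0 || cfg$n_excluded > cfg$n_participants,
           "n_excluded out of range", "endoskill_config_error")
  abort_if(cfg$attempts_per_exercise %% cfg$attempts_per_file != 0,
           "attempts_per_exercise must be a multiple of attempts_per_file",
           "endoskill_config_error")
  abort_if(cfg$effect_amplitude < 1, "effect_amplitude must be >= 1",
           "endoskill_config_error")
  abort_if(cfg$effect_trend < 0 || cfg$effect_trend >= 1,
           "effect_trend must be in [0, 1)", "endoskill_config_error")
  d <- cfg$attempt_duration_s
  abort_if(!all(c("meanlog", "sdlog", "cap") %in% names(d)) ||
             d$cap <= 0 || d$cap > 90,
           "attempt_duration_s needs meanlog, sdlog and a cap in (0, 90]",
           "endoskill_config_error")
  invisible(cfg)
}

# ---- fixed physical design constants of the generator ----------------------
# sEMG (raw armband units): strongly bursty activity so that the attempt
# maximum sits far above the RMS (peak factor ~ 18), matching the intended
# ranking V_Max/V_Min/V_Range above V_Var in raw units.
SYN <- list(
  emg_band = c(20, 95),        # Hz, coloured-noise energy concentration
  emg_peak_hz = 45,            # spectral envelope peak
  emg_rest_sd = 1.5,           # raw units, outside attempts
  emg_tonic_sd = 3,            # raw units, tonic activation during attempts
  burst_rate = 0.15,           # bursts per second of attempt content
  burst_len_s = 0.40,          # mean burst length
  burst_amp = 26,              # envelope peak, raw units
  participant_amp_sdlog = 0.05,# between-subject amplitude spread (MVC-normalised)
  chan_gain = c(1.15, 1.0, 0.85, 0.9, 1.1, 0.95, 1.05, 0.8),
  ori_base = c(roll = 1.2, pitch = 0.9, yaw = 1.5),  # radians
  gesture_raise = 0.45,        # m, sync-gesture Y elevation
  gesture_len = 1.6,           # s, total raise duration (ramp-hold-ramp)
  gesture_ramp = 0.25,         # s
  lead_in = 3.0,               # s before the first gesture
  gap = 4.0,                   # s between attempt blocks
  speed_targets = c(head = 0.015, spine_shoulders = 0.010,
                    elbow_l = 0.07, wrist_l = 0.13, hand_l = 0.16,
                    elbow_r = 0.09, wrist_r = 0.22, hand_r = 0.28),
  speed_noise_sd = 0.015,      # lognormal sd of per-attempt speed wobble
  jitter_sd = 0.002,           # m, tracker jitter (OU)
  jitter_tau = 0.3,            # s
  base_pos = rbind(head            = c(0.00, 1.72, 0.05),
                   spine_shoulders = c(0.00, 1.45, 0.00),
                   elbow_l         = c(-0.22, 1.18, 0.08),
                   wrist_l         = c(-0.27, 1.32, 0.28),
                   hand_l          = c(-0.29, 1.40, 0.40),
                   elbow_r         = c(0.22, 1.18, 0.08),
                   wrist_r         = c(0.27, 1.32, 0.28),
                   hand_r          = c(0.29, 1.40, 0.40))
)

#' Simulate a synthetic training cohort
#'
#' Generates one continuous multimodal recording per participant, exercise
#' and file (three attempts per file). Each attempt is delimited by a
#' sync gesture: the right hand's Y position is raised 0.45 m above its
#' baseline for more than one second at the attempt's start and end, so a
#' file carries exactly `2 * attempts_per_file` raises. sEMG channels are
#' band-limited (20-95 Hz) coloured noise under a burst envelope; the 2D
#' group's channels are scaled by `effect_amplitude`. Right hand and wrist
#' mean speeds decrease by `effect_trend` per attempt. Attempt durations
#' are log-normal with mode 45 s, hard-capped at 90 s with an abort flag.
#'
#' @param config A [cohort_config()].
#' @return An object of class `mm_cohort`: a list with `recordings` (list of
#'   `mm_recording`), `config`, `participants` (tibble with id, endoscope),
#'   `excluded_ids` (the `n_excluded` participants marked corrupted) and
#'   `truth` (tibble of ground-truth attempt boundaries, one row per
#'   attempt, with gesture-midpoint `t_start`/`t_end` and abort flags).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  ids <- sprintf("P%02d", seq_len(cfg$n_participants))
  modes <- sample(rep(names(cfg$group_split), cfg$group_split))
  excluded <- sample(ids, cfg$n_excluded)
  n_files <- cfg$attempts_per_exercise %/% cfg$attempts_per_file

  recordings <- list()
  truth <- list()
  for (p in seq_along(ids)) {
    pctx <- list(
      id = ids[p],
      endoscope = modes[p],
      amp = rlnorm(1, 0, SYN$participant_amp_sdlog) *
        if (modes[p] == "2D") cfg$effect_amplitude else 1,
      ori_base = SYN$ori_base * (1 + rnorm(3, 0, 0.08))
    )
    for (ex in seq_len(cfg$exercises)) {
      for (f in seq_len(n_files)) {
        rec <- simulate_recording(cfg, pctx, ex, f)
        recordings[[length(recordings) + 1L]] <- rec
        tt <- rec$truth
        tt$participant <- ids[p]
        tt$endoscope <- modes[p]
        tt$exercise <- ex
        tt$file <- f
        tt$attempt <- (f - 1L) * cfg$attempts_per_file + tt$attempt_in_file
        truth[[length(truth) + 1L]] <- tt
      }
    }
  }
  out <- list(
    recordings = recordings,
    config = cfg,
    participants = tibble::tibble(participant = ids, endoscope = modes),
    excluded_ids = excluded,
    truth = dplyr::bind_rows(truth)
  )
  class(out) <- "mm_cohort"
  out
}

#' @export
print.mm_cohort <- function(x, ...) {
  cat("<mm_cohort> ", length(x$recordings), " recordings, ",
      nrow(x$participants), " participants (",
      sum(x$participants$endoscope == "2D"), "x2D / ",
      sum(x$participants$endoscope == "3D"), "x3D), ",
      nrow(x$truth), " attempts\n", sep = "")
  invisible(x)
}

# One continuous capture of `attempts_per_file` attempts for one
# participant/exercise/file. Returns an mm_recording.
simulate_recording <- function(cfg, pctx, exercise, file_idx) {
  napf <- cfg$attempts_per_file
  glen <- SYN$gesture_len
  dur <- cfg$attempt_duration_s
  # attempt duration, measured gesture-midpoint to gesture-midpoint
  D <- rlnorm(napf, dur$meanlog, dur$sdlog)
  aborted <- D >= dur$cap
  D[aborted] <- dur$cap

  # timeline: lead | [gesture content gesture] gap | ... (last gap dropped)
  g_start <- numeric(napf); g_end <- numeric(napf)
  t_cursor <- SYN$lead_in
  for (a in seq_len(napf)) {
    g_start[a] <- t_cursor                      # opening raise begins
    g_end[a] <- g_start[a] + glen / 2 + D[a] + glen / 2  # closing raise ends
    t_cursor <- g_end[a] + SYN$gap
  }
  total <- t_cursor - SYN$gap + SYN$lead_in
  mid_start <- g_start + glen / 2
  mid_end <- mid_start + D
  content_start <- g_start + glen
  content_end <- g_end - glen

  semg <- sim_semg(cfg, pctx, total, content_start, content_end)
  orientation <- sim_orientation(cfg, pctx, total)
  skeleton <- sim_skeleton(cfg, pctx, total, content_start, content_end,
                           g_start, attempts_before = (file_idx - 1L) * napf)

  rec <- list(
    semg = semg,
    orientation = orientation,
    skeleton = skeleton,
    meta = list(participant = pctx$id, endoscope = pctx$endoscope,
                exercise = exercise, file = file_idx),
    truth = tibble::tibble(attempt_in_file = seq_len(napf),
                           t_start = mid_start, t_end = mid_end,
                           duration_s = D, aborted = aborted)
  )
  class(rec) <- "mm_recording"
  rec
}

#' @export
print.mm_recording <- function(x, ...) {
  cat("<mm_recording> ", x$meta$participant, " ", x$meta$endoscope,
      " exercise ", x$meta$exercise, " file ", x$meta$file, ": ",
      nrow(x$semg$x), " sEMG samples x8, ",
      nrow(x$orientation$x), " orientation samples, ",
      dim(x$skeleton$x)[1], " skeleton frames\n", sep = "")
  invisible(x)
}

# 8-channel coloured-noise sEMG under a burst envelope
sim_semg <- function(cfg, pctx, total, content_start, content_end) {
  rate <- cfg$emg_rate
  t <- seq(0, total, by = 1 / rate)
  n <- length(t)
  # band-limited unit-variance carrier, FFT-filtered at a 5-smooth length
  npad <- n
  while (smooth_length(npad) < n) npad <- npad + npad %/% 8 + 1
  npad <- smooth_length(npad)
  if (npad < n) npad <- n  # fallback; fft still works, just slower
  white <- matrix(rnorm(npad * 8), npad, 8)
  f2 <- (seq_len(npad) - 1) / npad * rate
  f2 <- pmin(f2, rate - f2)                     # two-sided -> folded freq
  H <- spectral_envelope(f2)
  xw <- Re(mvfft(mvfft(white) * H, inverse = TRUE)) / npad
  xw <- xw[seq_len(n), , drop = FALSE]
  xw <- sweep(xw, 2, apply(xw, 2, sd), "/")

  env <- rep(SYN$emg_rest_sd, n)
  for (a in seq_along(content_start)) {
    idx <- which(t >= content_start[a] & t <= content_end[a])
    if (!length(idx)) next
    env[idx] <- SYN$emg_tonic_sd
    len <- content_end[a] - content_start[a]
    # tool-action bursts: one per 1/burst_rate seconds of content, with
    # jittered placement, length and amplitude (the near-deterministic
    # count keeps per-attempt RMS tight, so amplitude effects are
    # recoverable at cohort size)
    nb <- max(1L, round(SYN$burst_rate * len))
    if (len > SYN$burst_len_s) {
      b0 <- content_start[a] +
        (seq_len(nb) - runif(nb, 0.1, 0.9)) / nb * (len - SYN$burst_len_s)
      bl <- SYN$burst_len_s * runif(nb, 0.85, 1.15)
      ba <- SYN$burst_amp * runif(nb, 0.9, 1.1)
      for (b in seq_len(nb)) {
        bi <- which(t >= b0[b] & t <= b0[b] + bl[b])
        if (length(bi))
          env[bi] <- env[bi] + ba[b] * sin(pi * (t[bi] - b0[b]) / bl[b])^2
      }
    }
  }
  gains <- SYN$chan_gain * pctx$amp * cfg$noise_sd
  x <- xw * env
  x <- sweep(x, 2, gains, "*")
  colnames(x) <- paste0("ch", 1:8)
  list(t = t, x = x)
}

# raised-cosine spectral envelope concentrated on the 20-95 Hz band
spectral_envelope <- function(f) {
  lo <- SYN$emg_band[1]; hi <- SYN$emg_band[2]; pk <- SYN$emg_peak_hz
  H <- numeric(length(f))
  inb <- f >= lo & f <= hi
  up <- inb & f <= pk
  dn <- inb & f > pk
  H[up] <- 0.5 - 0.5 * cos(pi * (f[up] - lo) / (pk - lo))
  H[dn] <- 0.5 + 0.5 * cos(pi * (f[dn] - pk) / (hi - pk))
  H
}

# roll/pitch/yaw orientation streams (radians)
sim_orientation <- function(cfg, pctx, total) {
  rate <- cfg$imu_rate
  t <- seq(0, total, by = 1 / rate)
  n <- length(t)
  x <- vapply(1:3, function(k) {
    base <- pctx$ori_base[k]
    base +
      0.25 * sin(2 * pi * runif(1, 0.15, 0.3) * t + runif(1, 0, 2 * pi)) +
      0.15 * sin(2 * pi * runif(1, 0.35, 0.6) * t + runif(1, 0, 2 * pi)) +
      ou_noise(n, 1 / rate, 0.05 * cfg$noise_sd, 1)
  }, numeric(n))
  colnames(x) <- c("roll", "pitch", "yaw")
  list(t = t, x = x)
}

# 8-part skeleton stream with per-attempt speed control and sync gestures
sim_skeleton <- function(cfg, pctx, total, content_start, content_end,
                         g_start, attempts_before) {
  rate <- cfg$skeleton_rate
  t <- seq(0, total, by = 1 / rate)
  n <- length(t)
  napf <- length(content_start)
  parts <- body_part_names()
  x <- array(NA_real_, c(n, 3, length(parts)),
             dimnames = list(NULL, c("x", "y", "z"), parts))

  # smooth velocity-scale profile: full speed inside attempt content,
  # suppressed during gestures/gaps so raises stay clean excursions
  for (p in seq_along(parts)) {
    part <- parts[p]
    raw <- vapply(1:3, function(axis) {
      m <- numeric(n)
      for (h in 1:3) {
        fr <- runif(1, 0.3, 1.2)
        m <- m + runif(1, 0.5, 1) / fr * sin(2 * pi * fr * t + runif(1, 0, 2 * pi))
      }
      m
    }, numeric(n))
    steps <- diff(raw)                          # n-1 x 3
    speed_raw <- sqrt(rowSums(steps^2)) * rate  # instantaneous m/s

    # per-attempt target speed with the learning trend on the right arm
    base_speed <- SYN$speed_targets[[part]]
    s_att <- vapply(seq_len(napf), function(a) {
      k <- attempts_before + a                  # global attempt index
      trend <- if (part %in% c("hand_r", "wrist_r"))
        (1 - cfg$effect_trend)^(k - 1) else 1
      target <- base_speed * trend * rlnorm(1, 0, SYN$speed_noise_sd)
      idx <- which(t[-1] >= content_start[a] & t[-1] <= content_end[a])
      mean_raw <- mean(speed_raw[idx])
      if (is.finite(mean_raw) && mean_raw > 0) target / mean_raw else 0
    }, numeric(1))
    anchor_t <- c(0)
    anchor_s <- c(0.05 * s_att[1])              # calm before the first raise
    for (a in seq_len(napf)) {
      anchor_t <- c(anchor_t, content_start[a], content_end[a],
                    content_end[a] + SYN$gesture_len)
      anchor_s <- c(anchor_s, s_att[a], s_att[a], 0.05 * s_att[a])
    }
    sprof <- approx(anchor_t, anchor_s, xout = t[-1], rule = 2)$y
    pos <- rbind(0, apply(steps * sprof, 2, cumsum))
    pos <- sweep(pos, 2, SYN$base_pos[part, ], "+")
    jit <- vapply(1:3, function(axis)
      ou_noise(n, 1 / rate, SYN$jitter_sd * cfg$noise_sd, SYN$jitter_tau),
      numeric(n))
    x[, , p] <- pos + jit
  }

  # sync gestures: trapezoid raise of the right hand (and, attenuated, the
  # right wrist) at the start and end of every attempt
  raise <- function(tg) {
    dtg <- t - tg
    r <- numeric(n)
    ramp <- SYN$gesture_ramp; gl <- SYN$gesture_len
    inr <- dtg >= 0 & dtg <= gl
    r[inr] <- pmin(1, pmin(dtg[inr], gl - dtg[inr]) / ramp)
    r * SYN$gesture_raise
  }
  for (a in seq_len(napf)) {
    for (tg in c(g_start[a], content_end[a])) {
      r <- raise(tg)
      x[, "y", "hand_r"] <- x[, "y", "hand_r"] + r
      x[, "y", "wrist_r"] <- x[, "y", "wrist_r"] + 0.8 * r
    }
  }
  list(t = t, x = x)
}

#' Exclude participants from a cohort
#'
#' Drops every recording of the listed participants (emulating exclusion of
#' corrupted/incomplete data) and reports the number of removed
#' attempt-datasets. On the default cohort, excluding 3 of 15 participants
#' removes 81 attempt-datasets (9 attempts x 3 exercises x 3 participants)
#' and leaves 324.
#'
#' @param cohort An `mm_cohort`.
#' @param ids Character vector of participant ids; defaults to the ids the
#'   generator marked as corrupted (`cohort$excluded_ids`).
#' @return The reduced `mm_cohort`, with attribute `n_removed` (count of
#'   removed attempt-datasets).
#' @export
exclude_participants <- function(cohort, ids = cohort$excluded_ids) {
  stopifnot(inherits(cohort, "mm_cohort"))
  unknown <- setdiff(ids, cohort$participants$participant)
  abort_if(length(unknown) > 0,
           paste0("unknown participant id(s): ", paste(unknown, collapse = ", ")),
           "endoskill_id_error")
  keep <- vapply(cohort$recordings,
                 function(r) !(r$meta$participant %in% ids), logical(1))
  removed_attempts <- sum(cohort$truth$participant %in% ids)
  cohort$recordings <- cohort$recordings[keep]
  cohort$truth <- cohort$truth[!(cohort$truth$participant %in% ids), ]
  cohort$participants <-
    cohort$participants[!(cohort$participants$participant %in% ids), ]
  cohort$excluded_ids <- setdiff(cohort$excluded_ids, ids)
  attr(cohort, "n_removed") <- removed_attempts
  cohort
}
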