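#' Band-limited power spectrum of an sEMG channel
#'
#' Mean-removed one-sided periodogram restricted to a frequency band. The
#' grid resolution is `rate / N` for the `N` samples used. Power is
#' normalised so that the band-unrestricted total equals the population
#' variance of the signal (Parseval). For speed on long attempts the
#' signal may be trimmed to the largest 5-smooth FFT length not exceeding
#' its length (`fast = TRUE`, at most a ~1 percent trim); set
#' `fast = FALSE` to use every sample.
#'
#' @param signal Numeric sample vector (>= 64 samples).
#' @param rate Sampling rate, Hz.
#' @param band Length-2 numeric, the (lo, hi) band in Hz; must lie within
#'   (0, rate/2].
#' @param fast Trim to a 5-smooth FFT length (default TRUE).
#' @return A `spectrum_band` object: list with `frequencies` (Hz, increasing),
#'   `power` (non-negative), `band`, `n_used`.
#' @export
power_spectrum <- function(signal, rate, band = c(10, 95), fast = TRUE) {
  abort_if(length(signal) < 64, "signal too short for a spectrum (< 64 samples)",
           "endoskill_feature_error")
  abort_if(band[1] <= 0 || band[2] > rate / 2 || band[1] >= band[2],
           "band must lie within (0, rate/2)", "endoskill_feature_error")
  n <- if (fast) smooth_length(length(signal)) else length(signal)
  x <- signal[seq_len(n)]
  x <- x - mean(x)
  X <- fft(x)
  kmax <- floor(n / 2)
  k <- seq_len(kmax)
  p <- 2 * Mod(X[k + 1])^2 / n^2
  if (n %% 2 == 0) p[kmax] <- p[kmax] / 2      # Nyquist bin is not doubled
  f <- k * rate / n
  inb <- f >= band[1] & f <= band[2]
  structure(list(frequencies = f[inb], power = p[inb],
                 band = band, n_used = n),
            class = "spectrum_band")
}

#' Spectral features of a band-limited spectrum
#'
#' The most and least powerful frequencies in the band, their power values,
#' and the (signed) distance between them. Ties are broken towards the
#' lowest frequency, so a uniform spectrum yields the band's lower edge for
#' both.
#'
#' @param s A `spectrum_band` from [power_spectrum()].
#' @param abs_range Report `f_Range` as an absolute value instead of signed
#'   `f_Max - f_Min` (default FALSE).
#' @return Named numeric: `f_Max`, `f_Min`, `f_Range`, `P_Max`, `P_Min`.
#' @export
spectral_features <- function(s, abs_range = FALSE) {
  stopifnot(inherits(s, "spectrum_band"))
  abort_if(length(s$power) == 0, "degenerate spectrum (empty band)",
           "endoskill_feature_error")
  imax <- which.max(s$power)
  imin <- which.min(s$power)
  f_range <- s$frequencies[imax] - s$frequencies[imin]
  c(f_Max = s$frequencies[imax],
    f_Min = s$frequencies[imin],
    f_Range = if (abs_range) abs(f_range) else f_range,
    P_Max = s$power[imax],
    P_Min = s$power[imin])
}

#' Amplitude features of an sEMG channel
#'
#' Extremes, range, root-mean-square and variance of the raw samples.
#' Variance uses the population convention (divisor N), consistent with
#' the Parseval normalisation of [power_spectrum()].
#'
#' @param signal Non-empty numeric vector.
#' @return Named numeric: `V_Max`, `V_Min`, `V_Range`, `V_RMS`, `V_Var`.
#' @export
amplitude_features <- function(signal) {
  abort_if(length(signal) == 0, "empty signal", "endoskill_feature_error")
  vmax <- max(signal)
  vmin <- min(signal)
  c(V_Max = vmax, V_Min = vmin, V_Range = vmax - vmin,
    V_RMS = sqrt(mean(signal^2)),
    V_Var = mean((signal - mean(signal))^2))
}

#' Morphology features of an sEMG channel
#'
#' Sign-slope changes (`V_SSC`, local extrema of the sampled curve),
#' zero crossings (`V_ZC`, strict sign product `< 0`; samples exactly at
#' zero do not count) and waveform length (`V_WFL`, cumulative absolute
#' sample-to-sample change). These grow with attempt length, so by default
#' each is divided by the sample count.
#'
#' @param signal Numeric vector, at least 3 samples.
#' @param per_sample Divide each count/length by the number of samples
#'   (default TRUE).
#' @return Named numeric: `V_SSC`, `V_ZC`, `V_WFL`.
#' @export
morphology_features <- function(signal, per_sample = TRUE) {
  n <- length(signal)
  abort_if(n < 3, "need at least 3 samples", "endoskill_feature_error")
  d <- diff(signal)
  ssc <- sum(d[-length(d)] * d[-1] < 0)
  zc <- sum(signal[-n] * signal[-1] < 0)
  wfl <- sum(abs(d))
  out <- c(V_SSC = ssc, V_ZC = zc, V_WFL = wfl)
  if (per_sample) out <- out / n
  out
}

#' Orientation (IMU) features
#'
#' Area under the absolute roll, pitch and yaw curves (trapezoidal rule
#' over the sample index), and the frequency-excursion score `FES`: the
#' ratio of the channel-averaged dominant sEMG frequency to the mean of
#' the three AUCs. A constant unit trace over N samples has raw AUC
#' `N - 1`.
#'
#' @param roll,pitch,yaw Equal-length numeric vectors (radians).
#' @param f_max_mean Dominant sEMG frequency averaged over the 8 channels
#'   (Hz, >= 0).
#' @param per_sample Divide each AUC by the sample count (default TRUE).
#' @return Named numeric: `Roll_AUC`, `Pitch_AUC`, `Yaw_AUC`, `FES` (`NA`
#'   when the mean AUC is zero).
#' @export
imu_features <- function(roll, pitch, yaw, f_max_mean, per_sample = TRUE) {
  stopifnot(length(roll) == length(pitch), length(pitch) == length(yaw))
  abort_if(f_max_mean < 0, "f_max_mean must be >= 0", "endoskill_feature_error")
  auc1 <- function(v) {
    a <- abs(v)
    s <- sum((a[-length(a)] + a[-1]) / 2)
    if (per_sample) s / length(a) else s
  }
  aucs <- c(Roll_AUC = auc1(roll), Pitch_AUC = auc1(pitch),
            Yaw_AUC = auc1(yaw))
  m <- mean(aucs)
  c(aucs, FES = if (m > 0) f_max_mean / m else NA_real_)
}

#' All 13 sEMG features for one channel
#'
#' Convenience wrapper computing the spectral, amplitude and morphology
#' features of Table-style attempt rating for a single channel. A constant
#' (dead) channel yields an all-zero spectrum, whose spectral features
#' collapse to the band's lower edge with zero power by the tie-break rule.
#'
#' @inheritParams power_spectrum
#' @inheritParams morphology_features
#' @param abs_range Passed to [spectral_features()].
#' @return Named numeric vector of the 13 features in canonical order.
#' @export
emg_channel_features <- function(signal, rate, band = c(10, 95),
                                 per_sample = TRUE, abs_range = FALSE,
                                 fast = TRUE) {
  s <- power_spectrum(signal, rate, band, fast = fast)
  out <- c(spectral_features(s, abs_range = abs_range),
           amplitude_features(signal),
           morphology_features(signal, per_sample = per_sample))
  out[emg_feature_names()]
}
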