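#' @importFrom stats approx fft filter mvfft median var sd runmed rnorm runif
#'   rlnorm rpois quantile fivenum pf aov predict coef complete.cases
#' @importFrom utils head tail
#' @importFrom grDevices boxplot.stats
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg, class = "endoskill_error") {
  if (isTRUE(cond)) stop(errorCondition(msg, class = c(class, "error")))
}

#' Canonical metric layout
#'
#' Each attempt is summarised by 160 canonical metrics: 13 sEMG features
#' computed once per armband channel (104 columns named `feature@ch1` ...
#' `feature@ch8`) plus 7 motion-analysis parameters (MAPs) computed once per
#' tracked body part (56 columns named `map@part`). Four armband orientation
#' features (`Roll_AUC`, `Pitch_AUC`, `Yaw_AUC`, `FES`) are computed as well
#' but carried outside the canonical 160 (see the methods vignette for why
#' they cannot be part of it under any per-channel multiplication).
#'
#' @return Character vectors of metric names.
#' @name metric-layout
NULL

#' @rdname metric-layout
#' @export
emg_feature_names <- function() {
  c("f_Max", "f_Min", "f_Range", "P_Max", "P_Min",
    "V_Max", "V_Min", "V_Range", "V_RMS",
    "V_SSC", "V_ZC", "V_WFL", "V_Var")
}

#' @rdname metric-layout
#' @export
map_feature_names <- function() {
  c("POC", "Trace", "Velocity",
    "Angle_Mean", "Angle_Max", "Angle_Min", "Angle_Range")
}

#' @rdname metric-layout
#' @export
body_part_names <- function() {
  c("head", "spine_shoulders",
    "elbow_l", "wrist_l", "hand_l",
    "elbow_r", "wrist_r", "hand_r")
}

#' @rdname metric-layout
#' @export
imu_feature_names <- function() {
  c("Roll_AUC", "Pitch_AUC", "Yaw_AUC", "FES")
}

#' @rdname metric-layout
#' @export
canonical_metrics <- function() {
  emg <- as.vector(t(outer(emg_feature_names(), paste0("ch", 1:8),
                           function(f, ch) paste0(f, "@", ch))))
  map <- as.vector(t(outer(map_feature_names(), body_part_names(),
                           function(f, p) paste0(f, "@", p))))
  c(emg, map)
}

#' @rdname metric-layout
#' @export
all_metrics <- function() c(canonical_metrics(), imu_feature_names())

#' Affiliation of a metric
#'
#' sEMG metrics are affiliated with their feature (averaged over the eight
#' channels in reduced distance maps); MAP metrics with their body part
#' (averaged over the seven MAPs); orientation metrics are singletons.
#'
#' @param metrics Character vector of metric names (`feature@channel`,
#'   `map@part`, or an orientation feature name).
#' @return Character vector of affiliation labels.
#' @export
metric_affiliation <- function(metrics) {
  vapply(metrics, function(m) {
    if (m %in% imu_feature_names()) return(m)
    parts <- strsplit(m, "@", fixed = TRUE)[[1]]
    abort_if(length(parts) != 2L, paste0("not a canonical metric name: ", m))
    if (grepl("^ch[0-9]+$", parts[2])) parts[1] else parts[2]
  }, character(1), USE.NAMES = FALSE)
}

# largest 5-smooth (2^a 3^b 5^c) integer <= n; used to keep FFT lengths fast
smooth_length <- function(n) {
  abort_if(n < 1, "n must be positive")
  best <- 1
  p5 <- 1
  while (p5 <= n) {
    p35 <- p5
    while (p35 <= n) {
      # largest power of two fitting the remaining factor
      k <- p35 * 2^floor(log2(n / p35))
      if (k > best) best <- k
      p35 <- p35 * 3
    }
    p5 <- p5 * 5
  }
  best
}

# Ornstein-Uhlenbeck noise on a regular grid (stationary, sd `sigma`,
# correlation time `tau` seconds)
ou_noise <- function(n, dt, sigma, tau) {
  if (n == 0L) return(numeric(0))
  a <- exp(-dt / tau)
  innov <- rnorm(n, sd = sigma * sqrt(1 - a^2))
  innov[1] <- rnorm(1, sd = sigma)
  as.numeric(stats::filter(innov, a, method = "recursive"))
}
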