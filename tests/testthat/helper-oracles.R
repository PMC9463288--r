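# Independent brute-force oracles. These reimplement every attempt-rating
# feature from its definition (explicit DFT, direct counting loops,
# exhaustive pair enumeration, eigenvalue-based epsilon) without sharing
# code with the package, and are only trusted at small problem sizes.

# explicit O(N^2) DFT periodogram, one-sided, Parseval-normalised
oracle_periodogram <- function(x, rate, band) {
  n <- length(x)
  x <- x - mean(x)
  kmax <- floor(n / 2)
  f <- p <- numeric(0)
  for (k in seq_len(kmax)) {
    w <- exp(-2i * pi * k * (0:(n - 1)) / n)
    Xk <- sum(x * w)
    pk <- 2 * Mod(Xk)^2 / n^2
    if (n %% 2 == 0 && k == kmax) pk <- pk / 2
    fk <- k * rate / n
    if (fk >= band[1] && fk <= band[2]) {
      f <- c(f, fk); p <- c(p, pk)
    }
  }
  list(frequencies = f, power = p)
}

oracle_spectral <- function(x, rate, band) {
  s <- oracle_periodogram(x, rate, band)
  imax <- which(s$power == max(s$power))[1]
  imin <- which(s$power == min(s$power))[1]
  c(f_Max = s$frequencies[imax], f_Min = s$frequencies[imin],
    f_Range = s$frequencies[imax] - s$frequencies[imin],
    P_Max = s$power[imax], P_Min = s$power[imin])
}

oracle_amplitude <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  c(V_Max = max(x), V_Min = min(x), V_Range = max(x) - min(x),
    V_RMS = sqrt(sum(x^2) / n), V_Var = sum((x - m)^2) / n)
}

oracle_morphology <- function(x, per_sample) {
  n <- length(x)
  ssc <- 0L; zc <- 0L; wfl <- 0
  for (k in 2:(n - 1))
    if ((x[k] - x[k - 1]) * (x[k + 1] - x[k]) < 0) ssc <- ssc + 1L
  for (k in 1:(n - 1)) {
    if (x[k] * x[k + 1] < 0) zc <- zc + 1L
    wfl <- wfl + abs(x[k + 1] - x[k])
  }
  out <- c(V_SSC = ssc, V_ZC = zc, V_WFL = wfl)
  if (per_sample) out / n else out
}

oracle_auc <- function(v, per_sample) {
  s <- 0
  for (k in 1:(length(v) - 1))
    s <- s + (abs(v[k]) + abs(v[k + 1])) / 2
  if (per_sample) s / length(v) else s
}

oracle_trace_velocity <- function(pos, ts) {
  tr <- 0
  for (k in 2:nrow(pos))
    tr <- tr + sqrt(sum((pos[k, ] - pos[k - 1, ])^2))
  c(Trace = tr, Velocity = tr / (ts[length(ts)] - ts[1]))
}

oracle_poc <- function(y, h) {
  # counts hysteresis-debounced reversals by tracking the running extreme
  dir <- 0L; count <- 0L
  hi <- y[1]; lo <- y[1]; ext <- y[1]
  for (v in y[-1]) {
    if (dir == 0L) {
      hi <- max(hi, v); lo <- min(lo, v)
      if (v - lo >= h) { dir <- 1L; ext <- v }
      else if (hi - v >= h) { dir <- -1L; ext <- v }
    } else if (dir == 1L) {
      if (v > ext) ext <- v
      else if (ext - v >= h) { count <- count + 1L; dir <- -1L; ext <- v }
    } else {
      if (v < ext) ext <- v
      else if (v - ext >= h) { count <- count + 1L; dir <- 1L; ext <- v }
    }
  }
  count
}

oracle_angles <- function(pos, parent, axis) {
  angs <- numeric(0)
  for (k in seq_len(nrow(pos))) {
    v <- pos[k, ] - parent[k, ]
    a <- axis[k, ]
    nv <- sqrt(sum(v^2)); na_ <- sqrt(sum(a^2))
    if (nv == 0 || na_ == 0) next
    cosang <- max(-1, min(1, sum(v * a) / (nv * na_)))
    angs <- c(angs, acos(cosang) * 180 / pi)
  }
  c(Angle_Mean = mean(angs), Angle_Max = max(angs),
    Angle_Min = min(angs), Angle_Range = max(angs) - min(angs))
}

# exhaustive all-pairs median (ascending sort, midpoint for even counts)
oracle_median_representative <- function(v2d, v3d) {
  d <- numeric(0)
  for (a in v2d) for (b in v3d) d <- c(d, abs(a - b))
  d <- sort(d)
  n <- length(d)
  if (n %% 2 == 1) d[(n + 1) / 2] else (d[n / 2] + d[n / 2 + 1]) / 2
}

# Greenhouse-Geisser epsilon from the eigenvalues of the contrast-space
# covariance
oracle_eps_gg_eigen <- function(Y, group) {
  k <- ncol(Y); N <- nrow(Y)
  group <- as.factor(group)
  S <- matrix(0, k, k)
  for (lv in levels(group)) {
    Yg <- Y[group == lv, , drop = FALSE]
    S <- S + crossprod(scale(Yg, center = TRUE, scale = FALSE))
  }
  S <- S / (N - nlevels(group))
  Cn <- stats::contr.helmert(k)
  Cn <- sweep(Cn, 2, sqrt(colSums(Cn^2)), "/")
  M <- t(Cn) %*% S %*% Cn
  lam <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  sum(lam)^2 / ((k - 1) * sum(lam^2))
}

random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
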