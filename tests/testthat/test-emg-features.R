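test_that("a pure sinusoid peaks at its own frequency bin", {
  rate <- 200
  t <- (0:999) / rate
  x <- sin(2 * pi * 40 * t)                  # 40 Hz sits exactly on the grid
  s <- power_spectrum(x, rate, band = c(10, 95))
  expect_equal(s$frequencies[which.max(s$power)], 40)
  expect_equal(unname(spectral_features(s)["f_Max"]), 40)
  # closed form: a unit sinusoid has variance 1/2, all in one bin
  expect_equal(max(s$power), 0.5, tolerance = 1e-10)
})

test_that("total spectral power satisfies Parseval", {
  set.seed(1)
  for (n in c(256, 1000, 4096)) {
    x <- rnorm(n) + 0.3 * sin(2 * pi * 33 * (1:n) / 200)
    s <- power_spectrum(x, 200, band = c(200 / n / 2, 100), fast = FALSE)
    expect_equal(sum(s$power), mean((x - mean(x))^2), tolerance = 1e-6)
  }
})

test_that("white noise spreads its power uniformly over the band", {
  set.seed(2)
  x <- rnorm(16384)
  s <- power_spectrum(x, 200, band = c(10, 95))
  expect_equal(sum(s$power), var(x) * (95 - 10) / 100, tolerance = 0.1)
})

test_that("constant and degenerate signals are handled by the rules", {
  s <- power_spectrum(rep(3.2, 256), 200, band = c(10, 95))
  expect_true(all(s$power == 0))
  sf <- spectral_features(s)                 # tie-break: band lower edge
  expect_equal(unname(sf["f_Max"]), min(s$frequencies))
  expect_equal(unname(sf["f_Max"]), unname(sf["f_Min"]))
  expect_equal(unname(sf["f_Range"]), 0)
  expect_equal(unname(sf["P_Max"]), 0)
  expect_error(power_spectrum(rnorm(32), 200), class = "endoskill_feature_error")
})

test_that("spectral features read off the periodogram directly", {
  s <- structure(list(frequencies = c(20, 40, 60), power = c(1, 5, 2),
                      band = c(10, 95), n_used = 3),
                 class = "spectrum_band")
  expect_equal(spectral_features(s),
               c(f_Max = 40, f_Min = 20, f_Range = 20, P_Max = 5, P_Min = 1))
  s$power <- c(2, 5, 1)                      # f_Min above f_Max: signed range
  expect_equal(unname(spectral_features(s)["f_Range"]), -20)
  expect_equal(unname(spectral_features(s, abs_range = TRUE)["f_Range"]), 20)
})

test_that("amplitude features follow their closed forms", {
  expect_equal(amplitude_features(c(3, -1, 2)),
               c(V_Max = 3, V_Min = -1, V_Range = 4,
                 V_RMS = sqrt(14 / 3), V_Var = 26 / 9))
  expect_equal(amplitude_features(rep(-2.5, 10)),
               c(V_Max = -2.5, V_Min = -2.5, V_Range = 0,
                 V_RMS = 2.5, V_Var = 0))
  t <- (0:9999) / 200
  x <- 2 * sin(2 * pi * 10 * t)
  expect_equal(unname(amplitude_features(x)["V_RMS"]), 2 / sqrt(2),
               tolerance = 0.01)
  expect_error(amplitude_features(numeric(0)),
               class = "endoskill_feature_error")
})

test_that("morphology features count crossings, slope changes and length", {
  raw <- morphology_features(c(1, -1, 1, -1), per_sample = FALSE)
  expect_equal(raw, c(V_SSC = 2, V_ZC = 3, V_WFL = 6))
  expect_equal(morphology_features(c(1, -1, 1, -1), per_sample = TRUE),
               raw / 4)
  expect_equal(unname(morphology_features(1:50, per_sample = FALSE)["V_SSC"]),
               0)
  set.seed(3)
  walk <- cumsum(sample(c(-1, 1), 200, replace = TRUE))
  expect_equal(unname(morphology_features(walk, per_sample = FALSE)["V_WFL"]),
               199)
})

test_that("orientation features integrate |curve| over the sample index", {
  n <- 50
  f <- imu_features(rep(1, n), rep(1, n), rep(1, n), f_max_mean = 10,
                    per_sample = FALSE)
  expect_equal(unname(f[1:3]), rep(n - 1, 3))
  expect_equal(unname(f["FES"]), 10 / (n - 1))

  f2 <- imu_features(rep(1, n), rep(2, n), rep(3, n), f_max_mean = 4)
  expect_equal(unname(f2["FES"]), 4 / mean(c(1, 2, 3) * (n - 1) / n))

  t <- seq(0, 50, by = 1e-3)
  f3 <- imu_features(abs(sin(2 * pi * t)), rep(1, length(t)),
                     rep(1, length(t)), f_max_mean = 0)
  expect_equal(unname(f3["Roll_AUC"]), 2 / pi, tolerance = 0.01)

  f4 <- imu_features(rep(0, n), rep(0, n), rep(0, n), f_max_mean = 10)
  expect_true(is.na(f4["FES"]))
})

test_that("feature symmetries hold on random signals", {
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(200) * runif(1, 0.5, 20)
    expect_equal(amplitude_features(x), amplitude_features(rev(x)))
    m <- morphology_features(x, per_sample = FALSE)
    mf <- morphology_features(-x, per_sample = FALSE)
    expect_equal(m[c("V_SSC", "V_ZC")], mf[c("V_SSC", "V_ZC")])
    c_ <- runif(1, 0.1, 10)
    expect_equal(unname(morphology_features(c_ * x,
                                            per_sample = FALSE)["V_WFL"]),
                 unname(c_ * m["V_WFL"]))
  }
})

test_that("every sEMG and orientation feature matches its brute-force oracle", {
  set.seed(5)
  for (i in 1:100) {
    n <- sample(64:200, 1)
    x <- rnorm(n) * runif(1, 0.5, 30) +
      runif(1, 0, 5) * sin(2 * pi * runif(1, 12, 90) * (1:n) / 200)
    band <- c(10, 95)
    got <- emg_channel_features(x, 200, band, per_sample = TRUE, fast = FALSE)
    want <- c(oracle_spectral(x, 200, band), oracle_amplitude(x),
              oracle_morphology(x, per_sample = TRUE))
    expect_equal(got, want[names(got)], tolerance = 1e-10)

    ni <- sample(10:60, 1)
    r <- rnorm(ni); p <- rnorm(ni); yw <- rnorm(ni)
    fm <- runif(1, 0, 90)
    got_imu <- imu_features(r, p, yw, fm, per_sample = TRUE)
    aucs <- c(oracle_auc(r, TRUE), oracle_auc(p, TRUE), oracle_auc(yw, TRUE))
    expect_equal(unname(got_imu[1:3]), aucs, tolerance = 1e-10)
    expect_equal(unname(got_imu["FES"]), fm / mean(aucs), tolerance = 1e-10)
  }
})
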