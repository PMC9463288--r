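# builds an N x k matrix whose pooled within-group covariance equals S
# exactly (whiten the sample, then colour by chol(S))
exact_cov_sample <- function(n, S, group) {
  k <- ncol(S)
  out <- matrix(NA_real_, n, k)
  for (lv in unique(group)) {
    i <- which(group == lv)
    Z <- scale(matrix(rnorm(length(i) * k), length(i), k),
               center = TRUE, scale = FALSE)
    W <- Z %*% solve(chol(crossprod(Z) / (length(i) - 1)))
    out[i, ] <- W %*% chol(S)
  }
  out
}

test_that("compound-symmetric data yield epsilon exactly 1", {
  set.seed(10)
  S <- matrix(0.4, 3, 3); diag(S) <- 1
  g <- rep(c("2D", "3D"), c(6, 6))
  Y <- exact_cov_sample(12, S, g)
  r <- hf_epsilon(Y, g)
  expect_equal(r$eps_gg, 1, tolerance = 1e-12)
  expect_equal(r$eps_hf, 1)
})

test_that("two repeated measures force epsilon to 1", {
  set.seed(11)
  Y <- matrix(rnorm(24), 12, 2)
  g <- rep(c("a", "b"), 6)
  expect_equal(hf_epsilon(Y, g)$eps_hf, 1)
})

test_that("epsilon matches the eigenvalue-based oracle", {
  set.seed(12)
  g <- rep(c("2D", "3D"), c(5, 7))
  for (i in 1:50) {
    A <- matrix(rnorm(9), 3, 3)
    S <- crossprod(A) + diag(3) * 0.1
    Y <- MASS::mvrnorm(12, rep(0, 3), S)
    r <- hf_epsilon(Y, g)
    expect_equal(r$eps_gg, oracle_eps_gg_eigen(Y, g), tolerance = 1e-10)
    expect_gt(r$eps_hf, 0.5)                 # 1/(k-1) lower bound
    expect_lte(r$eps_hf, 1)
  }
})

test_that("constant data trigger the singular-covariance warning", {
  Y <- matrix(5, 10, 3)
  g <- rep(c("a", "b"), 5)
  expect_warning(r <- hf_epsilon(Y, g), "singular")
  expect_equal(r$eps_hf, 1)
})

test_that("the split-plot decomposition matches the aov oracle", {
  set.seed(13)
  g <- rep(c("2D", "3D"), c(5, 7))
  for (i in 1:20) {
    Y <- MASS::mvrnorm(12, c(0, 0.3, 0.6) * runif(1, 0, 2),
                       crossprod(matrix(rnorm(9), 3, 3)) + diag(3))
    r <- ranova_session(Y, g)
    df <- data.frame(y = as.vector(Y), subj = factor(rep(1:12, 3)),
                     time = factor(rep(1:3, each = 12)),
                     grp = factor(rep(g, 3)))
    a <- summary(aov(y ~ grp * time + Error(subj / time), df))
    tab <- a[["Error: subj:time"]][[1]]
    expect_equal(r$F_time, tab["time", "F value"], tolerance = 1e-10)
    expect_equal(r$F_int, tab["grp:time", "F value"], tolerance = 1e-10)
    # with epsilon clipped at 1 the p-values equal the uncorrected ANOVA
    if (r$eps_hf == 1) {
      expect_equal(r$p_time, tab["time", "Pr(>F)"], tolerance = 1e-10)
      expect_equal(r$p_time_endo, tab["grp:time", "Pr(>F)"],
                   tolerance = 1e-10)
    }
  }
})

test_that("no time variation means F = 0 and p = 1", {
  set.seed(14)
  base <- rnorm(12)
  Y <- cbind(base, base, base)
  r <- suppressWarnings(ranova_session(Y, rep(c("a", "b"), 6)))
  expect_equal(r$F_time, 0)
  expect_equal(r$p_time, 1)
})

test_that("null repeated measures give calibrated, uniform p-values", {
  set.seed(15)
  g <- rep(c("2D", "3D"), c(5, 7))
  ps <- replicate(1000, ranova_session(matrix(rnorm(36), 12, 3), g)$p_time)
  expect_gt(mean(ps < 0.05), 0.03)
  expect_lt(mean(ps < 0.05), 0.07)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("a one-SD session trend makes its feature the clear minimum", {
  set.seed(16)
  g <- rep(c("2D", "3D"), c(6, 6))
  hits <- 0L
  for (rep_ in 1:20) {
    p_null <- replicate(30,
      ranova_session(matrix(rnorm(36), 12, 3), g)$p_time)
    Yt <- matrix(rnorm(36), 12, 3) +
      rep(c(0, 1, 2), each = 12)             # 1 within-subject SD per step
    p_trend <- ranova_session(Yt, g)$p_time
    if (p_trend < min(p_null)) hits <- hits + 1L
  }
  expect_gte(hits, 19)
})

test_that("ranova_table analyses every metric in every session", {
  tb <- small_tables()[[1]]
  tb$`Trace@head` <- 5                        # force a constant metric
  res <- ranova_table(tb, metrics = c("Velocity@hand_r", "V_RMS@ch1",
                                      "Trace@head"))
  expect_equal(nrow(res), 9)
  expect_setequal(unique(res$session), 1:3)
  expect_true(all(res$p_time > 0 & res$p_time <= 1))
  expect_true(all(res$eps_hf > 0.5 & res$eps_hf <= 1))
  # a constant metric is reported as p = 1, not an error
  expect_true(all(res$p_time[res$feature == "Trace@head"] == 1))
  adj <- ranova_table(tb, metrics = c("Velocity@hand_r", "V_RMS@ch1"),
                      adjust = "BH")
  expect_true(all(adj$p_time >= res$p_time[res$feature %in% adj$feature]))
})

test_that("significance ticks sit at the conventional -log10 values", {
  ticks <- significance_ticks()
  expect_equal(round(unname(ticks[1]), 4), 1.3010)
  expect_equal(unname(ticks[2]), 2)
  expect_equal(unname(ticks[3]), 3)
})

test_that("boxplot summaries flag strong features as outliers", {
  res <- tibble::tibble(
    feature = rep(c(sprintf("null%02d", 1:40), "Velocity@hand_r"), 3),
    session = rep(1:3, each = 41),
    p_time = rep(c(stats::runif(40, 0.2, 0.9), 1e-7), 3),
    p_time_endo = stats::runif(123, 0.05, 1),
    eps_hf = 1, F_time = 1, F_int = 1)
  s <- neglog10_summary(res)
  expect_equal(round(unname(s$ticks[1]), 4), 1.3010)
  tt <- s$summaries[s$summaries$effect == "time", ]
  for (i in seq_len(nrow(tt))) {
    expect_true("Velocity@hand_r" %in% tt$outliers[[i]]$feature)
  }
  v <- -log10(res$p_time[res$session == 1])
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
  expect_lte(tt$upper_whisker[1], q[2] + 1.5 * (q[2] - q[1]))
})
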