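#' Huynh-Feldt epsilon for a repeated-measures session
#'
#' Estimates the sphericity correction factor for a split-plot design with
#' `k` repeated measures (attempts within a session) and a between-subject
#' endoscope factor. The pooled within-group covariance `S` of the `k`
#' measures is projected onto an orthonormal contrast basis `C`
#' (`M = C S C'`); the Greenhouse-Geisser estimate is
#' `eps_GG = tr(M)^2 / ((k-1) tr(M^2))` and the Huynh-Feldt correction is
#' `eps_HF = (N (k-1) eps_GG - 2) / ((k-1) (N - g - (k-1) eps_GG))`,
#' clipped to at most 1 (and floored at its theoretical lower bound
#' `1/(k-1)`). Compound-symmetric data satisfy sphericity exactly and
#' yield 1.
#'
#' @param Y N x k numeric matrix: one row per subject, one column per
#'   repeated measure.
#' @param group Length-N factor/vector of between-subject group labels.
#' @return List with `eps_hf`, `eps_gg`, `S` (pooled covariance) and `M`.
#' @export
hf_epsilon <- function(Y, group) {
  Y <- as.matrix(Y)
  k <- ncol(Y)
  N <- nrow(Y)
  group <- as.factor(group)
  g <- nlevels(group)
  abort_if(N <= g, "need more subjects than groups", "endoskill_ranova_error")
  abort_if(k < 2, "need at least 2 repeated measures", "endoskill_ranova_error")

  S <- matrix(0, k, k)
  for (lv in levels(group)) {
    Yg <- Y[group == lv, , drop = FALSE]
    if (nrow(Yg) > 1)
      S <- S + crossprod(scale(Yg, center = TRUE, scale = FALSE))
  }
  S <- S / (N - g)

  C <- orthonormal_contrasts(k)
  M <- C %*% S %*% t(C)
  trM <- sum(diag(M))
  trM2 <- sum(M * M)
  if (trM2 <= .Machine$double.eps * max(1, trM^2)) {
    warning("singular within-subject covariance; epsilon set to 1",
            call. = FALSE)
    eps_gg <- 1
  } else {
    eps_gg <- trM^2 / ((k - 1) * trM2)
  }
  eps_hf <- (N * (k - 1) * eps_gg - 2) /
    ((k - 1) * (N - g - (k - 1) * eps_gg))
  eps_hf <- min(1, max(eps_hf, 1 / (k - 1)))
  list(eps_hf = eps_hf, eps_gg = eps_gg, S = S, M = M)
}

# (k-1) x k matrix with orthonormal rows, each orthogonal to the unit vector
orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)          # k x (k-1)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")
  t(C)
}

#' Split-plot repeated-measures ANOVA for one session
#'
#' One feature, one session (a triplet of consecutive attempts): subjects
#' are the random factor, attempt index the within-subject factor (k = 3),
#' endoscope the sole between-subject factor. Sequential sums of squares
#' on the within-subject stratum give the time and time x endoscope tests;
#' both are Huynh-Feldt corrected (numerator and denominator degrees of
#' freedom multiplied by `eps_hf`).
#'
#' @inheritParams hf_epsilon
#' @return A `ranova_result` list: `p_time`, `p_time_endo`, `eps_hf`,
#'   `F_time`, `F_int`, `df` (uncorrected degrees of freedom).
#' @export
ranova_session <- function(Y, group) {
  Y <- as.matrix(Y)
  k <- ncol(Y)
  N <- nrow(Y)
  group <- as.factor(group)
  g <- nlevels(group)
  abort_if(any(table(group) < 2), "every group needs at least 2 subjects",
           "endoskill_ranova_error")
  abort_if(anyNA(Y), "Y must be complete (impute first)",
           "endoskill_ranova_error")

  eps <- hf_epsilon(Y, group)$eps_hf

  z <- Y - rowMeans(Y)                       # within-subject stratum
  zt <- colMeans(z)                          # time means over all subjects
  ss_time <- N * sum(zt^2)
  ss_cells <- 0
  for (lv in levels(group)) {
    zg <- colMeans(z[group == lv, , drop = FALSE])
    ss_cells <- ss_cells + sum(group == lv) * sum(zg^2)
  }
  ss_int <- ss_cells - ss_time
  ss_err <- sum(z^2) - ss_cells

  df_time <- k - 1
  df_int <- (g - 1) * (k - 1)
  df_err <- (N - g) * (k - 1)
  ms_err <- ss_err / df_err

  if (ms_err <= 0) {
    f_time <- if (ss_time > 0) Inf else 0
    f_int <- if (ss_int > 0) Inf else 0
  } else {
    f_time <- (ss_time / df_time) / ms_err
    f_int <- (ss_int / df_int) / ms_err
  }
  p_time <- pf(f_time, eps * df_time, eps * df_err, lower.tail = FALSE)
  p_int <- pf(f_int, eps * df_int, eps * df_err, lower.tail = FALSE)

  structure(list(p_time = p_time, p_time_endo = p_int, eps_hf = eps,
                 F_time = f_time, F_int = f_int,
                 df = c(time = df_time, int = df_int, error = df_err)),
            class = "ranova_result")
}

#' RANOVA over all features and sessions of a feature table
#'
#' Splits the nine attempts into sessions (1-3, 4-6, 7-9), builds for every
#' metric and session the N x 3 subject-by-attempt matrix, and returns the
#' Huynh-Feldt-corrected time and time x endoscope p-values. Missing
#' entries are group-mean imputed first. Metrics constant within a session
#' are reported with p = 1.
#'
#' @param tbl A `feature_table` (one exercise) with complete attempts 1-9
#'   per participant.
#' @param metrics Metric columns to analyse; defaults to all canonical and
#'   orientation metrics present.
#' @param adjust Optional multiple-testing adjustment across features per
#'   session/effect (a [stats::p.adjust] method, e.g. `"BH"`); default
#'   `"none"`.
#' @return Tibble: `feature`, `session`, `p_time`, `p_time_endo`,
#'   `eps_hf`, `F_time`, `F_int`.
#' @export
ranova_table <- function(tbl, metrics = metric_columns(tbl),
                         adjust = "none") {
  tbl <- impute_features(tbl)
  k <- 3L
  sessions <- split(1:9, rep(1:3, each = k))
  parts <- sort(unique(tbl$participant))
  group <- vapply(parts, function(p)
    tbl$endoscope[tbl$participant == p][1], character(1))

  res <- list()
  for (s in seq_along(sessions)) {
    att <- sessions[[s]]
    Y0 <- matrix(NA_real_, length(parts), k,
                 dimnames = list(parts, att))
    for (m in metrics) {
      Y <- Y0
      for (j in seq_along(att)) {
        idx <- match(paste(parts, att[j]),
                     paste(tbl$participant, tbl$attempt))
        Y[, j] <- tbl[[m]][idx]
      }
      r <- if (var(as.vector(Y)) == 0)
        list(p_time = 1, p_time_endo = 1, eps_hf = 1, F_time = 0, F_int = 0)
      else
        suppressWarnings(ranova_session(Y, group))
      res[[length(res) + 1L]] <- tibble::tibble(
        feature = m, session = s,
        p_time = r$p_time, p_time_endo = r$p_time_endo,
        eps_hf = r$eps_hf, F_time = r$F_time, F_int = r$F_int)
    }
  }
  out <- dplyr::bind_rows(res)
  if (!identical(adjust, "none")) {
    for (s in unique(out$session)) {
      i <- out$session == s
      out$p_time[i] <- stats::p.adjust(out$p_time[i], adjust)
      out$p_time_endo[i] <- stats::p.adjust(out$p_time_endo[i], adjust)
    }
  }
  out
}

#' Significance thresholds on the -log10 scale
#'
#' The three conventional thresholds p = 0.05, 0.01, 0.001 converted to
#' -log10 ticks: 1.3010, 2 and 3.
#'
#' @param thresholds P-value thresholds (proportions).
#' @return Named numeric of -log10 tick values.
#' @export
significance_ticks <- function(thresholds = c(0.05, 0.01, 0.001)) {
  stats::setNames(-log10(thresholds), format(thresholds, drop0trailing = TRUE))
}

#' Boxplot summaries of -log10 RANOVA p-values
#'
#' Per session and effect (time; time x endoscope), the -log10 p-value
#' distribution over features: quartiles, whiskers by the 1.5 IQR
#' convention, and named outliers beyond the whiskers.
#'
#' @param results Output of [ranova_table()].
#' @param thresholds Significance thresholds; reported as -log10 ticks.
#' @return List with `ticks` and `summaries`, a tibble of session, effect,
#'   boxplot statistics (`lower_whisker`, `q1`, `median`, `q3`,
#'   `upper_whisker`) and a list-column `outliers` (tibbles with `feature`,
#'   `neglog10_p`).
#' @export
neglog10_summary <- function(results, thresholds = c(0.05, 0.01, 0.001)) {
  abort_if(nrow(results) == 0, "empty results", "endoskill_ranova_error")
  effects <- c(time = "p_time", time_endo = "p_time_endo")
  rows <- list()
  for (s in sort(unique(results$session))) {
    for (e in names(effects)) {
      sub <- results[results$session == s, ]
      v <- -log10(sub[[effects[[e]]]])
      bs <- grDevices::boxplot.stats(v, coef = 1.5)
      out_idx <- which(v %in% bs$out)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        session = s, effect = e,
        lower_whisker = bs$stats[1], q1 = bs$stats[2],
        median = bs$stats[3], q3 = bs$stats[4],
        upper_whisker = bs$stats[5],
        outliers = list(tibble::tibble(feature = sub$feature[out_idx],
                                       neglog10_p = v[out_idx])))
    }
  }
  list(ticks = significance_ticks(thresholds),
       summaries = dplyr::bind_rows(rows))
}
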