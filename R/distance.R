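#' Element-pair distances between metric values
#'
#' For scalar metric values the Euclidean distance is `|a - b|`; the
#' Mahalanobis distance divides by the square root of a pooled scalar
#' variance, so it equals the Euclidean distance under unit pooled
#' variance and is invariant when both vectors are rescaled together.
#'
#' @param a,b Numeric values (vectorised).
#' @param pooled_var Positive pooled variance (Mahalanobis only).
#' @return Non-negative distances.
#' @export
pair_distance_euclidean <- function(a, b) abs(a - b)

#' @rdname pair_distance_euclidean
#' @export
pair_distance_mahalanobis <- function(a, b, pooled_var) {
  abort_if(!is.finite(pooled_var) || pooled_var <= 0,
           "pooled variance must be positive", "endoskill_distance_error")
  abs(a - b) / sqrt(pooled_var)
}

#' Median representative distance between two metric-specific vectors
#'
#' Computes the distance between every element of the 2D-group vector and
#' every element of the 3D-group vector (`length(v2d) * length(v3d)`
#' comparisons), sorts them ascending and returns the median (midpoint of
#' the central pair for even counts). For the Mahalanobis algorithm the
#' pooled variance is, by default, the variance of the two vectors'
#' concatenated values; pass `pooled_var` to override (e.g. row-vector-only
#' variance).
#'
#' @param v2d,v3d Non-empty numeric vectors: all attempts' values of one
#'   metric for the 2D and 3D endoscope group within one exercise.
#' @param algorithm `"euclidean"` or `"mahalanobis"`.
#' @param pooled_var Optional scalar variance for the Mahalanobis
#'   algorithm.
#' @return The representative distance; `NA` for a Mahalanobis cell with
#'   zero pooled variance.
#' @export
median_representative <- function(v2d, v3d,
                                  algorithm = c("euclidean", "mahalanobis"),
                                  pooled_var = NULL) {
  algorithm <- match.arg(algorithm)
  abort_if(length(v2d) == 0 || length(v3d) == 0,
           "metric-specific vectors must be non-empty",
           "endoskill_distance_error")
  d <- median(abs(outer(v2d, v3d, "-")))
  if (algorithm == "euclidean") return(d)
  pv <- pooled_var %||% var(c(v2d, v3d))
  if (!is.finite(pv) || pv <= 0) return(NA_real_)
  d / sqrt(pv)
}

#' Build the 2D-vs-3D distance maps for one exercise
#'
#' Collects, per metric, all attempts' values into one metric-specific
#' vector per endoscope group, then computes the representative (median)
#' distance for every ordered (2D metric, 3D metric) pair: 160 canonical
#' rows x 160 canonical columns = 25,600 cells, including cross-metric
#' cells. The four orientation metrics are carried alongside and enter the
#' reduced map as singletons. The reduced map averages cells by
#' affiliation (13 sEMG features over their 8 channels, 8 body parts over
#' their 7 MAPs, 4 orientation singletons); rows and columns of both maps
#' are ordered by descending mean. Distances are computed on raw feature
#' values by default; set `normalized = TRUE` to min-max normalise the
#' table first.
#'
#' @param tbl A `feature_table` (one exercise) containing both endoscope
#'   groups.
#' @param algorithm `"euclidean"` or `"mahalanobis"`.
#' @param normalized Min-max normalise features before measuring distances
#'   (default FALSE).
#' @return A `distance_map`: list with `full` (160 x 160, rows = 2D
#'   metrics, columns = 3D metrics), `extras` (rows/columns for the 4
#'   orientation metrics), `reduced` (affiliation-averaged, 25 x 25),
#'   `algorithm`.
#' @export
build_distance_maps <- function(tbl,
                                algorithm = c("euclidean", "mahalanobis"),
                                normalized = FALSE) {
  algorithm <- match.arg(algorithm)
  abort_if(!all(c("2D", "3D") %in% tbl$endoscope),
           "both endoscope groups must be present",
           "endoskill_distance_error")
  if (normalized) tbl <- normalize_minmax(tbl)
  tbl <- impute_features(tbl)

  metrics <- intersect(all_metrics(), names(tbl))
  v2 <- lapply(metrics, function(m) tbl[[m]][tbl$endoscope == "2D"])
  v3 <- lapply(metrics, function(m) tbl[[m]][tbl$endoscope == "3D"])
  names(v2) <- names(v3) <- metrics

  nm <- length(metrics)
  full <- matrix(NA_real_, nm, nm, dimnames = list(metrics, metrics))
  for (i in seq_len(nm)) {
    a <- v2[[i]]
    for (j in seq_len(nm)) {
      full[i, j] <- median_representative(a, v3[[j]], algorithm)
    }
  }

  aff_row <- metric_affiliation(rownames(full))
  aff_col <- metric_affiliation(colnames(full))
  affs <- unique(c(emg_feature_names(), imu_feature_names(),
                   body_part_names()))
  affs <- affs[affs %in% unique(c(aff_row, aff_col))]
  reduced <- matrix(NA_real_, length(affs), length(affs),
                    dimnames = list(affs, affs))
  for (i in seq_along(affs)) {
    ri <- aff_row == affs[i]
    for (j in seq_along(affs)) {
      reduced[i, j] <- mean(full[ri, aff_col == affs[j]], na.rm = TRUE)
    }
  }

  canon <- intersect(metrics, canonical_metrics())
  extra <- setdiff(metrics, canon)
  order_desc <- function(m) {
    rm <- rowMeans(m, na.rm = TRUE)
    cm <- colMeans(m, na.rm = TRUE)
    m[order(rm, decreasing = TRUE), order(cm, decreasing = TRUE),
      drop = FALSE]
  }
  structure(list(
    full = order_desc(full[canon, canon, drop = FALSE]),
    extras = list(rows = full[extra, , drop = FALSE],
                  cols = full[, extra, drop = FALSE]),
    reduced = order_desc(reduced),
    algorithm = algorithm,
    normalized = normalized
  ), class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  cat("<distance_map> ", x$algorithm,
      if (x$normalized) " (normalized features)" else " (raw features)",
      ": full ", nrow(x$full), "x", ncol(x$full),
      " (", length(x$full), " cells), reduced ",
      nrow(x$reduced), "x", ncol(x$reduced), "\n", sep = "")
  cat("top rows: ", paste(head(rownames(x$reduced), 3), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Plot a reduced distance map
#'
#' Heatmap of the affiliation-averaged distance map with rows and columns
#' in their descending-mean order (top row = largest mean distance).
#'
#' @param x A `distance_map`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.distance_map <- function(x, ...) {
  m <- x$reduced
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)),
                  t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  axes = FALSE, xlab = "3D metrics", ylab = "2D metrics",
                  main = paste("Median", x$algorithm, "distances"), ...)
  graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.6)
  graphics::axis(2, seq_len(nrow(m)), rev(rownames(m)), las = 2,
                 cex.axis = 0.6)
  invisible(x)
}
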