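test_that("pair distances follow their closed forms and symmetries", {
  expect_equal(pair_distance_euclidean(3, 1), 2)
  expect_equal(pair_distance_euclidean(4.2, 4.2), 0)
  expect_equal(pair_distance_mahalanobis(3, 1, 1),
               pair_distance_euclidean(3, 1))
  expect_equal(pair_distance_mahalanobis(7, 2, 4), 2.5)
  expect_error(pair_distance_mahalanobis(1, 2, 0),
               class = "endoskill_distance_error")
  set.seed(20)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(pair_distance_euclidean(a, b), pair_distance_euclidean(b, a))
})

test_that("median representative enumerates all pairs and takes the median", {
  expect_equal(median_representative(0, c(1, 3)), 2)
  expect_equal(median_representative(5, 5), 0)
  set.seed(21)
  for (i in 1:20) {
    v2 <- rnorm(7) * 3
    v3 <- rnorm(9) * 3 + 1
    expect_equal(median_representative(v2, v3),
                 oracle_median_representative(v2, v3))
  }
  expect_error(median_representative(numeric(0), 1),
               class = "endoskill_distance_error")
})

test_that("mahalanobis distances are invariant to common rescaling", {
  set.seed(22)
  v2 <- rnorm(8); v3 <- rnorm(10)
  d <- median_representative(v2, v3, "mahalanobis")
  for (c_ in c(0.1, 3, 250)) {
    expect_equal(median_representative(c_ * v2, c_ * v3, "mahalanobis"), d)
  }
  expect_true(is.na(median_representative(rep(1, 4), rep(1, 5),
                                          "mahalanobis")))
})

test_that("one extreme element cannot drag the median outside the bulk", {
  set.seed(23)
  v2 <- rnorm(5); v3 <- rnorm(5)
  clean_max <- max(abs(outer(v2, v3, "-")))
  v3_out <- v3; v3_out[1] <- 1e6
  expect_lte(median_representative(v2, v3_out), clean_max)
})

test_that("the full map covers all 25,600 canonical cells, ordered and >= 0", {
  tb <- small_tables()[[1]]
  m <- build_distance_maps(tb, "euclidean")
  expect_equal(dim(m$full), c(160, 160))
  expect_length(m$full, 25600)
  expect_true(all(m$full >= 0))
  expect_setequal(rownames(m$full), canonical_metrics())
  rm_ <- rowMeans(m$full)
  expect_false(is.unsorted(rev(rm_)))          # descending row means
  cm_ <- colMeans(m$full)
  expect_false(is.unsorted(rev(cm_)))
  expect_error(build_distance_maps(tb[tb$endoscope == "2D", ]),
               class = "endoskill_distance_error")
})

test_that("a cell equals the median over its two metric-specific vectors", {
  tb <- small_tables()[[1]]
  m <- build_distance_maps(tb, "euclidean")
  v2 <- tb$`V_RMS@ch1`[tb$endoscope == "2D"]
  v3 <- tb$`Trace@hand_r`[tb$endoscope == "3D"]
  expect_equal(m$full["V_RMS@ch1", "Trace@hand_r"],
               oracle_median_representative(v2, v3))
  mm <- build_distance_maps(tb, "mahalanobis")
  expect_equal(mm$full["V_RMS@ch1", "Trace@hand_r"],
               oracle_median_representative(v2, v3) / stats::sd(c(v2, v3)))
})

test_that("the map is invariant to permuting attempts within groups", {
  tb <- small_tables()[[1]]
  set.seed(24)
  perm <- unlist(lapply(c("2D", "3D"), function(g) sample(which(tb$endoscope == g))))
  m1 <- build_distance_maps(tb, "euclidean")
  m2 <- build_distance_maps(tb[perm, ], "euclidean")
  expect_equal(m1$full, m2$full)
})

test_that("reduced cells average their affiliation blocks", {
  tb <- small_tables()[[1]]
  m <- build_distance_maps(tb, "euclidean")
  expect_equal(dim(m$reduced), c(25, 25))
  expect_setequal(rownames(m$reduced),
                  c(emg_feature_names(), imu_feature_names(),
                    body_part_names()))
  rows <- paste0("V_Max@ch", 1:8)
  cols <- paste0(map_feature_names(), "@hand_r")
  expect_equal(m$reduced["V_Max", "hand_r"],
               mean(m$full[rows, intersect(cols, colnames(m$full))]))
  # orientation metrics enter as singletons through the extras block
  expect_equal(m$reduced["FES", "FES"],
               median_representative(tb$FES[tb$endoscope == "2D"],
                                     tb$FES[tb$endoscope == "3D"]))
  expect_false(is.unsorted(rev(rowMeans(m$reduced))))
})

test_that("diagonal mahalanobis cells equal euclidean on standardised values", {
  tb <- small_tables()[[1]]
  me <- build_distance_maps(tb, "euclidean")
  mm <- build_distance_maps(tb, "mahalanobis")
  for (metric in c("V_Max@ch2", "Velocity@hand_r", "f_Max@ch5")) {
    v2 <- tb[[metric]][tb$endoscope == "2D"]
    v3 <- tb[[metric]][tb$endoscope == "3D"]
    s <- stats::sd(c(v2, v3))
    expect_equal(mm$full[metric, metric], me$full[metric, metric] / s,
                 tolerance = 1e-12)
  }
})
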