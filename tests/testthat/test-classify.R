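# minimal synthetic feature table for classifier tests
toy_table <- function(n = 60, sep = 3, noise = 0.2, seed = 30) {
  withr::with_seed(seed, {
    y <- rep(c("2D", "3D"), each = n / 2)
    tibble::tibble(
      participant = sprintf("P%02d", rep(1:10, length.out = n)),
      endoscope = y,
      exercise = 1, attempt = rep(1:9, length.out = n),
      `V_Max@ch1` = (y == "2D") * sep + rnorm(n, sd = noise),
      `V_RMS@ch1` = (y == "2D") * sep + rnorm(n, sd = noise),
      `Trace@hand_r` = rnorm(n))
  })
}

test_that("fold assignment is stratified, seeded and learner-independent", {
  y <- factor(rep(c("2D", "3D"), c(45, 63)))
  f1 <- endoskill:::stratified_folds(y, 5, seed = 9)
  f2 <- endoskill:::stratified_folds(y, 5, seed = 9)
  expect_identical(f1, f2)
  expect_false(identical(f1, endoskill:::stratified_folds(y, 5, seed = 10)))
  counts <- table(f1, y)
  expect_lte(max(counts[, "2D"]) - min(counts[, "2D"]), 1)
  expect_lte(max(counts[, "3D"]) - min(counts[, "3D"]), 1)
})

test_that("a separable feature is classified perfectly by every margin learner", {
  tb <- normalize_minmax(toy_table(sep = 5, noise = 0.1))
  for (fam in c("svm-linear", "knn-fine", "tree", "bagged-trees"))
    expect_equal(train_eval(tb, fam, seed = 3), 100)
})

test_that("labels independent of features stay near chance", {
  tb <- normalize_minmax(toy_table(n = 100, sep = 0, noise = 1, seed = 31))
  acc <- train_eval(tb, "svm-linear", seed = 4)
  expect_gte(acc, 30)
  expect_lte(acc, 70)
})

test_that("accuracies are deterministic under a fixed seed", {
  tb <- normalize_minmax(toy_table(sep = 1, noise = 0.8))
  for (fam in c("svm-rbf-medium", "bagged-trees", "boosted-trees",
                "subspace-knn", "rus-boosted-trees", "knn-weighted")) {
    a1 <- train_eval(tb, fam, seed = 5)
    a2 <- train_eval(tb, fam, seed = 5)
    expect_identical(a1, a2)
  }
})

test_that("the learner roster covers the 18 families and all run", {
  roster <- learner_roster()
  expect_length(roster, 18)
  expect_setequal(
    names(roster),
    c("svm-linear", "svm-quadratic", "svm-cubic", "svm-rbf-fine",
      "svm-rbf-medium", "svm-rbf-coarse", "knn-fine", "knn-medium",
      "knn-coarse", "knn-cosine", "knn-cubic-metric", "knn-weighted",
      "tree", "bagged-trees", "boosted-trees", "subspace-discriminant",
      "subspace-knn", "rus-boosted-trees"))
  tb <- normalize_minmax(toy_table(sep = 2, noise = 0.5))
  accs <- vapply(roster, function(sp) train_eval(tb, sp, seed = 6),
                 numeric(1))
  expect_true(all(accs >= 0 & accs <= 100))
  # the very coarse k-NN collapses to the majority class: near 50 here
  expect_lt(accs[["knn-coarse"]], 70)
  expect_gt(accs[["svm-linear"]], 90)
})

test_that("top-distance selection keeps rows reaching the upper fraction", {
  metrics <- canonical_metrics()[1:6]
  m <- matrix(1, 6, 6, dimnames = list(metrics, metrics))
  m[3, ] <- 10                               # one dominant row
  fake <- structure(list(full = m, algorithm = "euclidean"),
                    class = "distance_map")
  expect_identical(select_top_distance(fake, 0.15), metrics[3])
  expect_setequal(select_top_distance(fake, 1), metrics)
  m_na <- matrix(NA_real_, 2, 2,
                 dimnames = list(metrics[1:2], metrics[1:2]))
  fake_na <- structure(list(full = m_na, algorithm = "euclidean"),
                       class = "distance_map")
  expect_warning(keep <- select_top_distance(fake_na, 0.15), "falling back")
  expect_setequal(keep, metrics[1:2])
})

test_that("selection on the effect cohort keeps the amplitude metrics", {
  sel <- select_top_distance(default_map_ex1(), 0.15)
  expect_true(any(grepl("^V_Range@", sel)))
  expect_true(any(grepl("^(V_Max|V_Min|V_Range)@", sel)))
  expect_lt(length(sel), 160)
})

test_that("permuting labels on the effect cohort destroys the signal", {
  tb <- impute_features(default_tables()[[1]])
  nt <- normalize_minmax(tb)
  expect_gte(train_eval(nt, "svm-linear", seed = 7), 90)
  perm <- withr::with_seed(8, sample(nrow(nt)))
  nt$endoscope <- nt$endoscope[perm]
  acc <- train_eval(nt, "svm-linear", seed = 7)
  expect_gte(acc, 30)
  expect_lte(acc, 70)
})

test_that("the report grid flags the best learner per column", {
  tabs <- list(exercise1 = small_tables()[[1]])
  roster <- learner_roster()[c("svm-linear", "knn-fine", "tree")]
  rep_ <- classification_report(tabs, roster = roster, seed = 11)
  expect_equal(nrow(rep_), 3 * 2)
  expect_setequal(unique(rep_$feature_set), c("all", "top15"))
  for (fs in c("all", "top15")) {
    sub <- rep_[rep_$feature_set == fs, ]
    expect_equal(sub$learner[sub$best], sub$learner[which.max(sub$accuracy)])
  }
  expect_true(all(rep_$n_features[rep_$feature_set == "all"] == 160))
  # dropping to the top-distance subset costs at most ~15 accuracy points
  # on an effect cohort
  best <- tapply(rep_$accuracy, rep_$feature_set, max)
  expect_gte(best[["all"]], best[["top15"]] - 15)
})
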