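# Learner roster and fit/predict wrappers. Hyperparameters follow the
# Matlab classification-toolbox naming conventions (fine/medium/coarse =
# kernel-scale or neighbourhood granularity); all are overridable through
# learner_spec(). Every wrapper takes a numeric matrix X (rows = attempts,
# min-max-normalised features) and a 2-level factor y, and returns a
# prediction function for new rows.

#' Learner specification
#'
#' @param family One of the roster families (see [learner_roster()]).
#' @param ... Hyperparameter overrides (e.g. `cost`, `k`, `ntree`).
#' @return A `learner_spec` list with completed per-family defaults.
#' @export
learner_spec <- function(family, ...) {
  defaults <- learner_defaults()
  abort_if(!family %in% names(defaults),
           paste0("unknown learner family: ", family),
           "endoskill_classify_error")
  hp <- utils::modifyList(defaults[[family]], list(...))
  structure(list(family = family, hyperparameters = hp),
            class = "learner_spec")
}

learner_defaults <- function() {
  list(
    "svm-linear"    = list(kernel = "linear", cost = 1),
    "svm-quadratic" = list(kernel = "polynomial", degree = 2, cost = 1),
    "svm-cubic"     = list(kernel = "polynomial", degree = 3, cost = 1),
    "svm-rbf-fine"    = list(kernel = "radial", scale_factor = 0.25, cost = 1),
    "svm-rbf-medium"  = list(kernel = "radial", scale_factor = 1, cost = 1),
    "svm-rbf-coarse"  = list(kernel = "radial", scale_factor = 4, cost = 1),
    "knn-fine"       = list(k = 1, metric = "euclidean", weighted = FALSE),
    "knn-medium"     = list(k = 10, metric = "euclidean", weighted = FALSE),
    "knn-coarse"     = list(k = 100, metric = "euclidean", weighted = FALSE),
    "knn-cosine"     = list(k = 10, metric = "cosine", weighted = FALSE),
    "knn-cubic-metric" = list(k = 10, metric = "minkowski3", weighted = FALSE),
    "knn-weighted"   = list(k = 10, metric = "euclidean", weighted = TRUE),
    "tree"           = list(maxdepth = 30, cp = 0.01),
    "bagged-trees"   = list(ntree = 100),
    "boosted-trees"  = list(nrounds = 30, max_depth = 3, eta = 0.1),
    "subspace-discriminant" = list(n_learners = 30, dim_fraction = 0.5),
    "subspace-knn"   = list(n_learners = 30, dim_fraction = 0.5, k = 1),
    "rus-boosted-trees" = list(n_learners = 30, maxdepth = 2)
  )
}

#' The full learner roster
#'
#' The 18 classifier families evaluated for endoscope-type prediction:
#' six SVMs (linear, quadratic, cubic, fine/medium/coarse Gaussian), six
#' k-NN variants (fine, medium, coarse, cosine, cubic-metric, weighted),
#' a decision tree, and five ensembles (bagged trees, boosted trees,
#' subspace discriminant, subspace k-NN, RUS-boosted trees).
#'
#' @return Named list of `learner_spec`s.
#' @export
learner_roster <- function() {
  fams <- names(learner_defaults())
  stats::setNames(lapply(fams, learner_spec), fams)
}

fit_learner <- function(spec, X, y) {
  hp <- spec$hyperparameters
  fam <- spec$family
  if (startsWith(fam, "svm-")) return(fit_svm(hp, X, y))
  if (startsWith(fam, "knn-")) return(fit_knn(hp, X, y))
  switch(fam,
         "tree" = fit_tree(hp, X, y),
         "bagged-trees" = fit_bagged(hp, X, y),
         "boosted-trees" = fit_boosted(hp, X, y),
         "subspace-discriminant" = fit_subspace(hp, X, y, base = "lda"),
         "subspace-knn" = fit_subspace(hp, X, y, base = "knn"),
         "rus-boosted-trees" = fit_rusboost(hp, X, y),
         abort_if(TRUE, paste0("unknown family ", fam),
                  "endoskill_classify_error"))
}

fit_svm <- function(hp, X, y) {
  p <- ncol(X)
  args <- list(x = X, y = y, cost = hp$cost, kernel = hp$kernel,
               scale = FALSE)
  if (hp$kernel == "polynomial") {
    args$degree <- hp$degree; args$gamma <- 1 / p; args$coef0 <- 1
  }
  if (hp$kernel == "radial") {
    sigma <- hp$scale_factor * sqrt(p)     # Matlab-style kernel scale
    args$gamma <- 1 / sigma^2
  }
  fit <- do.call(e1071::svm, args)
  function(Xn) predict(fit, Xn)
}

fit_knn <- function(hp, X, y) {
  k <- min(hp$k, nrow(X))
  metric <- hp$metric
  weighted <- isTRUE(hp$weighted)
  function(Xn) knn_predict(X, y, Xn, k, metric, weighted)
}

# one code path for all k-NN variants so folds and tie-breaks are identical
knn_predict <- function(X, y, Xn, k, metric, weighted) {
  D <- switch(metric,
    euclidean = {
      cross <- tcrossprod(Xn, X)
      sq <- outer(rowSums(Xn^2), rowSums(X^2), "+") - 2 * cross
      sqrt(pmax(sq, 0))
    },
    minkowski3 = {
      t(apply(Xn, 1, function(r)
        colSums(abs(t(X) - r)^3)^(1 / 3)))
    },
    cosine = {
      nx <- sqrt(rowSums(Xn^2)); nx[nx == 0] <- 1
      nt <- sqrt(rowSums(X^2)); nt[nt == 0] <- 1
      1 - tcrossprod(Xn / nx, X / nt)
    },
    abort_if(TRUE, paste0("unknown metric ", metric),
             "endoskill_classify_error"))
  if (is.null(dim(D))) D <- matrix(D, nrow = nrow(Xn))
  lev <- levels(y)
  pred <- apply(D, 1, function(d) {
    o <- order(d)[seq_len(k)]
    w <- if (weighted) 1 / pmax(d[o], 1e-8)^2 else rep(1, k)
    scores <- vapply(lev, function(l) sum(w[y[o] == l]), numeric(1))
    lev[which.max(scores)]
  })
  factor(pred, levels = lev)
}

fit_tree <- function(hp, X, y) {
  df <- data.frame(.y = y, X, check.names = FALSE)
  fit <- rpart::rpart(.y ~ ., df, method = "class",
                      control = rpart::rpart.control(maxdepth = hp$maxdepth,
                                                     cp = hp$cp))
  function(Xn) predict(fit, data.frame(Xn, check.names = FALSE),
                       type = "class")
}

fit_bagged <- function(hp, X, y) {
  fit <- randomForest::randomForest(X, y, ntree = hp$ntree)
  function(Xn) predict(fit, Xn)
}

fit_boosted <- function(hp, X, y) {
  lev <- levels(y)
  dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(y) - 1)
  fit <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                  eta = hp$eta, nthread = 1),
    data = dtrain, nrounds = hp$nrounds, verbose = 0)
  function(Xn) factor(lev[1 + (predict(fit, xgboost::xgb.DMatrix(Xn)) > 0.5)],
                      levels = lev)
}

# random-subspace ensemble (majority vote) over LDA or 1-NN base learners
fit_subspace <- function(hp, X, y, base) {
  p <- ncol(X)
  d <- max(1L, floor(hp$dim_fraction * p))
  lev <- levels(y)
  members <- lapply(seq_len(hp$n_learners), function(i) {
    cols <- sample.int(p, d)
    Xi <- X[, cols, drop = FALSE]
    if (base == "lda") {
      keep <- which(apply(Xi, 2, var) > 0)
      if (!length(keep)) keep <- 1L
      cols <- cols[keep]
      Xi <- X[, cols, drop = FALSE]
      fit <- tryCatch(suppressWarnings(MASS::lda(Xi, y)),
                      error = function(e) NULL)
      pred <- if (is.null(fit)) {
        maj <- lev[which.max(tabulate(y))]
        function(Z) factor(rep(maj, nrow(Z)), levels = lev)
      } else {
        function(Z) predict(fit, Z)$class
      }
    } else {
      pred <- function(Z) knn_predict(Xi, y, Z, min(hp$k, nrow(Xi)),
                                      "euclidean", FALSE)
    }
    list(cols = cols, predict = pred)
  })
  function(Xn) {
    votes <- vapply(members, function(m)
      as.character(m$predict(Xn[, m$cols, drop = FALSE])),
      character(nrow(Xn)))
    votes <- matrix(votes, nrow = nrow(Xn))
    factor(apply(votes, 1, function(v)
      names(which.max(table(factor(v, levels = lev))))), levels = lev)
  }
}

# AdaBoost.M1 with shallow trees, each round trained on a random
# undersampled class-balanced draw from the boosting weights (RUS)
fit_rusboost <- function(hp, X, y) {
  n <- nrow(X)
  lev <- levels(y)
  w <- rep(1 / n, n)
  members <- list()
  n_min <- min(table(y))
  df_all <- data.frame(X, check.names = FALSE)
  for (m in seq_len(hp$n_learners)) {
    idx <- unlist(lapply(lev, function(l) {
      pool <- which(y == l)
      pr <- w[pool] / sum(w[pool])
      sample(pool, min(n_min, length(pool)), replace = TRUE, prob = pr)
    }))
    df <- data.frame(.y = y[idx], X[idx, , drop = FALSE],
                     check.names = FALSE)
    fit <- rpart::rpart(.y ~ ., df, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = hp$maxdepth, cp = 0, minsplit = 2))
    pred_all <- predict(fit, df_all, type = "class")
    err <- sum(w * (pred_all != y)) / sum(w)
    if (err >= 0.5 || err <= 0) {
      if (err <= 0) members[[length(members) + 1L]] <-
          list(fit = fit, alpha = 3)
      next
    }
    alpha <- 0.5 * log((1 - err) / err)
    members[[length(members) + 1L]] <- list(fit = fit, alpha = alpha)
    w <- w * exp(alpha * ifelse(pred_all != y, 1, -1))
    w <- w / sum(w)
  }
  if (!length(members)) {
    maj <- lev[which.max(tabulate(y))]
    return(function(Xn) factor(rep(maj, nrow(Xn)), levels = lev))
  }
  function(Xn) {
    dfn <- data.frame(Xn, check.names = FALSE)
    score <- numeric(nrow(Xn))
    for (m in members) {
      p <- predict(m$fit, dfn, type = "class")
      score <- score + m$alpha * ifelse(p == lev[2], 1, -1)
    }
    factor(lev[1 + (score > 0)], levels = lev)
  }
}
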