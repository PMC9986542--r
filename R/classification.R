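# Multi-class tumor-entity classification: SMOTE balancing, repeated
# stratified cross-validation over a model zoo, and aggregated confusion
# summaries with per-class one-vs-rest sensitivity and specificity.

MODEL_ZOO <- c("lda", "logistic", "knn", "svc", "gboost", "rf", "xtrees")

#' Feature table of a cohort
#'
#' @param cohort Cohort `data.frame`.
#' @return List with `features` (n x 3 matrix: `tau_ns`, `redox_ratio`,
#'   `r_flavin`), `labels` (factor) and `ids`.
#' @export
feature_table <- function(cohort) {
  features <- as.matrix(cohort[, c("tau_ns", "redox_ratio", "r_flavin")])
  if (any(!is.finite(features))) stop("feature table contains non-finite values")
  labels <- factor(as.character(cohort$group),
                   levels = intersect(GROUP_LEVELS, unique(cohort$group)))
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  list(features = features, labels = labels,
       ids = cohort$sample_id %||% as.character(seq_len(nrow(features))))
}

#' SMOTE: synthetic minority oversampling
#'
#' Augments every minority class up to the majority-class count with
#' synthetic rows `x + u * (x_nn - x)`, `u ~ Uniform(0, 1)`, where `x_nn`
#' is one of the `k_neighbors` within-class nearest neighbors (Euclidean)
#' of a class member. Intended for training folds only. Uses the current
#' RNG state.
#'
#' @param x Numeric feature matrix.
#' @param y Factor of class labels.
#' @param k_neighbors Number of neighbors considered (capped at class
#'   size - 1).
#' @return List with `x`, `y` and logical `synthetic` marking added rows.
#' @export
smote_augment <- function(x, y, k_neighbors = 5) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- droplevels(as.factor(y))
  counts <- table(y)
  target <- max(counts)
  x_new <- list()
  y_new <- list()
  for (cl in names(counts)) {
    deficit <- target - counts[[cl]]
    if (deficit == 0) next
    if (counts[[cl]] < 2) {
      stop("SMOTE needs at least 2 members in class ", cl)
    }
    xc <- x[y == cl, , drop = FALSE]
    k <- min(k_neighbors, nrow(xc) - 1)
    d <- as.matrix(stats::dist(xc))
    diag(d) <- Inf
    nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
    base_idx <- rep_len(seq_len(nrow(xc)), deficit)
    pick <- nn[cbind(base_idx, sample.int(k, deficit, replace = TRUE))]
    u <- stats::runif(deficit)
    synth <- xc[base_idx, , drop = FALSE] +
      u * (xc[pick, , drop = FALSE] - xc[base_idx, , drop = FALSE])
    x_new[[cl]] <- synth
    y_new[[cl]] <- rep(cl, deficit)
  }
  if (length(x_new) == 0) {
    return(list(x = x, y = y, synthetic = rep(FALSE, nrow(x))))
  }
  x_aug <- rbind(x, do.call(rbind, x_new))
  y_aug <- factor(c(as.character(y), unlist(y_new)), levels = levels(y))
  list(x = x_aug, y = y_aug,
       synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, nrow(x_aug) - nrow(x))))
}

#' Stratified fold assignment
#'
#' Shuffles each class and deals it round-robin across folds, so per-fold
#' class counts differ by at most one from proportionality. Uses the
#' current RNG state.
#'
#' @param y Factor of class labels.
#' @param k Number of folds.
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(y, k) {
  y <- as.factor(y)
  if (any(table(y) < k)) {
    stop("every class needs at least as many members as folds")
  }
  fold <- integer(length(y))
  offset <- 0L
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx) %% k
  }
  fold
}

# Fit one zoo member on (x, y) and predict classes for x_test. Features are
# expected pre-scaled. Sub-RNG use keeps determinism tied to the caller's
# seed.
fit_predict_model <- function(model, x, y, x_test) {
  lv <- levels(y)
  pred <- switch(
    model,
    lda = {
      fit <- MASS::lda(x, grouping = y)
      as.character(stats::predict(fit, x_test)$class)
    },
    logistic = {
      df <- data.frame(y = y, x)
      fit <- nnet::multinom(y ~ ., data = df, trace = FALSE, maxit = 300)
      as.character(stats::predict(fit, data.frame(x_test)))
    },
    knn = as.character(class::knn(x, x_test, cl = y, k = 5)),
    svc = {
      fit <- e1071::svm(x, y, kernel = "radial", cost = 1, scale = FALSE)
      as.character(stats::predict(fit, x_test))
    },
    gboost = {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
      fit <- xgboost::xgb.train(
        params = list(objective = "multi:softmax",
                      num_class = length(lv),
                      max_depth = 3, eta = 0.3, nthread = 1),
        data = dtrain, nrounds = 60, verbose = 0
      )
      lv[stats::predict(fit, xgboost::xgb.DMatrix(x_test)) + 1L]
    },
    rf = {
      fit <- randomForest::randomForest(x, y, ntree = 200)
      as.character(stats::predict(fit, x_test))
    },
    xtrees = {
      fit <- ranger::ranger(x = x, y = y, num.trees = 200,
                            splitrule = "extratrees",
                            num.random.splits = 1,
                            seed = sample.int(.Machine$integer.max, 1),
                            num.threads = 1)
      as.character(stats::predict(fit, data = x_test,
                                  num.threads = 1)$predictions)
    },
    stop("unknown model: ", model)
  )
  factor(pred, levels = lv)
}

#' Repeated stratified cross-validation with in-fold SMOTE
#'
#' For each repeat a fresh stratified `n_folds` partition is drawn; within
#' each validation the training split is z-scored (training statistics
#' only), SMOTE-balanced, the model fitted, and the untouched validation
#' split predicted. Every sample is predicted exactly once per repeat;
#' results are deterministic under `seed`.
#'
#' @param features Numeric matrix (n x p).
#' @param labels Factor of class labels (every class must have at least
#'   `n_folds` members).
#' @param ids Sample identifiers.
#' @param model Zoo member (`"lda"`, `"logistic"`, `"knn"`, `"svc"`,
#'   `"gboost"`, `"rf"`, `"xtrees"`). The support-vector model is the
#'   reporting default.
#' @param n_folds,n_repeats Cross-validation plan (default 5 x 50).
#' @param seed Integer seed driving per-repeat sub-seeds.
#' @param smote Apply SMOTE inside training folds (default `TRUE`).
#' @param k_neighbors SMOTE neighbor count.
#' @return `data.frame` of per-validation predictions with columns
#'   `repeat_id`, `fold`, `id`, `truth`, `pred`.
#' @export
repeated_stratified_cv <- function(features, labels, ids = NULL,
                                   model = "svc", n_folds = 5,
                                   n_repeats = 50, seed = 1L,
                                   smote = TRUE, k_neighbors = 5) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  model <- match.arg(model, MODEL_ZOO)
  labels <- droplevels(as.factor(labels))
  if (any(table(labels) < n_folds)) {
    stop("every class needs at least `n_folds` members")
  }
  ids <- ids %||% as.character(seq_len(nrow(features)))
  out <- vector("list", n_repeats * n_folds)
  slot <- 1L
  for (r in seq_len(n_repeats)) {
    set.seed(derive_seed(seed, 1000L + r))
    fold <- stratified_folds(labels, n_folds)
    for (f in seq_len(n_folds)) {
      test_idx <- which(fold == f)
      train_idx <- which(fold != f)
      mu <- colMeans(features[train_idx, , drop = FALSE])
      sd_ <- apply(features[train_idx, , drop = FALSE], 2, stats::sd)
      sd_[sd_ <= 0] <- 1
      x_train <- sweep(sweep(features[train_idx, , drop = FALSE], 2, mu), 2, sd_, "/")
      x_test <- sweep(sweep(features[test_idx, , drop = FALSE], 2, mu), 2, sd_, "/")
      y_train <- labels[train_idx]
      if (smote) {
        aug <- smote_augment(x_train, y_train, k_neighbors)
        x_train <- aug$x
        y_train <- aug$y
      }
      pred <- fit_predict_model(model, x_train, y_train, x_test)
      out[[slot]] <- data.frame(
        repeat_id = r, fold = f, id = ids[test_idx],
        truth = as.character(labels[test_idx]), pred = as.character(pred),
        stringsAsFactors = FALSE
      )
      slot <- slot + 1L
    }
  }
  res <- do.call(rbind, out)
  res$truth <- factor(res$truth, levels = levels(labels))
  res$pred <- factor(res$pred, levels = levels(labels))
  attr(res, "model") <- model
  attr(res, "n_folds") <- n_folds
  attr(res, "n_repeats") <- n_repeats
  attr(res, "n_models") <- n_repeats * n_folds
  res
}

#' Macro-averaged F-score of a prediction set
#'
#' Mean over classes of the per-class F1 (harmonic mean of one-vs-rest
#' precision and recall; classes with no true or predicted members score
#' 0).
#'
#' @param predictions Prediction `data.frame` from
#'   [repeated_stratified_cv()].
#' @return Macro F-score in `[0, 1]`.
#' @export
macro_f_score <- function(predictions) {
  counts <- table(truth = predictions$truth, pred = predictions$pred)
  f1 <- vapply(seq_len(nrow(counts)), function(i) {
    tp <- counts[i, i]
    prec_den <- sum(counts[, i])
    rec_den <- sum(counts[i, ])
    if (tp == 0) return(0)
    prec <- tp / prec_den
    rec <- tp / rec_den
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  mean(f1)
}

#' Evaluate the full model zoo
#'
#' Runs the repeated stratified CV protocol for every zoo member and ranks
#' models by macro F-score. The support-vector model is the reporting
#' default regardless of rank.
#'
#' @inheritParams repeated_stratified_cv
#' @param models Zoo members to evaluate.
#' @return `data.frame` with `model` and `macro_f`, sorted descending;
#'   per-model predictions in attribute `"predictions"`.
#' @export
model_zoo_evaluate <- function(features, labels, ids = NULL,
                               models = MODEL_ZOO, n_folds = 5,
                               n_repeats = 50, seed = 1L, smote = TRUE) {
  preds <- lapply(models, function(m) {
    repeated_stratified_cv(features, labels, ids, model = m,
                           n_folds = n_folds, n_repeats = n_repeats,
                           seed = seed, smote = smote)
  })
  names(preds) <- models
  ranking <- data.frame(model = models,
                        macro_f = vapply(preds, macro_f_score, numeric(1)))
  ranking <- ranking[order(-ranking$macro_f), ]
  rownames(ranking) <- NULL
  attr(ranking, "predictions") <- preds
  attr(ranking, "reporting_model") <- "svc"
  ranking
}

#' Aggregate a confusion summary over all validations
#'
#' Prediction counts summed over every validation run, row-normalized
#' detection probabilities, and per-class one-vs-rest sensitivity
#' `SE = TP / (TP + FN)` and specificity `SP = TN / (TN + FP)` in percent.
#'
#' @param predictions Prediction `data.frame` from
#'   [repeated_stratified_cv()] (non-empty).
#' @return Object of class `confusion_summary` with fields `counts`
#'   (K x K, rows = truth), `detection_prob`, `se_percent`, `sp_percent`
#'   and `total`.
#' @export
aggregate_confusion <- function(predictions) {
  if (is.null(predictions) || nrow(predictions) == 0) {
    stop("empty prediction set")
  }
  counts <- table(truth = predictions$truth, pred = predictions$pred)
  counts <- unclass(counts)
  total <- sum(counts)
  se <- 100 * diag(counts) / rowSums(counts)
  tn <- vapply(seq_len(nrow(counts)), function(i) {
    total - sum(counts[i, ]) - sum(counts[, i]) + counts[i, i]
  }, numeric(1))
  fp <- colSums(counts) - diag(counts)
  sp <- 100 * tn / (tn + fp)
  structure(list(counts = counts,
                 detection_prob = counts / rowSums(counts),
                 se_percent = stats::setNames(se, rownames(counts)),
                 sp_percent = stats::setNames(sp, rownames(counts)),
                 total = total),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("Aggregated confusion matrix (rows = truth,", x$total, "predictions)\n")
  tab <- cbind(x$counts,
               `SE%` = round(x$se_percent, 1),
               `SP%` = round(x$sp_percent, 1))
  print(tab)
  invisible(x)
}
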