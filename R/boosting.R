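#' Discrete AdaBoost with decision stumps
#'
#' Classic discrete AdaBoost: per round a depth-1 decision stump is fit on
#' weighted data, its vote weight is `a_i = 0.5 * log((1 - err) / err)`, and
#' misclassified samples are up-weighted. Training stops early when a round
#' reaches weighted error 0 (the stump is kept with a capped weight) or can
#' do no better than 0.5. The ensemble predicts by the sign of the weighted
#' stump sum.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y binary labels (0/1 or -1/+1); both classes must be present.
#' @param n_rounds maximum boosting rounds (default 100).
#' @return An `adaboost_model`: `stumps` (feature, threshold, polarity per
#'   round), `alphas`, `n_rounds`.
#' @export
train_adaboost <- function(x, y, n_rounds = 100) {
  x <- as.matrix(x)
  y <- ifelse(y > 0, 1, -1)
  if (length(unique(y)) < 2) stop("both classes must be present")
  n <- nrow(x)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  for (r in seq_len(n_rounds)) {
    st <- .fit_stump(x, y, w)
    pred <- .stump_predict(st, x)
    err <- sum(w[pred != y])
    if (err >= 0.5) break
    a <- if (err == 0) 0.5 * log((1 - 1e-10) / 1e-10) else
      0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- st
    alphas <- c(alphas, a)
    if (err == 0) break
    w <- w * exp(-a * y * pred)
    w <- w / sum(w)
  }
  structure(list(stumps = stumps, alphas = alphas,
                 n_rounds = length(alphas)),
            class = "adaboost_model")
}

# Best weighted-error stump over all features, thresholds and polarities.
# polarity +1 predicts +1 where x > threshold; -1 flips.
.fit_stump <- function(x, y, w) {
  best <- list(err = Inf)
  for (f in seq_len(ncol(x))) {
    o <- order(x[, f])
    xv <- x[o, f]; yv <- y[o]; wv <- w[o]
    # err(threshold between j and j+1, polarity +1)
    #   = sum w[y==+1, below] + sum w[y==-1, above]
    below_pos <- cumsum(wv * (yv == 1))
    below_neg <- cumsum(wv * (yv == -1))
    tot_neg <- below_neg[length(below_neg)]
    cand <- which(diff(xv) > 0)         # thresholds between distinct values
    errs_pos <- c(tot_neg, below_pos[cand] + (tot_neg - below_neg[cand]))
    thr <- c(xv[1] - 1, (xv[cand] + xv[cand + 1]) / 2)
    j_pos <- which.min(errs_pos)
    if (errs_pos[j_pos] < best$err)
      best <- list(feature = f, threshold = thr[j_pos], polarity = 1,
                   err = errs_pos[j_pos])
    j_neg <- which.max(errs_pos)
    if (1 - errs_pos[j_neg] < best$err)
      best <- list(feature = f, threshold = thr[j_neg], polarity = -1,
                   err = 1 - errs_pos[j_neg])
  }
  best[c("feature", "threshold", "polarity")]
}

.stump_predict <- function(st, x) {
  st$polarity * ifelse(x[, st$feature] > st$threshold, 1, -1)
}

#' @rdname train_adaboost
#' @param model an `adaboost_model`.
#' @param type `"score"` for probabilities in `[0, 1]` (logistic transform
#'   of the margin), `"margin"` for the raw weighted sum, `"class"` for
#'   -1/+1.
#' @export
predict_adaboost <- function(model, x, type = c("score", "margin", "class")) {
  type <- match.arg(type)
  x <- as.matrix(x)
  margin <- rep(0, nrow(x))
  for (i in seq_along(model$stumps))
    margin <- margin + model$alphas[i] * .stump_predict(model$stumps[[i]], x)
  switch(type,
         margin = margin,
         class = ifelse(margin >= 0, 1, -1),
         score = 1 / (1 + exp(-2 * margin)))
}

#' Regularized gradient-boosted trees
#'
#' Boosted trees minimizing the logistic loss plus the per-tree regularizer
#' `gamma * M + (lambda / 2) * sum_j w_j^2` over `M` leaves with weights
#' `w_j`; each leaf takes the penalized Newton step `w = -G / (H + lambda)`
#' from the leaf's gradient and Hessian sums. Backed by
#' \pkg{xgboost} (`binary:logistic`, loss-guided growth with a leaf cap),
#' whose training objective is exactly this penalized second-order
#' formulation.
#'
#' @param x numeric feature matrix.
#' @param y binary 0/1 labels; both classes must be present.
#' @param params a [gradboost_params()].
#' @return A `gradboost_model` wrapping the fitted booster.
#' @export
train_gradient_boosting <- function(x, y, params = gradboost_params()) {
  x <- as.matrix(x)
  y <- as.integer(y > 0)
  if (length(unique(y)) < 2) stop("both classes must be present")
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  eta = params$learning_rate,
                  tree_method = "hist",
                  grow_policy = "lossguide",
                  max_depth = 0,
                  max_leaves = params$max_leaves,
                  gamma = params$leaf_penalty,
                  lambda = params$l2_penalty,
                  base_score = 0.5,
                  nthread = 1),
    data = dtrain, nrounds = params$n_rounds, verbose = 0)
  structure(list(booster = booster, params = params),
            class = "gradboost_model")
}

#' @rdname train_gradient_boosting
#' @param model a `gradboost_model`.
#' @export
predict_gradboost <- function(model, x) {
  stats::predict(model$booster, xgboost::xgb.DMatrix(as.matrix(x),
                                                     nthread = 1))
}

#' Gradient-boosting hyperparameters
#'
#' @param n_rounds boosting rounds.
#' @param learning_rate shrinkage per round.
#' @param max_leaves leaf cap `M` per tree.
#' @param leaf_penalty `gamma`, cost per leaf.
#' @param l2_penalty `lambda`, L2 penalty on leaf weights.
#' @return A `gradboost_params` list.
#' @export
gradboost_params <- function(n_rounds = 100, learning_rate = 0.3,
                             max_leaves = 8, leaf_penalty = 0,
                             l2_penalty = 1) {
  if (l2_penalty < 0 || leaf_penalty < 0 || max_leaves < 1)
    stop("invalid gradient-boosting parameters")
  list(n_rounds = n_rounds, learning_rate = learning_rate,
       max_leaves = max_leaves, leaf_penalty = leaf_penalty,
       l2_penalty = l2_penalty)
}

#' Penalized Newton leaf weight
#'
#' The closed-form optimal leaf weight `-G / (H + lambda)` for gradient sum
#' `G`, Hessian sum `H` and L2 penalty `lambda` — the step every leaf of the
#' boosted trees takes.
#'
#' @param G,H gradient and Hessian sums over the leaf's samples.
#' @param lambda L2 penalty.
#' @return The leaf weight.
#' @export
gbt_leaf_weight <- function(G, H, lambda) -G / (H + lambda)

#' Confusion-matrix metrics and AUC
#'
#' Accuracy, sensitivity (`TP / (TP + FN)`, cases positive), specificity
#' (`TN / (TN + FP)`) at a score threshold, and the threshold-free AUC by
#' the rank (Mann-Whitney) statistic with ties counted 0.5.
#'
#' @param y_true binary 0/1 labels.
#' @param scores numeric scores in `[0, 1]`.
#' @param threshold classification threshold (default 0.5).
#' @return List with `accuracy`, `sensitivity`, `specificity`, `auc` (`NA`
#'   with a warning if only one class is present).
#' @export
compute_metrics <- function(y_true, scores, threshold = 0.5) {
  y_true <- as.integer(y_true > 0)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y_true == 1)
  tn <- sum(pred == 0 & y_true == 0)
  fp <- sum(pred == 1 & y_true == 0)
  fn <- sum(pred == 0 & y_true == 1)
  npos <- tp + fn; nneg <- tn + fp
  auc <- if (npos == 0 || nneg == 0) {
    warning("AUC undefined: only one class present")
    NA_real_
  } else {
    r <- rank(scores)  # midranks handle ties as 0.5
    (sum(r[y_true == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  }
  list(accuracy = (tp + tn) / length(y_true),
       sensitivity = if (npos > 0) tp / npos else NA_real_,
       specificity = if (nneg > 0) tn / nneg else NA_real_,
       auc = auc)
}

#' Stratified fold assignment
#'
#' Shuffles each class independently and deals it round-robin into `k`
#' folds, so per-fold class counts differ by at most one (exactly equal
#' when divisible, e.g. 20 positives over 10 folds gives 2 per fold).
#'
#' @param y binary labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer fold id (1..k) per sample.
#' @export
stratified_folds <- function(y, k = 10, seed = 1) {
  y <- as.integer(y > 0)
  if (min(table(y)) < k)
    stop("a class has fewer than k members; use a smaller k")
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repeat a fresh stratified shuffle (seed derived from `seed` and
#' the repeat index); per fold the model is trained on the remainder and
#' scored on the fold; metrics are averaged over folds x repeats and ROC
#' points are built from the pooled per-fold scores.
#'
#' @param x feature matrix.
#' @param y binary 0/1 labels (cases = 1).
#' @param model_spec `"adaboost"` or `"gradboost"`, or a list
#'   `list(train = function(x, y), predict = function(model, x))`.
#' @param k folds (default 10).
#' @param repeats repeats (default 10).
#' @param seed master seed.
#' @param adaboost_rounds,gb_params hyperparameters for the built-in specs.
#' @return An `evaluation_report`: `metrics` (mean and sd of accuracy /
#'   sensitivity / specificity / auc over folds x repeats), `fold_metrics`
#'   (long data frame), `roc` (pooled ROC points), `k`, `repeats`, `seed`.
#' @export
repeated_stratified_cv <- function(x, y, model_spec = "adaboost", k = 10,
                                   repeats = 10, seed = 1,
                                   adaboost_rounds = 100,
                                   gb_params = gradboost_params()) {
  x <- as.matrix(x)
  y <- as.integer(y > 0)
  spec <- if (is.list(model_spec)) model_spec
  else switch(model_spec,
              adaboost = list(
                train = function(x, y) train_adaboost(x, y, adaboost_rounds),
                predict = predict_adaboost),
              gradboost = list(
                train = function(x, y) train_gradient_boosting(x, y, gb_params),
                predict = predict_gradboost),
              stop("unknown model_spec: ", model_spec))
  rows <- list()
  pooled_scores <- numeric(0)
  pooled_y <- integer(0)
  for (rep_i in seq_len(repeats)) {
    folds <- stratified_folds(y, k, derive_seed(seed, 100L + rep_i))
    for (f in seq_len(k)) {
      test <- folds == f
      model <- spec$train(x[!test, , drop = FALSE], y[!test])
      sc <- spec$predict(model, x[test, , drop = FALSE])
      m <- suppressWarnings(compute_metrics(y[test], sc))
      rows[[length(rows) + 1L]] <-
        data.frame(repeat_i = rep_i, fold = f,
                   accuracy = m$accuracy, sensitivity = m$sensitivity,
                   specificity = m$specificity, auc = m$auc)
      pooled_scores <- c(pooled_scores, sc)
      pooled_y <- c(pooled_y, y[test])
    }
  }
  fold_metrics <- do.call(rbind, rows)
  summ <- function(col) c(mean = mean(fold_metrics[[col]], na.rm = TRUE),
                          sd = stats::sd(fold_metrics[[col]], na.rm = TRUE))
  metrics <- sapply(c("accuracy", "sensitivity", "specificity", "auc"), summ)
  thr <- sort(unique(c(-Inf, pooled_scores, Inf)), decreasing = TRUE)
  roc <- t(vapply(thr, function(t) {
    c(fpr = mean(pooled_scores[pooled_y == 0] >= t),
      tpr = mean(pooled_scores[pooled_y == 1] >= t))
  }, c(fpr = 0, tpr = 0)))
  structure(list(metrics = metrics, fold_metrics = fold_metrics,
                 roc = as.data.frame(roc), k = k, repeats = repeats,
                 seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: %d-fold x %d repeats\n", x$k, x$repeats))
  print(round(x$metrics, 4))
  invisible(x)
}

#' Compare two gene sets under identical cross-validation
#'
#' Runs the same models with the same fold seeds on two datasets that share
#' samples and labels but differ in feature columns (the proposed vs the
#' reference gene panel), and reports paired metric deltas.
#'
#' @param dataset_a,dataset_b lists with `x` (feature matrix) and `y`
#'   (labels) as produced by [integrate_cohorts()]; `y` must be identical.
#' @param model_specs character vector of model specs (see
#'   [repeated_stratified_cv()]).
#' @param k,repeats,seed CV settings.
#' @param ... passed to [repeated_stratified_cv()].
#' @return List per model with `a`, `b` (evaluation reports) and `delta`
#'   (mean metric differences, a minus b).
#' @export
compare_gene_sets <- function(dataset_a, dataset_b,
                              model_specs = c("adaboost", "gradboost"),
                              k = 10, repeats = 10, seed = 1, ...) {
  if (!identical(as.integer(dataset_a$y), as.integer(dataset_b$y)) ||
      nrow(dataset_a$x) != nrow(dataset_b$x))
    stop("datasets must share the same samples and labels")
  out <- lapply(model_specs, function(spec) {
    a <- repeated_stratified_cv(dataset_a$x, dataset_a$y, spec, k = k,
                                repeats = repeats, seed = seed, ...)
    b <- repeated_stratified_cv(dataset_b$x, dataset_b$y, spec, k = k,
                                repeats = repeats, seed = seed, ...)
    list(a = a, b = b,
         delta = a$metrics["mean", ] - b$metrics["mean", ])
  })
  stats::setNames(out, model_specs)
}
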