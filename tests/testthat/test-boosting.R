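test_that("AdaBoost halts on separable data and flips with the labels", {
  x <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  m <- train_adaboost(x, y, n_rounds = 50)
  expect_equal(m$n_rounds, 1)              # err 0 in round one
  expect_identical(predict_adaboost(m, x, type = "class"),
                   c(-1, -1, -1, 1, 1, 1))
  m2 <- train_adaboost(x, 1 - y, n_rounds = 50)
  expect_identical(predict_adaboost(m2, x, type = "class"),
                   -predict_adaboost(m, x, type = "class"))
  expect_error(train_adaboost(x, rep(1, 6)), "both classes")
})

test_that("two AdaBoost rounds match a hand-executed trace", {
  # 1-D points 1..6; labels +,+,-,-,+,- : no single stump is perfect.
  x <- matrix(1:6, ncol = 1)
  y <- c(1, 1, -1, -1, 1, -1)
  m <- train_adaboost(x, y, n_rounds = 2)
  # round 1 (uniform weights 1/6): best stump is x <= 2 -> +1 (errs on #5),
  # weighted error 1/6, a1 = 0.5 log(5)
  expect_equal(m$alphas[1], 0.5 * log(5))
  st1 <- m$stumps[[1]]
  h1 <- st1$polarity * ifelse(1:6 > st1$threshold, 1, -1)
  expect_equal(sum((h1 != y) / 6), 1 / 6)
  # round 2: reweighted w = (1/10,...,1/10, 1/2 on #5); best achievable
  # weighted error is 2/10 (e.g. x <= 5 -> +1, errs on #3, #4)
  w2 <- exp(-m$alphas[1] * y * h1) / 6
  w2 <- w2 / sum(w2)
  expect_equal(unname(w2), c(.1, .1, .1, .1, .5, .1))
  st2 <- m$stumps[[2]]
  h2 <- st2$polarity * ifelse(1:6 > st2$threshold, 1, -1)
  expect_equal(sum(w2[h2 != y]), 0.2)
  expect_equal(m$alphas[2], 0.5 * log(0.8 / 0.2))
})

test_that("kept AdaBoost rounds always have weighted error below one half", {
  with_seed(71, for (i in 1:5) {
    x <- matrix(rnorm(40 * 3), 40, 3)
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    m <- train_adaboost(x, y, n_rounds = 25)
    expect_true(all(m$alphas > 0))         # err < 0.5 <=> alpha > 0
  })
})

test_that("gradient-boosted leaf weights take the penalized Newton step", {
  # one round, eta 1, a split forced between the two x groups; from the
  # 0.5 base score g_i = p - y = 0.5 - y, h_i = 0.25, so each leaf weight
  # is -G/(H + lambda) over its samples
  x <- matrix(c(rep(0, 8), rep(1, 8)), ncol = 1)
  y <- c(rep(0, 6), rep(1, 2), rep(1, 8))
  lambda <- 1.5
  m <- train_gradient_boosting(x, y, gradboost_params(
    n_rounds = 1, learning_rate = 1, max_leaves = 2, l2_penalty = lambda))
  pred <- predict_gradboost(m, matrix(c(0, 1), ncol = 1))
  w_left <- gbt_leaf_weight(sum(0.5 - y[1:8]), 8 * 0.25, lambda)
  w_right <- gbt_leaf_weight(sum(0.5 - y[9:16]), 8 * 0.25, lambda)
  expect_equal(pred, plogis(c(w_left, w_right)), tolerance = 1e-6)
  expect_equal(gbt_leaf_weight(3, 2, 1), -1)
})

test_that("an intercept-only boosted model converges to the base-rate
           log-odds, and heavy L2 shrinks weights toward zero", {
  x <- matrix(rnorm(30), ncol = 1)
  y <- c(rep(1, 9), rep(0, 21))
  # leaf_penalty so large no split clears it: every tree is a single leaf
  m <- train_gradient_boosting(x, y, gradboost_params(
    n_rounds = 60, learning_rate = 0.5, leaf_penalty = 1e6, l2_penalty = 0))
  expect_equal(unique(round(predict_gradboost(m, x), 6)),
               round(mean(y), 6))
  # lambda -> inf: predictions pinned at the 0.5 base score
  m2 <- train_gradient_boosting(x, y, gradboost_params(
    n_rounds = 10, l2_penalty = 1e9))
  expect_equal(predict_gradboost(m2, x), rep(0.5, 30), tolerance = 1e-4)
  expect_error(train_gradient_boosting(x, rep(1, 30)), "both classes")
})

test_that("confusion metrics and rank AUC behave exactly", {
  m <- compute_metrics(c(1, 1, 0, 0, 0, 0, 0, 0),
                       c(.9, .8, .1, .2, .3, .1, .2, .4))
  expect_equal(m$accuracy, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$auc, 1)
  # ranked scores [.9,.8,.4,.3] on labels [1,1,0,0] give AUC 1; swapping
  # the scores of one positive/negative pair drops it to 0.75
  expect_equal(compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.4, 0.3))$auc, 1)
  expect_equal(compute_metrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.8, 0.3))$auc, 0.75)
  # oracle: exhaustive pair counting with ties at 0.5
  with_seed(72, for (i in 1:10) {
    y <- rbinom(12, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(runif(12), 1)
    pairs <- expand.grid(p = which(y == 1), n = which(y == 0))
    oracle <- mean(ifelse(s[pairs$p] > s[pairs$n], 1,
                          ifelse(s[pairs$p] == s[pairs$n], 0.5, 0)))
    expect_equal(compute_metrics(y, s)$auc, oracle)
  })
  expect_equal(compute_metrics(c(1, 0, 1, 0), rep(0.5, 4))$auc, 0.5)
  expect_warning(compute_metrics(c(1, 1), c(0.2, 0.9)), "one class")
})

test_that("stratified folds balance the positive class exactly at 87/20/10", {
  y <- c(rep(1, 20), rep(0, 67))
  f <- stratified_folds(y, k = 10, seed = 5)
  expect_true(all(table(f[y == 1]) == 2))
  expect_true(all(table(f[y == 0]) %in% c(6, 7)))
  expect_error(stratified_folds(c(rep(1, 5), rep(0, 40)), k = 10),
               "smaller k")
})

test_that("cross-validation hits the ceiling on a perfect signal and 0.5 on
           pure noise", {
  with_seed(73, {
    y <- c(rep(1, 20), rep(0, 30))
    x_perfect <- matrix(y + rnorm(50, sd = 0.01), ncol = 1)
    rep1 <- repeated_stratified_cv(x_perfect, y, "adaboost", k = 5,
                                   repeats = 2, seed = 1)
    expect_equal(unname(rep1$metrics["mean", ]), rep(1, 4))
    null_spec <- list(train = function(x, y) NULL,
                      predict = function(model, x)
                        with_seed(NULL, runif(nrow(x))))
    rep0 <- repeated_stratified_cv(matrix(rnorm(50), ncol = 1), y, null_spec,
                                   k = 5, repeats = 20, seed = 2)
    expect_lt(abs(rep0$metrics["mean", "auc"] - 0.5), 0.05)
  })
  # determinism under a fixed seed
  y <- c(rep(1, 12), rep(0, 18))
  x <- with_seed(74, matrix(rnorm(30 * 2), 30, 2))
  a <- repeated_stratified_cv(x, y, "adaboost", k = 3, repeats = 2, seed = 9)
  b <- repeated_stratified_cv(x, y, "adaboost", k = 3, repeats = 2, seed = 9)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$fold_metrics, b$fold_metrics)
})

test_that("gene-set comparison is paired: identical features give identical
           metrics, planted markers beat null genes", {
  with_seed(75, {
    y <- c(rep(1, 15), rep(0, 25))
    xa <- matrix(rnorm(40 * 5), 40, 5) + 2 * y
    xb <- matrix(rnorm(40 * 8), 40, 8)
    same <- compare_gene_sets(list(x = xa, y = y), list(x = xa, y = y),
                              model_specs = "adaboost", k = 5, repeats = 2,
                              seed = 3)
    expect_equal(unname(same$adaboost$delta), rep(0, 4))
    cmp <- compare_gene_sets(list(x = xa, y = y), list(x = xb, y = y),
                             model_specs = "adaboost", k = 5, repeats = 2,
                             seed = 3)
    expect_gt(cmp$adaboost$delta[["auc"]], 0.2)
    expect_error(compare_gene_sets(list(x = xa, y = y),
                                   list(x = xb, y = 1 - y), "adaboost"),
                 "same samples")
  })
})
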