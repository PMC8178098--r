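test_that("grid initialization is reproducible and respects data ranges", {
  d <- matrix(rnorm(40), 10, 4)
  d[, 2] <- 7                              # constant dimension
  a <- init_grid(3, 3, 4, d, seed = 5, method = "uniform")
  b <- init_grid(3, 3, 4, d, seed = 5, method = "uniform")
  expect_identical(a$weights, b$weights)
  expect_equal(dim(a$weights), c(9, 4))
  expect_true(all(a$weights[, 2] == 7))
  expect_true(all(a$weights[, 1] >= min(d[, 1]) &
                    a$weights[, 1] <= max(d[, 1])))
  # sample init draws data rows
  s <- init_grid(3, 3, 4, d, seed = 5, method = "sample")
  expect_true(all(apply(s$weights, 1, function(w)
    any(apply(d, 1, function(r) all(r == w))))))
  expect_error(init_grid(0, 3, 4), "positive")
  expect_error(init_grid(3, 3, 0), "dimension")
})

test_that("BMU search matches brute force, with lowest-index tie-break", {
  m <- init_grid(3, 3, 5, seed = 2)
  expect_equal(find_bmu(m, m$weights[4, ]), 4)
  # equidistant construction: nodes 2 and 7 moved symmetrically about x
  x <- rep(0, 5)
  m$weights[2, ] <- c(1, 0, 0, 0, 0)
  m$weights[7, ] <- c(-1, 0, 0, 0, 0)
  m$weights[-c(2, 7), ] <- 5
  expect_equal(find_bmu(m, x), 2)
  # random inputs against an exhaustive scan
  with_seed(3, for (i in 1:25) {
    mm <- init_grid(3, 3, 4, seed = i)
    xx <- rnorm(4)
    brute <- which.min(colSums((t(mm$weights) - xx)^2))
    expect_equal(find_bmu(mm, xx), brute)
  })
  expect_error(find_bmu(m, 1:3), "dimension")
})

test_that("one competitive-learning update follows the neighborhood rule", {
  m <- init_grid(3, 3, 3, seed = 1)
  x <- c(10, -10, 2)
  # full pull: U = 1 at the BMU, gamma = 1
  up <- update_weights(m, x, bmu = 5, gamma = 1, sigma = 1e-9)
  expect_equal(unname(up$weights[5, ]), x)
  # gamma = 0 changes nothing
  expect_identical(update_weights(m, x, 5, gamma = 0, sigma = 1)$weights,
                   m$weights)
  # grid-distance-1 neighbor at sigma = 1, gamma = 0.5:
  # w + 0.5 * exp(-0.5) * (x - w), hand-computed
  up2 <- update_weights(m, x, bmu = 5, gamma = 0.5, sigma = 1)
  w2 <- m$weights[2, ]                     # node 2 is grid distance 1 from 5
  expect_equal(unname(up2$weights[2, ]),
               unname(w2 + 0.5 * exp(-0.5) * (x - w2)))
  # only weights change
  expect_identical(up2$grid_coords, m$grid_coords)
})

test_that("training is seed-deterministic, bitwise", {
  d <- with_seed(8, matrix(rnorm(15 * 6), 15, 6))
  p <- som_params(seed = 123, max_iterations = 300)
  m1 <- train_som(d, p)
  m2 <- train_som(d, p)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$training_steps_run, m2$training_steps_run)
  expect_identical(assign_clusters(m1, d), assign_clusters(m2, d))
})

test_that("a single repeated input is an attractor with vanishing
           quantization error", {
  d <- matrix(rep(c(3, -1, 2), each = 12), 12, 3)
  m <- train_som(d, som_params(seed = 4))
  expect_lt(m$quantization_error, 1e-3)
  expect_true(all(abs(sweep(m$weights, 2, c(3, -1, 2))) < 0.1))
})

test_that("well-separated blobs never share a BMU and empty nodes are legal", {
  d <- with_seed(10, rbind(matrix(rnorm(10 * 4), 10, 4),
                           matrix(rnorm(10 * 4, mean = 10), 10, 4)))
  m <- train_som(d, som_params(seed = 11))
  lab <- assign_clusters(m, d)
  expect_length(intersect(unique(lab[1:10]), unique(lab[11:20])), 0)
  expect_lte(length(unique(lab)), 9)       # empty nodes allowed
  pruned <- prune_empty_clusters(m, lab)
  expect_equal(sum(pruned$member_counts), 20)
})

test_that("quantization error trends downward over epochs on blob data", {
  d <- with_seed(12, rbind(matrix(rnorm(15 * 5), 15, 5),
                           matrix(rnorm(15 * 5, mean = 6), 15, 5)))
  m <- train_som(d, som_params(seed = 13))
  qe <- m$epoch_qe
  # online training fluctuates step to step; the trend over 20-epoch block
  # means must be non-increasing in at least 90% of transitions
  blocks <- tapply(qe, (seq_along(qe) - 1) %/% 20, mean)
  expect_gte(mean(diff(blocks) <= 1e-3), 0.9)
  expect_lt(qe[length(qe)], qe[1])
})

test_that("a noiseless 1-D manifold maps monotonically onto the grid", {
  t <- seq(0, 1, length.out = 40)
  d <- cbind(t, 2 * t, -t, 0.5 * t)        # straight line in 4-D
  m <- train_som(d, som_params(rows = 9, cols = 1, seed = 14))
  lab <- assign_clusters(m, d)
  expect_gt(abs(cor(t, lab, method = "spearman")), 0.8)
})

test_that("cluster assignment equals nearest-prototype classification and is
           idempotent", {
  d <- with_seed(15, matrix(rnorm(30 * 4), 30, 4))
  m <- train_som(d, som_params(seed = 16, max_iterations = 500))
  lab <- assign_clusters(m, d)
  brute <- apply(d, 1, function(x)
    which.min(colSums((t(m$weights) - x)^2)))
  expect_equal(lab, brute)
  expect_identical(lab, assign_clusters(m, d))
  # inputs equal to the node weights label 1..9 in order
  expect_equal(assign_clusters(m, m$weights), 1:9)
  expect_error(assign_clusters(m, d[, 1:2]), "dimension")
})

test_that("schedule parameters are validated and monotone", {
  expect_error(som_params(rows = 1, cols = 1), "at least 2 nodes")
  expect_error(som_params(initial_learning_rate = 0), "learning_rate")
  expect_error(som_params(final_learning_rate = 0.9,
                          initial_learning_rate = 0.5), "final_learning_rate")
  p <- som_params()
  g <- vapply(seq(0, 1000), function(i) phasesom:::.gamma_at(p, i, 1000), 0)
  s <- vapply(seq(0, 1000), function(i) phasesom:::.sigma_at(p, i, 1000), 0)
  expect_true(all(diff(g) <= 0))
  expect_true(all(diff(s) <= 0))
  expect_equal(g[1], 0.5)
  expect_equal(g[1001], 0.01)
  expect_equal(s[1001], 0.5)
})
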