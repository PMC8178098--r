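test_that("per-phase clustering fills one label column per phase", {
  tg <- two_group_tensor(n_per_group = 4, n_probes = 30, seed = 21)
  out <- per_phase_clustering(tg$tensor, som_params(seed = 31))
  expect_equal(dim(out$labels), c(8, 3))
  expect_identical(colnames(out$labels), c("A", "SA", "C"))
  expect_true(all(out$labels %in% 1:9))
  # identical data and identical seeds give identical columns
  m <- tg$tensor$matrices$A
  p <- som_params(seed = 99)
  labs <- replicate(3, assign_clusters(train_som(em_values(m), p),
                                       em_values(m)))
  expect_true(all(labs[, 1] == labs[, 2]) && all(labs[, 1] == labs[, 3]))
})

test_that("planted two-group structure is recovered exactly per phase at
           8-sigma separation", {
  tg <- two_group_tensor(n_per_group = 5, n_probes = 50, separation = 8,
                         seed = 23)
  out <- per_phase_clustering(tg$tensor,
                              som_params(seed = 32, initial_radius = 2.5,
                                         final_radius = 1.5))
  for (ph in c("A", "SA", "C")) {
    expect_equal(adjusted_rand_index(out$labels[, ph], tg$group), 1)
  }
})

test_that("second-stage SOM groups identical label rows together", {
  labs <- matrix(rep(c(2L, 5L, 7L), each = 12), 12, 3,
                 dimnames = list(sprintf("p%02d", 1:12), c("A", "SA", "C")))
  out <- second_stage_som(labs, som_params(seed = 41))
  expect_length(unique(out$second_stage_labels), 1)
  # two distinct rows repeated -> exactly two non-empty nodes
  labs2 <- rbind(matrix(rep(c(1L, 1L, 1L), each = 10), 10, 3),
                 matrix(rep(c(9L, 9L, 9L), each = 10), 10, 3))
  colnames(labs2) <- c("A", "SA", "C")
  rownames(labs2) <- sprintf("p%02d", 1:20)
  out2 <- second_stage_som(labs2, som_params(seed = 42))
  expect_length(unique(out2$second_stage_labels), 2)
  expect_length(unique(out2$second_stage_labels[1:10]), 1)
  expect_length(unique(out2$second_stage_labels[11:20]), 1)
})

test_that("empty-cluster pruning keeps exactly the populated prototypes", {
  m <- init_grid(3, 3, 3, seed = 1)
  labels <- c(1, 3, 3, 7, 8, 9, 9, 9)
  pr <- prune_empty_clusters(m, labels)
  expect_identical(pr$prototype_ids, c(1L, 3L, 7L, 8L, 9L))
  expect_equal(as.integer(pr$member_counts), c(1L, 2L, 1L, 1L, 3L))
  expect_equal(nrow(pr$prototype_weights), 5)
  # all populated -> nothing pruned; single populated node survives
  expect_length(prune_empty_clusters(m, 1:9)$prototype_ids, 9)
  expect_identical(prune_empty_clusters(m, rep(5, 4))$prototype_ids, 5L)
})

test_that("super-clustering cuts the prototype dendrogram and renumbers by
           first patient occurrence", {
  # five prototypes, two of which are mutually nearest: a cut at 4 merges
  # exactly that pair
  w <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10), c(10.5, 10.2))
  pruned <- list(prototype_ids = c(1L, 3L, 7L, 8L, 9L), prototype_weights = w,
                 member_counts = table(rep(1:5, times = c(6, 5, 2, 1, 6))))
  labels <- setNames(rep(c(1L, 3L, 7L, 8L, 9L), times = c(6, 5, 2, 1, 6)),
                     sprintf("KD%02d", 1:20))
  sc <- super_cluster(pruned, labels, cut_k = 4)
  expect_equal(max(sc$super_labels), 4)
  expect_equal(unname(sc$super_labels), rep(1:4, times = c(6, 5, 2, 7)))
  expect_identical(names(sc$super_labels), names(labels))
  # full cut: each prototype its own super-cluster
  full <- super_cluster(pruned, labels, cut_k = 5)
  expect_equal(max(full$super_labels), 5)
  expect_error(super_cluster(pruned, labels, cut_k = 6), "exceeds")
})

test_that("agglomerative partition matches a naive average-linkage oracle", {
  with_seed(51, for (rep in 1:5) {
    w <- matrix(rnorm(6 * 3), 6, 3)
    pruned <- list(prototype_ids = 1:6, prototype_weights = w)
    labels <- setNames(rep(1:6, each = 2), sprintf("p%02d", 1:12))
    for (k in 2:4) {
      sc <- super_cluster(pruned, labels, cut_k = k)
      oracle <- oracle_average_linkage(w, k)
      expect_equal(adjusted_rand_index(sc$prototype_super, oracle), 1)
    }
  })
})

test_that("two-stage clustering preserves patients, refines consistently and
           commutes with patient permutation", {
  tg <- two_group_tensor(n_per_group = 5, n_probes = 40, separation = 8,
                         seed = 23)
  cl <- two_stage_clustering(tg$tensor, params = som_params(seed = 33),
                             cut_k = 2)
  expect_equal(length(cl$super_labels), 10)
  expect_equal(sum(table(cl$super_labels)), 10)
  # super-clusters never split a second-stage cluster
  expect_true(all(tapply(cl$super_labels, cl$second_stage_labels,
                         function(s) length(unique(s))) == 1))
  expect_equal(adjusted_rand_index(cl$super_labels, tg$group), 1)
  # permuting patient order permutes labels identically
  perm <- with_seed(1, sample(10))
  mats <- lapply(tg$tensor$matrices, function(m)
    expression_matrix(em_values(m)[perm, , drop = FALSE]))
  cl2 <- two_stage_clustering(assemble_phase_tensor(mats),
                              params = som_params(seed = 33), cut_k = 2)
  expect_equal(adjusted_rand_index(cl2$super_labels,
                                   cl$super_labels[names(cl2$super_labels)]),
               1)
})
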