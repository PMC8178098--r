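# Shared fixtures, all generated in code.

with_seed <- phasesom:::with_seed

# tiny expression matrix with known values
tiny_matrix <- function(values = matrix(1:6, 2, 3), samples = c("s1", "s2"),
                        probes = c("p1", "p2", "p3")) {
  expression_matrix(matrix(as.numeric(values), nrow(values), ncol(values)),
                    sample_ids = samples, probes)
}

# three-phase tensor with planted two-group structure at a given separation
# (in within-group sd units, split over `n_signal` probes)
two_group_tensor <- function(n_per_group = 5, n_probes = 50, separation = 8,
                             n_signal = 4, seed = 1) {
  n <- 2 * n_per_group
  group <- rep(1:2, each = n_per_group)
  offset <- separation / sqrt(n_signal)
  mats <- with_seed(seed, {
    lapply(c(A = "A", SA = "SA", C = "C"), function(ph) {
      v <- matrix(rnorm(n * n_probes), n, n_probes,
                  dimnames = list(sprintf("pt%02d", 1:n),
                                  sprintf("g%03d", 1:n_probes)))
      v[, seq_len(n_signal)] <- v[, seq_len(n_signal)] +
        offset * (group == 2)
      expression_matrix(v)
    })
  })
  list(tensor = assemble_phase_tensor(mats), group = group)
}

# one full planted-structure pipeline run at the study conditions:
# impute -> two-stage SOM clustering -> super-clusters -> per-phase
# ANOVA/BH selection -> cross-phase intersection
pipeline_recovery_run <- function(seed, effect_size = 3, n_probes = 2000) {
  cc <- generate_case_cohort(seed = seed, effect_size = effect_size,
                             n_probes = n_probes)
  tn <- assemble_phase_tensor(lapply(cc$tensor$matrices, impute_missing_zero))
  cl <- two_stage_clustering(
    tn, params = som_params(seed = derive_seed(seed, 7),
                            initial_radius = 2.5, final_radius = 1.5))
  sel <- suppressWarnings(phase_feature_selection(tn, cl$super_labels))
  truth <- cc$truth
  fs <- sel$final_set
  list(
    ari = adjusted_rand_index(cl$super_labels,
                              truth$super_cluster_assignment),
    n_selected = length(fs),
    precision = if (length(fs)) mean(fs %in% truth$marker_probes) else NA_real_,
    recall = mean(truth$marker_probes %in% fs),
    perfect = setequal(fs, truth$marker_probes) &&
      length(fs) == length(truth$marker_probes),
    phase_specific_selected = sum(names(truth$phase_specific_probes) %in% fs),
    clustering = cl, selection = sel, truth = truth)
}

# independent agglomerative-clustering oracle: naive average-linkage merge
# over an explicit distance matrix, returning the partition at k groups
oracle_average_linkage <- function(x, k) {
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  while (length(clusters) > k) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      dij <- mean(d[clusters[[i]], clusters[[j]]])
      if (dij < best[1]) best <- c(dij, i, j)
    }
    i <- best[2]; j <- best[3]
    clusters[[j]] <- c(clusters[[j]], clusters[[i]])
    clusters[[i]] <- NULL
  }
  out <- integer(nrow(x))
  for (g in seq_along(clusters)) out[clusters[[g]]] <- g
  out
}

# exhaustive Benjamini-Hochberg step-up oracle for small m
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  k_max <- 0
  for (k in seq_len(m)) if (p[o[k]] <= k * alpha / m) k_max <- k
  reject <- rep(FALSE, m)
  if (k_max > 0) reject[o[seq_len(k_max)]] <- TRUE
  reject
}
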