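#' Replace missing expression values with zero
#'
#' The curation policy for undefined cells: every missing entry becomes 0 and
#' its mask is cleared; non-missing cells are untouched. Zero is a neutral
#' value on the log-ratio scale the common-platform data use. Run outlier
#' detection and covariance filtering first so flagged material is removed
#' before imputation can dilute it.
#'
#' @param x an [expression_matrix].
#' @return The matrix with no missing cells, plus attribute `n_imputed`.
#' @export
impute_missing_zero <- function(x) {
  v <- em_values(x)
  n <- sum(is.na(v))
  v[is.na(v)] <- 0
  out <- expression_matrix(v)
  attr(out, "n_imputed") <- n
  out
}

# ---- isolation forest (random partition depth) -------------------------

# Average unsuccessful-search path length in a BST of n nodes; the usual
# normalizer for isolation depth.
.iso_c <- function(n) {
  if (n <= 1) return(0)
  2 * (log(n - 1) + 0.5772156649015329) - 2 * (n - 1) / n
}

.iso_tree_depths <- function(x, depth_limit) {
  n <- nrow(x)
  depths <- numeric(n)
  recurse <- function(idx, depth) {
    if (length(idx) <= 1L || depth >= depth_limit) {
      depths[idx] <<- depth + .iso_c(length(idx))
      return(invisible())
    }
    repeat {
      f <- sample.int(ncol(x), 1L)
      rng <- range(x[idx, f])
      if (rng[1] < rng[2]) break
      # all candidate features constant for this node?
      if (all(apply(x[idx, , drop = FALSE], 2, function(c) max(c) == min(c)))) {
        depths[idx] <<- depth + .iso_c(length(idx))
        return(invisible())
      }
    }
    split <- stats::runif(1, rng[1], rng[2])
    left <- idx[x[idx, f] < split]
    right <- setdiff(idx, left)
    recurse(left, depth + 1L)
    recurse(right, depth + 1L)
  }
  recurse(seq_len(n), 0L)
  depths
}

#' Isolation-forest anomaly scores
#'
#' Random-partition-depth anomaly detector: points isolated in few random
#' axis-aligned splits get short average path lengths and scores near 1.
#'
#' @param x numeric matrix, rows = observations.
#' @param n_trees number of random trees.
#' @param subsample per-tree subsample size (capped at `nrow(x)`).
#' @param seed integer seed.
#' @return Numeric vector of scores in (0, 1), higher = more anomalous.
#' @export
isolation_forest_score <- function(x, n_trees = 100, subsample = 256,
                                   seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  psi <- min(subsample, n)
  with_seed(seed, {
    depth_sum <- numeric(n)
    depth_n <- numeric(n)
    limit <- ceiling(log2(max(psi, 2)))
    for (t in seq_len(n_trees)) {
      idx <- sample.int(n, psi)
      d <- .iso_tree_depths(x[idx, , drop = FALSE], limit)
      depth_sum[idx] <- depth_sum[idx] + d
      depth_n[idx] <- depth_n[idx] + 1
    }
    depth_n[depth_n == 0] <- 1
    2^(-(depth_sum / depth_n) / .iso_c(psi))
  })
}

# ---- local outlier factor (density ratio) ------------------------------

#' Local outlier factor
#'
#' Classic k-nearest-neighbour density-ratio score: the ratio of a point's
#' neighbours' local reachability density to its own. Scores near 1 are
#' inliers; substantially larger values are outliers.
#'
#' @param x numeric matrix, rows = observations.
#' @param k neighbourhood size.
#' @return Numeric vector of LOF scores (>= 0).
#' @export
local_outlier_factor <- function(x, k = 10) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- max(1L, min(k, n - 1L))
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  # k-distance and neighbour sets (ties included would complicate; use the
  # first k by distance with stable ordering)
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  kdist <- vapply(seq_len(n), function(i) d[i, nn[i, k]], 0)
  reach <- function(i, j) max(kdist[j], d[i, j])
  lrd <- vapply(seq_len(n), function(i) {
    rs <- vapply(nn[i, ], function(j) reach(i, j), 0)
    m <- mean(rs)
    if (m == 0) Inf else 1 / m
  }, 0)
  vapply(seq_len(n), function(i) {
    if (!is.finite(lrd[i])) return(1)
    r <- lrd[nn[i, ]] / lrd[i]
    r[!is.finite(r)] <- 1
    mean(r)
  }, 0)
}

#' Consensus multivariate outlier detection
#'
#' Scores every sample with two multivariate detectors — an isolation forest
#' (random partition depth) and the local outlier factor (k-NN density
#' ratio) — and flags a sample only when *both* detectors rank it inside the
#' top `contamination` fraction. The consensus rule is deliberately
#' conservative: scores are always reported, removal is a separate pipeline
#' option.
#'
#' Missing cells are seen as zeros for scoring only; the matrix itself is not
#' modified.
#'
#' @param x an [expression_matrix] with >= 5 samples.
#' @param contamination expected outlier fraction in `[0, 0.5]`.
#' @param seed integer seed (isolation forest randomness).
#' @param lof_k LOF neighbourhood size.
#' @return List with `flagged` (character sample ids), `scores` (data frame:
#'   sample_id, iforest, lof), and `contamination`.
#' @export
detect_outlier_samples <- function(x, contamination = 0.05, seed = 1,
                                   lof_k = 10) {
  if (contamination < 0 || contamination > 0.5)
    stop("contamination must be in [0, 0.5]")
  v <- em_values(x)
  if (nrow(v) < 5) stop("need at least 5 samples for outlier detection")
  v[is.na(v)] <- 0
  # canonical sample order so flagging is permutation-equivariant
  ord <- order(rownames(v))
  vs <- v[ord, , drop = FALSE]
  iso <- isolation_forest_score(vs, seed = seed)
  lof <- local_outlier_factor(vs, k = lof_k)
  n <- nrow(vs)
  budget <- floor(contamination * n)
  flagged <- character(0)
  if (budget > 0) {
    # top-k by score, but a sample must stand strictly above the (k+1)-th
    # largest score: with all-equal scores nothing is an outlier
    top_frac <- function(s) {
      thr <- sort(s, decreasing = TRUE)[min(budget + 1L, n)]
      rownames(vs)[s > thr]
    }
    flagged <- intersect(top_frac(iso), top_frac(lof))
  }
  scores <- data.frame(sample_id = rownames(vs), iforest = iso, lof = lof,
                       row.names = NULL)
  scores <- scores[match(rownames(v), scores$sample_id), ]
  rownames(scores) <- NULL
  list(flagged = flagged[order(match(flagged, rownames(v)))],
       scores = scores, contamination = contamination)
}

#' Filter genes with high joint variability
#'
#' Computes the gene-gene covariance matrix (over samples) and removes genes
#' whose joint variability with some other gene is extreme. Each gene's
#' statistic is its maximum absolute off-diagonal covariance; the threshold
#' is the `covariance_quantile` of those statistics. Removal is greedy by
#' largest offending covariance at or above the threshold, dropping the
#' higher column index of the offending pair and re-scoring, so a
#' duplicated gene loses exactly one copy (the later column).
#'
#' @param x an [expression_matrix] with >= 2 genes and >= 3 samples; no
#'   missing values (impute or filter first; missing are treated as zero).
#' @param covariance_quantile quantile in (0, 1] of the max-absolute-
#'   covariance statistic above which a gene is removed. Default 0.999.
#' @return List with `matrix` (filtered [expression_matrix]) and `removed`
#'   (data frame: probe_id, max_abs_cov).
#' @export
filter_high_covariance_genes <- function(x, covariance_quantile = 0.999) {
  if (covariance_quantile <= 0 || covariance_quantile > 1)
    stop("covariance_quantile must be in (0, 1]")
  v <- em_values(x)
  if (ncol(v) < 2) {
    return(list(matrix = x,
                removed = data.frame(probe_id = character(0),
                                     max_abs_cov = numeric(0))))
  }
  if (nrow(v) < 3) stop("need at least 3 samples to estimate covariance")
  v[is.na(v)] <- 0
  cv <- abs(stats::cov(v))
  diag(cv) <- 0
  stat <- apply(cv, 2, max)
  thr <- stats::quantile(stat, covariance_quantile, names = FALSE)
  keep <- rep(TRUE, ncol(v))
  removed <- integer(0)
  repeat {
    sub <- cv[keep, keep, drop = FALSE]
    if (!any(sub >= thr)) break
    s <- apply(sub, 2, max)
    worst <- which(s == max(s))
    drop_local <- worst[length(worst)]            # tie-break: later column
    drop_global <- which(keep)[drop_local]
    removed <- c(removed, drop_global)
    keep[drop_global] <- FALSE
    if (sum(keep) < 2) break
  }
  list(matrix = expression_matrix(em_values(x)[, keep, drop = FALSE]),
       removed = data.frame(probe_id = colnames(v)[removed],
                            max_abs_cov = stat[removed], row.names = NULL))
}

#' Run the full curation stage
#'
#' Order of operations: consensus outlier detection and covariance filtering
#' run on the raw matrix (missing cells seen as zero only for scoring), then
#' missing values are zero-imputed — flagged material is identified before
#' imputation can contaminate it. By default outliers are report-only
#' (`remove_outliers = FALSE`).
#'
#' @param x an [expression_matrix].
#' @param contamination outlier budget, see [detect_outlier_samples()].
#' @param covariance_quantile see [filter_high_covariance_genes()];
#'   `NULL` skips covariance filtering entirely. The quantile rule always
#'   removes the most-covarying tail, so on cohorts where a few genes
#'   legitimately carry correlated subgroup structure (the discovery
#'   target) it removes exactly the signal — leave it off unless screening
#'   raw platform deposits.
#' @param remove_outliers drop flagged samples (default `FALSE`: report
#'   only).
#' @param seed integer seed.
#' @return List with `matrix` (curated [expression_matrix]) and `report`
#'   (flagged samples with scores, removed genes, `n_imputed`).
#' @export
curate <- function(x, contamination = 0.05, covariance_quantile = NULL,
                   remove_outliers = FALSE, seed = 1) {
  out <- detect_outlier_samples(x, contamination = contamination, seed = seed)
  v <- em_values(x)
  if (remove_outliers && length(out$flagged))
    v <- v[setdiff(rownames(v), out$flagged), , drop = FALSE]
  flt <- if (is.null(covariance_quantile)) {
    list(matrix = expression_matrix(v),
         removed = data.frame(probe_id = character(0),
                              max_abs_cov = numeric(0)))
  } else {
    filter_high_covariance_genes(expression_matrix(v), covariance_quantile)
  }
  imp <- impute_missing_zero(flt$matrix)
  list(matrix = imp,
       report = list(flagged_samples = out$flagged,
                     outlier_scores = out$scores,
                     removed_genes = flt$removed,
                     n_imputed = attr(imp, "n_imputed")))
}
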