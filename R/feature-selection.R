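#' One-way ANOVA F statistic
#'
#' Standard one-way ANOVA of a single variable across `N` groups: the
#' treatment mean square `MST = sum(n_i (m_i - m)^2) / (N - 1)` over the
#' mean square error `MSE = sum((n_i - 1) s_i^2) / (n - N)`, with the
#' p-value from the upper tail of the F distribution on `(N - 1, n - N)`
#' degrees of freedom. `MSE = 0` with `MST > 0` gives `F = Inf`, `p = 0`;
#' `MST = MSE = 0` (a constant variable) gives an undefined `F = NA` — such
#' probes are excluded and logged by the selection stage.
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups, every
#'   group non-empty, total n > number of groups).
#' @return List with `F`, `p`, `df1`, `df2`, `group_means`,
#'   `group_variances`, `group_sizes`.
#' @export
anova_f <- function(groups) {
  if (length(groups) < 2) stop("at least two groups are required")
  n_i <- lengths(groups)
  if (any(n_i == 0)) stop("empty group supplied")
  N <- length(groups)
  n <- sum(n_i)
  if (n <= N) stop("total sample count must exceed the group count")
  m_i <- vapply(groups, mean, 0)
  v_i <- vapply(groups, function(g) if (length(g) > 1) stats::var(g) else 0, 0)
  m <- sum(n_i * m_i) / n
  mst <- sum(n_i * (m_i - m)^2) / (N - 1)
  mse <- sum((n_i - 1) * v_i) / (n - N)
  if (mse > 0) {
    f <- mst / mse
    p <- stats::pf(f, N - 1, n - N, lower.tail = FALSE)
  } else if (mst > 0) {
    f <- Inf; p <- 0
  } else {
    f <- NA_real_; p <- NA_real_
  }
  list(F = f, p = p, df1 = N - 1, df2 = n - N,
       group_means = m_i, group_variances = v_i, group_sizes = n_i)
}

# Vectorized one-way ANOVA of every column of x against labels g.
.anova_f_matrix <- function(x, g) {
  g <- as.factor(g)
  N <- nlevels(g)
  n <- nrow(x)
  n_i <- as.vector(table(g))
  sums <- rowsum(x, g)                    # N x P group sums
  means <- sums / n_i
  grand <- colSums(x) / n
  ssb <- colSums(n_i * (means - rep(grand, each = N))^2)
  sst <- colSums(x^2) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  mst <- ssb / (N - 1)
  mse <- ssw / (n - N)
  f <- ifelse(mse > 0, mst / mse, ifelse(mst > 0, Inf, NA_real_))
  p <- ifelse(is.na(f), NA_real_,
              stats::pf(f, N - 1, n - N, lower.tail = FALSE))
  data.frame(probe_id = colnames(x), F = f, p = p, row.names = NULL)
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up procedure: with sorted p-values `p_(1) <= ... <= p_(m)`, find the
#' largest `k` with `p_(k) <= k * alpha / m` and reject the `k` smallest.
#' Adjusted values are `q_(k) = min_{j >= k} (m * p_(j) / j)` capped at 1
#' (via [stats::p.adjust()]); rejection at level `alpha` is equivalent to
#' `q <= alpha`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` allowed; never
#'   rejected).
#' @param alpha FDR level.
#' @return List with `q` (adjusted values) and `reject` (logical mask).
#' @export
benjamini_hochberg <- function(p, alpha = 0.01) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  m <- sum(!is.na(p))
  reject <- rep(FALSE, length(p))
  if (m > 0) {
    ok <- which(!is.na(p))
    o <- ok[order(p[ok])]
    below <- which(p[o] <= seq_len(m) * alpha / m)
    if (length(below)) reject[o[seq_len(max(below))]] <- TRUE
  }
  list(q = q, reject = reject)
}

#' Per-phase significant probe selection
#'
#' Scores every probe of one phase by one-way ANOVA against the
#' super-cluster labels, adjusts across all probes of the phase by
#' Benjamini-Hochberg, and returns the rejected set at FDR `alpha`.
#' Constant probes (undefined F) are excluded and reported.
#'
#' @param phase_matrix an [expression_matrix] for one phase (curated).
#' @param super_labels integer super-cluster label per sample, in the
#'   matrix's sample order (>= 2 distinct values).
#' @param alpha FDR level (default 0.01).
#' @return List with `significant` (character probe ids), `table` (probe,
#'   F, p, q, reject), `excluded` (constant probes), `alpha`.
#' @export
select_per_phase <- function(phase_matrix, super_labels, alpha = 0.01) {
  v <- em_values(phase_matrix)
  if (length(super_labels) != nrow(v))
    stop("super_labels must cover every sample")
  if (length(unique(super_labels)) < 2)
    stop("at least two super-clusters are required")
  if (anyNA(v)) stop("missing values present; curate first")
  tab <- .anova_f_matrix(v, super_labels)
  bh <- benjamini_hochberg(tab$p, alpha)
  tab$q <- bh$q
  tab$reject <- bh$reject
  list(significant = tab$probe_id[tab$reject],
       table = tab,
       excluded = tab$probe_id[is.na(tab$F)],
       alpha = alpha)
}

#' Cross-phase intersection of significant probes
#'
#' The proposed gene set: probes significant in all three phases. An empty
#' intersection is legal (a warning, not an error) — the pipeline continues.
#'
#' @param sets named list of three character vectors (per-phase significant
#'   probes, names `A`, `SA`, `C`).
#' @return List with `final_set` (sorted probe ids significant in all
#'   phases) and `per_phase` (the input sets).
#' @export
intersect_phases <- function(sets) {
  if (length(sets) != 3) stop("three per-phase sets are required")
  final <- sort(Reduce(intersect, sets))
  if (!length(final))
    warning("no probe is significant across all three phases")
  list(final_set = final, per_phase = sets)
}

#' Per-phase selection plus intersection in one call
#'
#' @param tensor a curated `phase_tensor`.
#' @param super_labels integer super-cluster label per patient.
#' @param alpha FDR level.
#' @return List with `final_set`, `per_phase` (selection results per
#'   phase), `alpha`.
#' @export
phase_feature_selection <- function(tensor, super_labels, alpha = 0.01) {
  per_phase <- lapply(tensor$matrices, select_per_phase,
                      super_labels = super_labels, alpha = alpha)
  inter <- intersect_phases(lapply(per_phase, `[[`, "significant"))
  list(final_set = inter$final_set, per_phase = per_phase, alpha = alpha)
}
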