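#' Quantile-normalize a dataset against its average-quantile reference
#'
#' Meta-analysis normalization: within one dataset, every sample's sorted
#' values are replaced by the across-sample mean of the order statistics
#' (the reference distribution), so after normalization all samples share an
#' identical value distribution. Ties within a sample receive the mean of
#' the reference values at their tied ranks. Normalization is always
#' per-dataset, never pooled across datasets.
#'
#' Backed by `limma::normalizeQuantiles` (samples as columns, `ties = TRUE`
#' is exactly this tie dialect) when the dataset supplies its own
#' reference.
#'
#' For cross-dataset meta-analysis a *shared* reference is essential:
#' normalizing every dataset to its own average quantiles leaves
#' between-dataset location/scale shifts untouched. Pass `reference` (the
#' pooled average quantiles over all cohorts, see
#' [pooled_quantile_reference()]) to map each dataset onto one common
#' distribution; each dataset is still transformed individually.
#'
#' @param x an [expression_matrix] with no missing values and >= 2 samples
#'   (one suffices when `reference` is supplied).
#' @param dataset_id label recorded in the audit.
#' @param reference optional non-decreasing numeric vector of target order
#'   statistics, length `ncol(x)`.
#' @return List with `matrix` (normalized [expression_matrix]) and `audit`
#'   (dataset_id, non-decreasing `reference_quantiles`, `tie_policy`).
#' @export
quantile_normalize <- function(x, dataset_id = "dataset", reference = NULL) {
  v <- em_values(x)
  if (anyNA(v))
    stop("missing values present; run curation (impute_missing_zero) first")
  if (is.null(reference)) {
    if (nrow(v) < 2) stop("quantile normalization needs >= 2 samples")
    ref <- rowMeans(matrix(apply(t(v), 2, sort), ncol = nrow(v)))
    norm <- t(limma::normalizeQuantiles(t(v), ties = TRUE))
    dimnames(norm) <- dimnames(v)
  } else {
    if (length(reference) != ncol(v))
      stop("reference length must equal the probe count")
    if (is.unsorted(reference)) stop("reference must be non-decreasing")
    ref <- reference
    norm <- t(apply(v, 1, function(r) {
      out <- ref[rank(r, ties.method = "first")]
      # ties share the mean of the reference values at their tied ranks
      stats::ave(out, match(r, r), FUN = mean)
    }))
    dimnames(norm) <- dimnames(v)
  }
  list(matrix = expression_matrix(norm),
       audit = list(dataset_id = dataset_id,
                    reference_quantiles = ref,
                    tie_policy = "mean-of-tied-rank-reference"))
}

#' Pooled average-quantile reference over several cohorts
#'
#' The element-wise mean of every sample's sorted value vector across all
#' supplied datasets: the common target distribution for cross-dataset
#' quantile normalization ("the average of each quantile ... used as the
#' reference").
#'
#' @param matrices list of [expression_matrix] objects sharing a probe
#'   universe size.
#' @return Non-decreasing numeric vector of pooled order statistics.
#' @export
pooled_quantile_reference <- function(matrices) {
  sorted <- lapply(matrices, function(m)
    matrix(apply(em_values(m), 1, sort), ncol = nrow(em_values(m))))
  p <- unique(vapply(sorted, nrow, 1L))
  if (length(p) != 1) stop("all datasets must share the probe count")
  rowMeans(do.call(cbind, sorted))
}

#' Collapse multi-probe genes to per-gene medians
#'
#' A platform measures probes; where several probes interrogate one gene,
#' each sample's gene value is the median over that gene's probes (even
#' counts: midpoint of the middle pair). Probes absent from the annotation
#' are retained under their probe id. In the cross-platform path the
#' collapse runs *before* quantile normalization.
#'
#' @param x an [expression_matrix].
#' @param annotation a [probe_annotation()] map (probe id -> gene id).
#' @return An [expression_matrix] whose columns are gene ids (plus
#'   unannotated probe ids), with attribute `n_probes_collapsed`.
#' @export
collapse_probes_to_genes <- function(x, annotation) {
  v <- em_values(x)
  probes <- colnames(v)
  gene <- unname(unclass(annotation)[probes])
  unmapped <- is.na(gene)
  gene[unmapped] <- probes[unmapped]
  groups <- split(seq_along(gene), gene)
  # keep first-occurrence column order for the output
  groups <- groups[order(vapply(groups, min, 1L))]
  out <- vapply(groups, function(ix) {
    if (length(ix) == 1L) v[, ix] else apply(v[, ix, drop = FALSE], 1,
                                             stats::median)
  }, numeric(nrow(v)))
  if (nrow(v) == 1L) out <- matrix(out, nrow = 1L,
                                   dimnames = list(rownames(v), names(groups)))
  res <- expression_matrix(out, sample_ids = rownames(v),
                           probe_ids = names(groups))
  attr(res, "n_probes_collapsed") <- sum(lengths(groups) > 1L)
  res
}

#' Integrate case and control cohorts into a labeled dataset
#'
#' Row-concatenates independently normalized datasets restricted to a fixed
#' gene panel, labeling case samples 1 and controls 0, with a provenance
#' column recording the source dataset. Inputs are expected to be collapsed
#' to genes and quantile-normalized already (each on its own).
#'
#' @param case an [expression_matrix] of case samples.
#' @param controls list of control [expression_matrix] objects (>= 1).
#' @param gene_subset character vector of gene ids; every input must contain
#'   all of them.
#' @param case_id,control_ids provenance labels.
#' @return List with `x` (numeric matrix, rows = samples, columns =
#'   `gene_subset` in the stated order), `y` (integer 0/1 labels), `source`
#'   (character provenance per row), `sample_ids`.
#' @export
integrate_cohorts <- function(case, controls, gene_subset,
                              case_id = "case",
                              control_ids = paste0("control", seq_along(controls))) {
  if (!length(controls)) stop("at least one control dataset is required")
  all_in <- c(list(case), controls)
  all_ids <- c(case_id, control_ids)
  for (i in seq_along(all_in)) {
    miss <- setdiff(gene_subset, em_probe_ids(all_in[[i]]))
    if (length(miss))
      stop(sprintf("dataset '%s' is missing required gene(s): %s",
                   all_ids[i], paste(miss, collapse = ", ")))
  }
  mats <- lapply(all_in, function(m)
    em_values(m)[, gene_subset, drop = FALSE])
  x <- do.call(rbind, mats)
  y <- c(rep(1L, nrow(mats[[1]])),
         rep(0L, sum(vapply(mats[-1], nrow, 1L))))
  source <- rep(all_ids, vapply(mats, nrow, 1L))
  sample_ids <- unlist(lapply(all_in, em_sample_ids), use.names = FALSE)
  rownames(x) <- make.unique(sample_ids)
  list(x = x, y = y, source = source, sample_ids = sample_ids)
}
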