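# Fixed ±1 sign patterns for group marker offsets. Rows = groups, columns
# recycle over markers; pairwise Hamming distance >= 2 over any 5 columns,
# so any two groups differ by at least 2*effect_size*noise_sd on several
# markers — group-mean separation is what one-way ANOVA (and the SOM) see.
.group_sign_patterns <- function(n_groups, n_markers) {
  base <- rbind(c( 1,  1,  1,  1,  1),
                c( 1, -1, -1,  1, -1),
                c(-1,  1, -1, -1,  1),
                c(-1, -1,  1, -1, -1),
                c( 1,  1, -1, -1, -1),
                c(-1, -1, -1,  1,  1))
  if (n_groups > nrow(base)) {
    extra <- matrix(sign(stats::rnorm((n_groups - nrow(base)) * 5)), ncol = 5)
    extra[extra == 0] <- 1
    base <- rbind(base, extra)
  }
  base[seq_len(n_groups), rep_len(seq_len(5), n_markers), drop = FALSE]
}

#' Generate a synthetic three-phase case cohort with planted structure
#'
#' Emulates the statistical structure the workflow assumes: `n_patients`
#' split into `n_groups` latent subgroups (the planted super-clusters);
#' background probes i.i.d. `Normal(0, noise_sd^2)` per phase; `n_markers`
#' phase-consistent marker probes whose group means are offset by
#' `effect_size * noise_sd` times a fixed per-group ±1 sign pattern,
#' identically in all three phases; `n_phase_specific` probes carrying the
#' same kind of offset in only a subset of phases (1 or 2 of them) — these
#' must *not* survive the cross-phase intersection; missing cells planted
#' completely at random at `missing_rate`. Defaults mirror the study scale:
#' 20 patients in groups of 6/5/2/7 with 5 phase-consistent markers.
#'
#' @param n_patients number of patients (default 20).
#' @param n_probes number of probes (default 2000; study scale 37,653 is
#'   supported but slow).
#' @param group_sizes integer vector of planted group sizes summing to
#'   `n_patients` (default `c(6, 5, 2, 7)`).
#' @param n_markers phase-consistent marker probes (default 5).
#' @param n_phase_specific probes with offsets in only 1-2 phases
#'   (default 5).
#' @param effect_size offset magnitude in `noise_sd` units (default 3).
#' @param noise_sd background standard deviation (default 1).
#' @param missing_rate fraction of cells planted missing (default 0.01).
#' @param seed integer seed.
#' @return List with `tensor` (a `phase_tensor`) and `truth`
#'   (`super_cluster_assignment`, `marker_probes`, `phase_specific_probes`
#'   with their active phases, `effect_size`, `missing_cells`, `seed`).
#' @export
generate_case_cohort <- function(n_patients = 20, n_probes = 2000,
                                 group_sizes = c(6, 5, 2, 7),
                                 n_markers = 5, n_phase_specific = 5,
                                 effect_size = 3, noise_sd = 1,
                                 missing_rate = 0.01, seed = 1) {
  if (sum(group_sizes) != n_patients)
    stop("group_sizes must sum to n_patients")
  if (length(group_sizes) < 2) stop("at least 2 groups are required")
  if (n_markers + n_phase_specific >= n_probes)
    stop("marker probes must be fewer than n_probes")
  if (missing_rate < 0 || missing_rate >= 1) stop("invalid missing_rate")
  if (effect_size < 0) stop("effect sizes must be >= 0")
  phases <- c("A", "SA", "C")
  n_groups <- length(group_sizes)
  with_seed(seed, {
    group <- rep(seq_len(n_groups), group_sizes)
    patient_ids <- sprintf("KD%04d", seq_len(n_patients))
    probe_ids <- sprintf("probe%05d", seq_len(n_probes))
    marker_idx <- seq_len(n_markers)
    ps_idx <- if (n_phase_specific > 0)
      n_markers + seq_len(n_phase_specific) else integer(0)
    signs <- .group_sign_patterns(n_groups, n_markers + n_phase_specific)
    # each phase-specific probe is active in a random 1- or 2-phase subset
    ps_active <- lapply(ps_idx, function(i)
      sort(sample(3L, sample(2L, 1L))))
    mats <- list()
    for (ph in seq_along(phases)) {
      v <- matrix(stats::rnorm(n_patients * n_probes, sd = noise_sd),
                  n_patients, n_probes,
                  dimnames = list(patient_ids, probe_ids))
      for (j in marker_idx)
        v[, j] <- v[, j] + effect_size * noise_sd * signs[group, j]
      for (jj in seq_along(ps_idx))
        if (ph %in% ps_active[[jj]]) {
          j <- ps_idx[jj]
          v[, j] <- v[, j] + effect_size * noise_sd * signs[group, j]
        }
      if (missing_rate > 0) {
        miss <- which(stats::runif(length(v)) < missing_rate)
        v[miss] <- NA_real_
      }
      mats[[phases[ph]]] <- expression_matrix(v)
    }
    truth <- list(
      super_cluster_assignment = stats::setNames(group, patient_ids),
      marker_probes = probe_ids[marker_idx],
      phase_specific_probes = stats::setNames(
        lapply(ps_active, function(a) phases[a]), probe_ids[ps_idx]),
      effect_size = effect_size, noise_sd = noise_sd,
      missing_rate = missing_rate, seed = seed)
    list(tensor = assemble_phase_tensor(mats), truth = truth)
  })
}

#' Generate a synthetic control cohort
#'
#' Controls share the case cohort's probe universe but carry no marker
#' offsets; an optional global location shift emulates a cohort-level
#' difference. Downstream these samples are labeled 0.
#'
#' @param n_controls number of control samples (default 67, the study's
#'   control-group size).
#' @param n_probes number of probes (must match the case cohort for
#'   common-platform use).
#' @param shift global location shift (default 0).
#' @param noise_sd background standard deviation.
#' @param seed integer seed.
#' @return An [expression_matrix].
#' @export
generate_control_cohort <- function(n_controls = 67, n_probes = 2000,
                                    shift = 0, noise_sd = 1, seed = 2) {
  with_seed(seed, {
    v <- matrix(stats::rnorm(n_controls * n_probes, mean = shift,
                             sd = noise_sd),
                n_controls, n_probes,
                dimnames = list(sprintf("CTRL%04d", seq_len(n_controls)),
                                sprintf("probe%05d", seq_len(n_probes))))
    expression_matrix(v)
  })
}

#' Generate a synthetic multi-dataset cross-platform suite
#'
#' Emulates integrating case/control datasets deposited on heterogeneous
#' platforms: each dataset receives its own affine distortion (location and
#' scale, standing in for linear-RMA vs log2 vs z-score value conventions),
#' and a fraction of genes is represented by 2-3 probes sharing the gene
#' signal plus probe-level noise (so median collapse is exercised). Case
#' (label 1) samples carry marker offsets on `marker_genes`; defaults
#' mirror the study's integration scale: six datasets, 1,347 samples of
#' which 558 are cases.
#'
#' @param per_dataset_sizes integer sample count per dataset.
#' @param per_dataset_cases cases among them (0 for control-only datasets).
#' @param marker_genes number of case-offset genes (default 5).
#' @param n_genes genes per dataset (default 300; all datasets share the
#'   gene universe).
#' @param effect_size case offset in `noise_sd` units.
#' @param platform_effects list of `c(location, scale)` per dataset; `NULL`
#'   draws a fixed heterogeneous default.
#' @param multiprobe_rate fraction of genes carried by 2-3 probes
#'   (default 0.3).
#' @param noise_sd base noise standard deviation.
#' @param seed integer seed.
#' @return List with `datasets` (per dataset: `matrix` (probe-level
#'   [expression_matrix]), `labels`, `dataset_id`), `annotation`
#'   (probe -> gene [probe_annotation()]), `truth` (marker gene ids,
#'   platform effects, per-dataset labels).
#' @export
generate_cross_platform_suite <- function(
    per_dataset_sizes = c(206, 129, 459, 171, 149, 233),
    per_dataset_cases = c(0, 0, 78, 171, 76, 233),
    marker_genes = 5, n_genes = 300, effect_size = 2,
    platform_effects = NULL, multiprobe_rate = 0.3,
    noise_sd = 1, seed = 3) {
  if (any(per_dataset_sizes <= 0)) stop("dataset sizes must be positive")
  if (length(per_dataset_cases) != length(per_dataset_sizes))
    stop("per_dataset_cases must match per_dataset_sizes")
  if (any(per_dataset_cases > per_dataset_sizes))
    stop("cases cannot exceed dataset size")
  n_ds <- length(per_dataset_sizes)
  if (is.null(platform_effects))
    platform_effects <- rep_len(list(c(8, 2), c(6, 1), c(0, 1),
                                     c(0, 0.5), c(3, 1), c(0, 1)), n_ds)
  gene_ids <- sprintf("GENE%04d", seq_len(n_genes))
  marker <- gene_ids[seq_len(marker_genes)]
  with_seed(seed, {
    multi <- stats::runif(n_genes) < multiprobe_rate
    n_probe_per_gene <- ifelse(multi, sample(2:3, n_genes, replace = TRUE), 1L)
    probe_gene <- rep(seq_len(n_genes), n_probe_per_gene)
    probe_ids <- sprintf("%s_p%d", gene_ids[probe_gene],
                         unlist(lapply(n_probe_per_gene, seq_len)))
    annotation <- probe_annotation(
      stats::setNames(gene_ids[probe_gene], probe_ids))
    datasets <- vector("list", n_ds)
    for (d in seq_len(n_ds)) {
      n <- per_dataset_sizes[d]
      n_case <- per_dataset_cases[d]
      y <- c(rep(1L, n_case), rep(0L, n - n_case))
      g <- matrix(stats::rnorm(n * n_genes, sd = noise_sd), n, n_genes)
      if (n_case > 0)
        g[y == 1, seq_len(marker_genes)] <-
          g[y == 1, seq_len(marker_genes)] + effect_size * noise_sd
      # expand genes to probes: shared gene signal + probe noise
      v <- g[, probe_gene, drop = FALSE] +
        matrix(stats::rnorm(n * length(probe_gene), sd = 0.3 * noise_sd),
               n, length(probe_gene))
      eff <- platform_effects[[d]]
      v <- v * eff[2] + eff[1]
      dimnames(v) <- list(sprintf("D%d_S%04d", d, seq_len(n)), probe_ids)
      datasets[[d]] <- list(matrix = expression_matrix(v), labels = y,
                            dataset_id = sprintf("dataset%d", d))
    }
    list(datasets = datasets, annotation = annotation,
         truth = list(marker_genes = marker,
                      platform_effects = platform_effects,
                      effect_size = effect_size, seed = seed))
  })
}
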