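#' Read a gene-list file
#'
#' One gene/probe id per line; `#` starts a comment; blank lines ignored.
#' The packaged reference panel of literature KD genes is at
#' `system.file("extdata", "known_kd_genes.txt", package = "phasesom")`.
#'
#' @param path path to the file.
#' @return Character vector of ids.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

.write_json <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

.stage_file <- function(dir, name) file.path(dir, name)

#' Run the common-platform workflow end to end
#'
#' Curation (report-only outlier detection, covariance filter, zero
#' imputation) per phase, two-stage SOM clustering, hierarchical
#' super-clustering, per-phase ANOVA/FDR selection with cross-phase
#' intersection, then — when a control cohort is supplied — per-phase
#' quantile-normalized integration and a repeated stratified CV comparison
#' of the selected genes against a reference gene panel. Every stage's
#' output is persisted under `output_dir` with a JSON manifest of config,
#' seeds and file checksums.
#'
#' @param tensor a `phase_tensor` of case samples.
#' @param controls optional control [expression_matrix] (same probe
#'   universe) for the comparison stage.
#' @param known_genes character vector: the reference gene panel; `NULL`
#'   skips the comparison of panels and evaluates only the selected set.
#' @param som1,som2 first- and second-stage [som_params()]; the master seed
#'   is `som1$seed`. The first stage defaults to the stiff schedule of
#'   [per_phase_clustering()].
#' @param cut_k number of super-clusters (default 4).
#' @param alpha FDR level (default 0.01).
#' @param cv_k,cv_repeats CV folds and repeats.
#' @param model_specs boosting models to evaluate.
#' @param contamination,covariance_quantile curation settings.
#' @param output_dir directory for persisted outputs; `NULL` keeps results
#'   in memory only.
#' @return List with `curation`, `clustering` (a `phase_label_matrix`),
#'   `selection`, `evaluation` (per model x gene set, when controls given),
#'   `manifest`.
#' @export
run_workflow <- function(tensor, controls = NULL, known_genes = NULL,
                         som1 = som_params(initial_radius = 2.5,
                                           final_radius = 1.5),
                         som2 = som_params(),
                         cut_k = 4, alpha = 0.01, cv_k = 10,
                         cv_repeats = 10,
                         model_specs = c("adaboost", "gradboost"),
                         contamination = 0.05, covariance_quantile = NULL,
                         output_dir = NULL) {
  master <- som1$seed
  # --- curation, per phase -------------------------------------------------
  curated <- list()
  reports <- list()
  for (ph in tensor$phases) {
    cur <- curate(tensor$matrices[[ph]], contamination = contamination,
                  covariance_quantile = covariance_quantile,
                  seed = derive_seed(master, 30L + match(ph, tensor$phases)))
    curated[[ph]] <- cur$matrix
    reports[[ph]] <- cur$report
  }
  tensor_cur <- assemble_phase_tensor(curated)
  # --- two-stage clustering ------------------------------------------------
  clustering <- two_stage_clustering(tensor_cur, params = som1,
                                     second_params = som2, cut_k = cut_k)
  # --- feature selection ---------------------------------------------------
  selection <- phase_feature_selection(tensor_cur, clustering$super_labels,
                                       alpha = alpha)
  # --- comparison ----------------------------------------------------------
  evaluation <- NULL
  if (!is.null(controls) && length(selection$final_set)) {
    ctrl_cur <- impute_missing_zero(controls)
    gene_sets <- list(proposed = selection$final_set)
    if (!is.null(known_genes)) gene_sets$known <- known_genes
    evaluation <- list()
    for (ph in tensor_cur$phases) {
      # normalize over the full shared gene universe (normalizing only the
      # handful of panel genes would collapse every sample onto the same
      # few reference values), then restrict to each panel
      common <- intersect(em_probe_ids(curated[[ph]]),
                          em_probe_ids(ctrl_cur))
      case_m <- expression_matrix(em_values(curated[[ph]])[, common,
                                                           drop = FALSE])
      ctrl_m <- expression_matrix(em_values(ctrl_cur)[, common,
                                                      drop = FALSE])
      ref <- pooled_quantile_reference(list(case_m, ctrl_m))
      case_n <- quantile_normalize(case_m, paste0("case_", ph),
                                   reference = ref)$matrix
      ctrl_n <- quantile_normalize(ctrl_m, "controls",
                                   reference = ref)$matrix
      datasets <- lapply(gene_sets, function(gs)
        integrate_cohorts(case_n, list(ctrl_n), gs,
                          case_id = paste0("case_", ph),
                          control_ids = "controls"))
      evaluation[[ph]] <- if (length(datasets) == 2) {
        compare_gene_sets(datasets$proposed, datasets$known,
                          model_specs = model_specs, k = cv_k,
                          repeats = cv_repeats,
                          seed = derive_seed(master, 40L))
      } else {
        lapply(stats::setNames(model_specs, model_specs), function(spec)
          list(a = repeated_stratified_cv(datasets$proposed$x,
                                          datasets$proposed$y, spec,
                                          k = cv_k, repeats = cv_repeats,
                                          seed = derive_seed(master, 40L))))
      }
    }
  }
  result <- list(curation = reports, clustering = clustering,
                 selection = selection, evaluation = evaluation)
  result$manifest <- .persist_run(result, tensor_cur, output_dir,
                                  config = list(
                                    master_seed = master, cut_k = cut_k,
                                    alpha = alpha, cv_k = cv_k,
                                    cv_repeats = cv_repeats,
                                    grid = c(som1$rows, som1$cols),
                                    contamination = contamination,
                                    covariance_quantile = covariance_quantile))
  result
}

.persist_run <- function(result, tensor, output_dir, config) {
  manifest <- list(config = config, created = format(Sys.time()),
                   files = list())
  if (is.null(output_dir)) return(manifest)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  cl <- result$clustering
  lab <- data.frame(patient = cl$patient_ids, cl$labels,
                    node = unname(cl$second_stage_labels),
                    super = unname(cl$super_labels))
  utils::write.table(lab, .stage_file(output_dir, "label_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ftab <- Reduce(function(a, b) merge(a, b, by = "probe_id"),
                 lapply(tensor$phases, function(ph) {
                   t <- result$selection$per_phase[[ph]]$table
                   names(t)[-1] <- paste0(names(t)[-1], "_", ph)
                   t
                 }))
  utils::write.table(ftab, .stage_file(output_dir, "anova_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(result$selection$final_set,
             .stage_file(output_dir, "final_gene_set.txt"))
  if (!is.null(result$evaluation)) {
    rows <- list()
    for (ph in names(result$evaluation))
      for (spec in names(result$evaluation[[ph]])) {
        cmp <- result$evaluation[[ph]][[spec]]
        for (side in intersect(c("a", "b"), names(cmp))) {
          m <- cmp[[side]]$metrics
          rows[[length(rows) + 1L]] <- data.frame(
            phase = ph, model = spec,
            gene_set = if (side == "a") "proposed" else "known",
            t(m["mean", ]), check.names = FALSE)
        }
      }
    utils::write.table(do.call(rbind, rows),
                       .stage_file(output_dir, "evaluation_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  files <- list.files(output_dir, full.names = TRUE)
  manifest$files <- lapply(stats::setNames(files, basename(files)),
                           function(f) unname(tools::md5sum(f)))
  .write_json(manifest, .stage_file(output_dir, "manifest.json"))
  manifest
}

#' Run the cross-platform comparison workflow
#'
#' Per dataset: median probe-to-gene collapse, zero imputation, and
#' quantile normalization restricted to each gene panel against the pooled
#' average-quantile reference of all datasets (each dataset transformed
#' individually, one common target distribution — without the shared
#' reference the platform location/scale shifts would survive
#' normalization); then integration into one labeled dataset per panel and
#' a repeated stratified CV comparison of the proposed vs the reference
#' genes.
#'
#' @param suite list as produced by [generate_cross_platform_suite()]:
#'   `datasets` (each with `matrix`, `labels`, `dataset_id`) and
#'   `annotation`.
#' @param proposed_genes,known_genes character gene panels.
#' @param exclude_samples optional character sample ids dropped before
#'   integration (e.g. flagged incomplete cases).
#' @param model_specs,cv_k,cv_repeats,seed CV settings.
#' @return List with `datasets_integrated` (per panel: `x`, `y`, `source`),
#'   `comparison` (per model: reports + deltas), `n_samples`.
#' @export
run_cross_platform <- function(suite, proposed_genes, known_genes,
                               exclude_samples = NULL,
                               model_specs = c("adaboost", "gradboost"),
                               cv_k = 10, cv_repeats = 10, seed = 1) {
  # collapse, impute and exclude per dataset; normalize each dataset over
  # the full shared gene universe against the pooled reference, then
  # restrict to the panels
  mats <- list(); labs <- list()
  for (d in suite$datasets) {
    m <- impute_missing_zero(
      collapse_probes_to_genes(d$matrix, suite$annotation))
    keep <- !(em_sample_ids(m) %in% exclude_samples)
    mats[[d$dataset_id]] <- expression_matrix(
      em_values(m)[keep, , drop = FALSE])
    labs[[d$dataset_id]] <- d$labels[keep]
  }
  common <- Reduce(intersect, lapply(mats, em_probe_ids))
  for (panel in list(proposed = proposed_genes, known = known_genes)) {
    miss <- setdiff(panel, common)
    if (length(miss)) {
      culprit <- names(mats)[vapply(mats, function(m)
        any(!(miss %in% em_probe_ids(m))), TRUE)][1]
      stop(sprintf("dataset '%s' is missing required gene(s): %s",
                   culprit, paste(miss, collapse = ", ")))
    }
  }
  mats <- lapply(mats, function(m)
    expression_matrix(em_values(m)[, common, drop = FALSE]))
  ref <- pooled_quantile_reference(mats)
  mats <- stats::setNames(lapply(names(mats), function(id)
    quantile_normalize(mats[[id]], id, reference = ref)$matrix),
    names(mats))
  per_panel <- lapply(list(proposed = proposed_genes, known = known_genes),
                      function(genes) {
    x <- do.call(rbind, lapply(mats, function(m)
      em_values(m)[, genes, drop = FALSE]))
    list(x = x, y = unlist(labs, use.names = FALSE),
         source = rep(names(mats),
                      vapply(mats, function(m) nrow(em_values(m)), 1L)))
  })
  if (length(unique(per_panel$proposed$y)) < 2)
    stop("integrated dataset must contain both classes")
  comparison <- compare_gene_sets(per_panel$proposed, per_panel$known,
                                  model_specs = model_specs, k = cv_k,
                                  repeats = cv_repeats, seed = seed)
  list(datasets_integrated = per_panel, comparison = comparison,
       n_samples = length(per_panel$proposed$y))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 is
#' identical partitions, 0 is the chance level. Used to score recovered
#' super-clusters against planted groups.
#'
#' @param a,b integer label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
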