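#!/usr/bin/env Rscript

# Step 1 — simulate the study cohorts.
#
# Builds the synthetic analogue of the study design: a 20-patient case
# cohort observed at three clinical phases (Acute, Subacute, Convalescent)
# with four planted patient subgroups (sizes 6/5/2/7) and five
# phase-consistent marker genes at effect size 3 among 2,000 probes; a
# 67-sample control cohort on the same probe universe; and a six-dataset
# cross-platform suite (1,347 samples, 558 cases) with per-platform
# location/scale shifts and multi-probe genes. Later steps regenerate the
# data deterministically from the seeds recorded here, so nothing large is
# written to disk.

suppressMessages(library(phasesom))

master_seed <- 20210524L
config <- list(
  master_seed = master_seed,
  case_seed = derive_seed(master_seed, 1),
  control_seed = derive_seed(master_seed, 2),
  xplat_seed = derive_seed(master_seed, 3),
  som_seed = derive_seed(master_seed, 7),
  n_patients = 20, n_probes = 2000, group_sizes = c(6, 5, 2, 7),
  n_markers = 5, effect_size = 3, n_controls = 67,
  xplat_sizes = c(206, 129, 459, 171, 162, 233),
  xplat_cases = c(0, 0, 78, 171, 89, 233), xplat_excluded = 13)

dir.create("results", showWarnings = FALSE)
jsonlite::write_json(config, "results/cohort_config.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cc <- generate_case_cohort(
  n_patients = config$n_patients, n_probes = config$n_probes,
  group_sizes = config$group_sizes, n_markers = config$n_markers,
  effect_size = config$effect_size, seed = config$case_seed)
ctrl <- generate_control_cohort(config$n_controls, config$n_probes,
                                seed = config$control_seed)

cat("case tensor:", paste(dim(cc$tensor$matrices$A), collapse = " x "),
    "x", length(cc$tensor$phases), "phases\n")
cat("planted groups:",
    paste(table(cc$truth$super_cluster_assignment), collapse = "/"), "\n")
cat("marker probes:", paste(cc$truth$marker_probes, collapse = ", "), "\n")
cat("control cohort:", paste(dim(ctrl), collapse = " x "), "\n")

jsonlite::write_json(
  list(super_cluster_assignment = as.list(cc$truth$super_cluster_assignment),
       marker_probes = cc$truth$marker_probes,
       phase_specific_probes = cc$truth$phase_specific_probes,
       effect_size = cc$truth$effect_size),
  "results/planted_truth.json", auto_unbox = TRUE, pretty = TRUE)

# a small excerpt exercises the delimited-matrix round trip
excerpt <- expression_matrix(
  em_values(cc$tensor$matrices$A)[, 1:50, drop = FALSE])
write_expression_matrix(excerpt, "results/case_phaseA_first50probes.tsv")
cat("wrote results/cohort_config.json, results/planted_truth.json and a",
    "phase-A excerpt\n")
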