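# phasesom

Biomarker discovery from **time-series (three-phase) gene expression
cohorts** by two-stage self-organizing-map clustering and FDR-controlled
per-phase feature selection — the computational setting of Kawasaki
disease (KD), a pediatric vasculitis sampled at the Acute, Subacute and
Convalescent phase, whose diagnosis still lacks a molecular marker.

The workflow, end to end:

1. **Curation** — zero-imputation of missing cells, consensus multivariate
   outlier detection (isolation forest + local outlier factor,
   report-only by default), optional high-covariance gene screening.
2. **Inter-phase clustering** — one 3x3 SOM per clinical phase, trained by
   competitive learning: draw an input `x(q)`, find the best matching unit
   `u = argmin_x ||x(q) − w_x||`, update every node
   `w_x ← w_x + U(u,x,i) γ(i) (x(q) − w_x)` with a decaying learning
   coefficient `γ(i)` and shrinking Gaussian neighborhood `U`.
3. **Intra-phase clustering** — a second 3x3 SOM over each patient's
   per-phase label triple `L_T = L_A ∪ L_SA ∪ L_C` (one-hot encoded);
   empty nodes are pruned and the surviving prototypes are merged by
   hierarchical clustering (average linkage, Euclidean distances) with a
   dendrogram cut into four **super-clusters**.
4. **Feature selection** — per phase, every probe is scored by one-way
   ANOVA against the super-cluster labels, `F = MST/MSE` on
   `(N−1, n−N)` degrees of freedom, Benjamini–Hochberg adjusted at FDR
   α = 0.01; the proposed panel is the **intersection of the three
   per-phase significant sets**.
5. **Comparison** — the proposed panel versus a reference gene panel,
   each integrated with a control cohort (median probe→gene collapse,
   quantile normalization against a pooled average-quantile reference),
   classified by discrete AdaBoost and regularized gradient-boosted trees
   under repeated stratified 10-fold cross-validation (accuracy,
   sensitivity, specificity, AUC).

A synthetic-cohort generator with planted ground truth (super-cluster
structure, phase-consistent markers, platform shifts, multi-probe genes)
makes every stage testable without external data.

## Worked example

Simulate the study layout (20 patients in planted groups of 6/5/2/7, five
phase-consistent marker probes at effect size 3 among 2,000) and run the
discovery stages:

```r
library(phasesom)

cc <- generate_case_cohort(seed = derive_seed(20210524, 1))
tn <- assemble_phase_tensor(lapply(cc$tensor$matrices, impute_missing_zero))
cl <- two_stage_clustering(
  tn, params = som_params(seed = derive_seed(20210524, 7),
                          initial_radius = 2.5, final_radius = 1.5))
cl
#> phase_label_matrix: 20 patients, 4 super-clusters (sizes 6/5/2/7)
table(cl$second_stage_labels)       # occupied second-stage nodes
#> 1 2 3 7 9
#> 2 1 6 6 5

sel <- phase_feature_selection(tn, cl$super_labels, alpha = 0.01)
sel$final_set
#> [1] "probe00001" "probe00002" "probe00003" "probe00004" "probe00005"
adjusted_rand_index(cl$super_labels, cc$truth$super_cluster_assignment)
#> [1] 1
```

Four of the nine second-stage nodes are empty (pruned), the four
super-clusters reproduce the planted 6/5/2/7 patient subgroups exactly
(adjusted Rand index 1), and the cross-phase intersection returns
precisely the five planted markers — e.g. their phase-A F statistics
range from 31.3 to 83.6 against a Benjamini–Hochberg cutoff near
F ≈ 15. Marker recovery is seed-dependent at these conditions; the
methods vignette (`vignettes/two-stage-som-workflow.Rmd`) quantifies the
recovery rate and explains the architectural bound.

The numbered drivers under `analysis/` run the same stages at the study
scale plus the control-cohort and cross-platform comparisons
(`Rscript analysis/01_simulate_cohorts.R`, then `02` … `05`), writing
their tables under `results/`. On the recorded master seed the proposed
panel reaches AUC 0.96–1.00 across phases and 1.00 on the integrated
1,347-sample cross-platform cohort, against ~0.5 for an equal-size null
reference panel.

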