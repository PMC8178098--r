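#' First-stage (inter-phase) patient clustering
#'
#' Trains one SOM per clinical phase on that phase's patients x probes
#' matrix and records each patient's cluster (BMU node) per phase, giving
#' the patients x phases label matrix that the second stage clusters.
#' Per-phase seeds are derived from `params$seed` via [derive_seed()] with
#' fixed offsets, so a run is reproducible from the master seed.
#'
#' The default first-stage schedule keeps the map in the stiff ("elastic")
#' regime — radius decaying only from 2.5 (about the grid diameter) to 1.5 —
#' because with far more probes than patients each prototype must stay an
#' average over many samples for the weak group signal to survive the
#' probe-level noise; a sharply annealed map degenerates into a noise-driven
#' vector quantizer of individual patients.
#'
#' @param tensor a `phase_tensor` (see [assemble_phase_tensor()]).
#' @param params a [som_params()]; `params$seed` is the master seed.
#' @return List with `labels` (integer matrix, rows = patients, columns
#'   `A`, `SA`, `C`), `models` (one `som_model` per phase),
#'   `patient_ids`.
#' @export
per_phase_clustering <- function(tensor,
                                 params = som_params(initial_radius = 2.5,
                                                     final_radius = 1.5)) {
  stopifnot(inherits(tensor, "phase_tensor"))
  phases <- tensor$phases
  models <- vector("list", length(phases))
  names(models) <- phases
  labels <- NULL
  for (k in seq_along(phases)) {
    m <- tensor$matrices[[k]]
    p <- params
    p$seed <- derive_seed(params$seed, 10L + k)
    v <- em_values(m)
    if (anyNA(v)) stop("phase ", phases[k],
                       " contains missing values; curate first")
    # canonical sample order, so results are equivariant under permutation
    ord <- order(rownames(v))
    fit <- train_som(v[ord, , drop = FALSE], p)
    models[[k]] <- fit
    lab <- assign_clusters(fit, v[ord, , drop = FALSE])
    labels <- cbind(labels, lab[match(rownames(v), rownames(v)[ord])])
  }
  colnames(labels) <- phases
  rownames(labels) <- em_sample_ids(tensor$matrices[[1]])
  list(labels = labels, models = models,
       patient_ids = rownames(labels))
}

#' Second-stage (intra-phase) SOM over per-phase labels
#'
#' Clusters the patients' 3-dimensional rows of per-phase cluster labels
#' with an additional SOM, projecting the three per-phase clustermaps into
#' one. By default labels enter one-hot encoded (`encoding = "onehot"`, one
#' indicator block per phase), under which squared Euclidean distance
#' between two patients counts the phases on which their clusters disagree
#' — a proper consensus metric. `encoding = "integer"` feeds the raw node
#' indices instead, which imposes an artificial ordering on cluster numbers
#' (node 3 is no closer to node 2 than to node 9) and empirically recovers
#' planted structure much less reliably.
#'
#' @param labels integer matrix from [per_phase_clustering()].
#' @param params a [som_params()]; its seed is used directly.
#' @param encoding `"onehot"` (default) or `"integer"`.
#' @return List with `model` (`som_model`), `second_stage_labels` (node per
#'   patient), `encoding`.
#' @export
second_stage_som <- function(labels, params = som_params(),
                             encoding = c("onehot", "integer")) {
  encoding <- match.arg(encoding)
  x <- if (encoding == "integer") {
    storage.mode(labels) <- "double"
    labels
  } else {
    n_nodes <- max(labels)
    do.call(cbind, lapply(seq_len(ncol(labels)), function(j) {
      m <- matrix(0, nrow(labels), n_nodes)
      m[cbind(seq_len(nrow(labels)), labels[, j])] <- 1
      m
    }))
  }
  rownames(x) <- rownames(labels)
  ord <- if (is.null(rownames(x))) seq_len(nrow(x)) else order(rownames(x))
  fit <- train_som(x[ord, , drop = FALSE], params)
  lab <- assign_clusters(fit, x)  # model fixed; order-free
  names(lab) <- rownames(labels)
  list(model = fit, second_stage_labels = lab, encoding = encoding)
}

#' Discard empty second-stage clusters
#'
#' Grid nodes to which no patient maps are dropped from further analysis;
#' the surviving nodes are the prototypes handed to super-clustering.
#'
#' @param model a trained `som_model`.
#' @param labels integer node labels per patient.
#' @return List with `prototype_ids` (surviving node indices),
#'   `prototype_weights` (their weight vectors), `member_counts` (named
#'   count per surviving node).
#' @export
prune_empty_clusters <- function(model, labels) {
  counts <- table(factor(labels, levels = seq_len(nrow(model$weights))))
  survivors <- as.integer(names(counts)[counts > 0])
  stopifnot(length(survivors) >= 1)  # every patient has a BMU
  list(prototype_ids = survivors,
       prototype_weights = model$weights[survivors, , drop = FALSE],
       member_counts = counts[counts > 0])
}

#' Merge prototypes into super-clusters
#'
#' Agglomerative hierarchical clustering on the Euclidean distances between
#' the surviving prototype weight vectors, cut into `cut_k` groups
#' (default 4). Patients inherit their prototype's super-cluster;
#' super-clusters are renumbered 1..`cut_k` by first patient occurrence.
#'
#' @param pruned output of [prune_empty_clusters()].
#' @param labels per-patient second-stage node labels.
#' @param cut_k number of super-clusters (<= number of survivors).
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @return List with `super_labels` (named integer per patient),
#'   `prototype_super` (super-cluster per prototype id), `hclust` (merge
#'   history), `dist` (prototype distance matrix), `cut_k`.
#' @export
super_cluster <- function(pruned, labels, cut_k = 4, linkage = "average") {
  k_surv <- length(pruned$prototype_ids)
  if (cut_k > k_surv)
    stop("cut_k (", cut_k, ") exceeds surviving prototypes (", k_surv, ")")
  d <- stats::dist(pruned$prototype_weights)
  if (k_surv == 1L) {
    proto_groups <- 1L
  } else {
    hc <- stats::hclust(d, method = linkage)
    proto_groups <- stats::cutree(hc, k = cut_k)
  }
  names(proto_groups) <- pruned$prototype_ids
  raw <- proto_groups[as.character(labels)]
  # renumber by first patient occurrence so numbering is reproducible
  remap <- stats::setNames(seq_along(unique(raw)), unique(raw))
  super <- as.integer(remap[as.character(raw)])
  names(super) <- names(labels)
  list(super_labels = super,
       prototype_super = as.integer(remap[as.character(proto_groups)]),
       hclust = if (k_surv > 1L) hc else NULL,
       dist = as.matrix(d), cut_k = cut_k)
}

#' Run the full two-stage clustering
#'
#' First-stage per-phase SOMs, the label matrix, the second-stage SOM over
#' it, empty-node pruning, and hierarchical super-clustering — the complete
#' patient-subgrouping stage in one call.
#'
#' @param tensor a `phase_tensor`.
#' @param params first-stage [som_params()]; the master seed lives here.
#' @param second_params second-stage [som_params()]; its seed is overridden
#'   by a derivation from the master seed.
#' @param cut_k number of super-clusters.
#' @param encoding label encoding for the second stage.
#' @param linkage super-cluster linkage.
#' @return A `phase_label_matrix`: list with `patient_ids`, `labels`
#'   (per-phase), `second_stage_labels`, `super_labels`, plus `models`,
#'   `pruned`, `tree`.
#' @export
two_stage_clustering <- function(tensor,
                                 params = som_params(initial_radius = 2.5,
                                                     final_radius = 1.5),
                                 second_params = som_params(),
                                 cut_k = 4,
                                 encoding = c("onehot", "integer"),
                                 linkage = "average") {
  encoding <- match.arg(encoding)
  stage1 <- per_phase_clustering(tensor, params)
  second_params$seed <- derive_seed(params$seed, 20L)
  stage2 <- second_stage_som(stage1$labels, second_params, encoding)
  pruned <- prune_empty_clusters(stage2$model, stage2$second_stage_labels)
  sc <- super_cluster(pruned, stage2$second_stage_labels, cut_k, linkage)
  structure(list(patient_ids = stage1$patient_ids,
                 labels = stage1$labels,
                 second_stage_labels = stage2$second_stage_labels,
                 super_labels = sc$super_labels,
                 models = list(stage1 = stage1$models,
                               stage2 = stage2$model),
                 pruned = pruned, tree = sc),
            class = "phase_label_matrix")
}

#' @export
print.phase_label_matrix <- function(x, ...) {
  cat(sprintf("phase_label_matrix: %d patients, %d super-clusters (sizes %s)\n",
              length(x$patient_ids), max(x$super_labels),
              paste(table(x$super_labels), collapse = "/")))
  invisible(x)
}
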