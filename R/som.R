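#' Training schedule for a rectangular self-organizing map
#'
#' The map is a `rows x cols` rectangular grid of weight vectors trained by
#' competitive learning: at each step a random input is drawn, its best
#' matching unit (BMU, the node with the smallest Euclidean distance) is
#' found, and every node is pulled toward the input by
#' `w <- w + U(bmu, node, i) * gamma(i) * (x - w)`, where `gamma(i)` is a
#' monotonically decreasing learning coefficient and `U` a neighborhood
#' function of grid distance that shrinks over time.
#'
#' Defaults: 3x3 grid; `gamma` decays exponentially from `gamma0 = 0.5` to
#' `gammaT = 0.01` at step `T` (a `"linear"` schedule `gamma0 * (1 - i/T)`
#' is available). The small final rate matters: prototypes must settle into
#' local averages of their receptive fields rather than track the last
#' sample drawn, otherwise high-dimensional noise swamps weak cluster
#' structure. Gaussian neighborhood `exp(-d_grid^2 / (2 sigma(i)^2))` (a
#' `"bubble"` hard cut-off is available) with `sigma` decaying exponentially
#' from `max(rows, cols)/2` to 0.5 at step `T`; `T = 500 * n_inputs`
#' single-sample steps unless set.
#'
#' @param rows,cols grid dimensions (`rows * cols >= 2`).
#' @param max_iterations total single-sample steps `T`; `NULL` means
#'   `500 * n_inputs`, resolved at training time.
#' @param initial_learning_rate `gamma(0)` in (0, 1].
#' @param final_learning_rate `gamma(T)` for the exponential schedule.
#' @param learning_decay `"exponential"` or `"linear"`.
#' @param neighborhood_kind `"gaussian"` or `"bubble"`.
#' @param initial_radius `sigma(0)` in grid-distance units; `NULL` means
#'   `max(rows, cols) / 2`.
#' @param final_radius `sigma(T)`.
#' @param seed integer seed.
#' @param convergence_tol stop early when the maximum absolute weight change
#'   over one full epoch (`n_inputs` steps) falls below this.
#' @param init weight initialization, `"sample"` (random input rows) or
#'   `"uniform"` (uniform within per-dimension data range); see
#'   [init_grid()].
#' @return A `som_params` list.
#' @export
som_params <- function(rows = 3, cols = 3, max_iterations = NULL,
                       initial_learning_rate = 0.5,
                       final_learning_rate = 0.01,
                       learning_decay = c("exponential", "linear"),
                       neighborhood_kind = c("gaussian", "bubble"),
                       initial_radius = NULL, final_radius = 0.5,
                       seed = 1, convergence_tol = 1e-9,
                       init = c("sample", "uniform")) {
  learning_decay <- match.arg(learning_decay)
  neighborhood_kind <- match.arg(neighborhood_kind)
  init <- match.arg(init)
  if (rows < 1 || cols < 1 || rows * cols < 2)
    stop("grid must have at least 2 nodes")
  if (initial_learning_rate <= 0 || initial_learning_rate > 1)
    stop("initial_learning_rate must be in (0, 1]")
  if (is.null(initial_radius)) initial_radius <- max(rows, cols) / 2
  if (final_learning_rate <= 0 || final_learning_rate > initial_learning_rate)
    stop("final_learning_rate must be in (0, initial_learning_rate]")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 max_iterations = max_iterations,
                 initial_learning_rate = initial_learning_rate,
                 final_learning_rate = final_learning_rate,
                 learning_decay = learning_decay,
                 neighborhood_kind = neighborhood_kind,
                 initial_radius = initial_radius,
                 final_radius = final_radius,
                 seed = as.integer(seed),
                 convergence_tol = convergence_tol,
                 init = init),
            class = "som_params")
}

# row-major grid coordinates, 1-based node indices
.som_grid_coords <- function(rows, cols) {
  cbind(row = rep(seq_len(rows), each = cols),
        col = rep(seq_len(cols), times = rows))
}

#' Initialize a SOM grid
#'
#' The grid is initialized on the input data: with `method = "sample"`
#' (default) each node's weight vector is a randomly drawn input row (drawn
#' with replacement when nodes outnumber inputs), which starts the map
#' inside the data cloud; `method = "uniform"` draws each coordinate
#' uniformly within the per-dimension data range (a constant dimension
#' yields a constant weight coordinate). Standard normal weights are used
#' when no data are supplied.
#'
#' @param rows,cols grid dimensions.
#' @param dim input dimension.
#' @param data optional matrix (rows = inputs).
#' @param seed integer seed.
#' @param method `"sample"` or `"uniform"` (ignored without data).
#' @return A `som_model`: `weights` (nodes x dim, row-major node order),
#'   `grid_coords`, `params`, `training_steps_run`, `quantization_error`.
#' @export
init_grid <- function(rows, cols, dim, data = NULL, seed = 1,
                      method = c("sample", "uniform")) {
  method <- match.arg(method)
  if (rows < 1 || cols < 1) stop("grid dimensions must be positive")
  if (dim < 1) stop("input dimension must be >= 1")
  n_nodes <- rows * cols
  w <- with_seed(seed, {
    if (is.null(data)) {
      matrix(stats::rnorm(n_nodes * dim), nrow = n_nodes)
    } else if (method == "sample") {
      data <- as.matrix(data)
      data[sample.int(nrow(data), n_nodes, replace = n_nodes > nrow(data)), ,
           drop = FALSE]
    } else {
      data <- as.matrix(data)
      lo <- apply(data, 2, min)
      hi <- apply(data, 2, max)
      u <- matrix(stats::runif(n_nodes * dim), nrow = n_nodes)
      sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
    }
  })
  structure(list(weights = w,
                 grid_coords = .som_grid_coords(rows, cols),
                 params = NULL,
                 training_steps_run = 0L,
                 quantization_error = NA_real_),
            class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  g <- x$grid_coords
  cat(sprintf("som_model: %dx%d grid, dim %d, %d steps, quantization error %s\n",
              max(g[, "row"]), max(g[, "col"]), ncol(x$weights),
              x$training_steps_run,
              format(x$quantization_error, digits = 4)))
  invisible(x)
}

#' Best matching unit
#'
#' Returns the node index (row-major, 1-based) with the smallest Euclidean
#' distance to `x`; ties break to the lowest index.
#'
#' @param model a `som_model`.
#' @param x numeric input vector of the model's dimension.
#' @return Integer node index.
#' @export
find_bmu <- function(model, x) {
  if (length(x) != ncol(model$weights))
    stop("input dimension ", length(x), " does not match model dimension ",
         ncol(model$weights))
  d2 <- rowSums(sweep(model$weights, 2, x, `-`)^2)
  which.min(d2)  # which.min takes the first of tied minima
}

.neighborhood <- function(grid_coords, bmu, sigma, kind) {
  d2 <- (grid_coords[, "row"] - grid_coords[bmu, "row"])^2 +
    (grid_coords[, "col"] - grid_coords[bmu, "col"])^2
  if (kind == "gaussian") exp(-d2 / (2 * sigma^2)) else as.numeric(d2 <= sigma^2)
}

.gamma_at <- function(p, i, T) {
  g0 <- p$initial_learning_rate
  if (p$learning_decay == "exponential")
    g0 * (p$final_learning_rate / g0)^(i / T)
  else g0 * (1 - i / T)
}

.sigma_at <- function(p, i, T) {
  s0 <- p$initial_radius
  sT <- p$final_radius
  s0 * (sT / s0)^(i / T)
}

#' Apply one competitive-learning update
#'
#' `w_y <- w_y + U(bmu, y, i) * gamma * (x - w_y)` for every node `y`, with
#' `U(bmu, bmu, i) = 1`. Only the weights change.
#'
#' @param model a `som_model`.
#' @param x input vector.
#' @param bmu node index of the best matching unit.
#' @param gamma learning coefficient at this step.
#' @param sigma neighborhood radius at this step.
#' @param kind `"gaussian"` or `"bubble"`.
#' @return The model with updated weights.
#' @export
update_weights <- function(model, x, bmu, gamma, sigma,
                           kind = "gaussian") {
  u <- .neighborhood(model$grid_coords, bmu, sigma, kind)
  coef <- u * gamma
  model$weights <- model$weights +
    coef * sweep(-model$weights, 2, x, `+`)
  model
}

#' Train a self-organizing map
#'
#' Iterates random input selection, BMU search, and the neighborhood update
#' with decaying learning rate and radius, stopping at `T` steps or when the
#' maximum absolute weight change over a full epoch (`n_inputs` steps) drops
#' below `convergence_tol`. The final quantization error (mean Euclidean
#' distance of inputs to their BMU) is recorded. Empty nodes (BMU of no
#' input) are legal outcomes.
#'
#' @param data numeric matrix, rows = input vectors.
#' @param params a [som_params()].
#' @return A trained `som_model` (with `epoch_qe`, the quantization error
#'   after each epoch, as an attribute-like list entry).
#' @export
train_som <- function(data, params = som_params()) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  n <- nrow(data)
  if (n < 1) stop("at least one input vector is required")
  T_steps <- params$max_iterations
  if (is.null(T_steps)) T_steps <- 500L * n
  model <- init_grid(params$rows, params$cols, ncol(data), data = data,
                     seed = params$seed, method = params$init)
  model$params <- params
  fit <- with_seed(derive_seed(params$seed, 1L),
    .som_train_cpp(data, model$weights,
                   model$grid_coords, as.numeric(T_steps),
                   params$initial_learning_rate,
                   params$final_learning_rate,
                   params$learning_decay == "linear",
                   params$initial_radius, params$final_radius,
                   params$neighborhood_kind == "gaussian",
                   params$convergence_tol))
  model$weights <- fit$weights
  model$training_steps_run <- fit$steps
  model$quantization_error <- .quantization_error(fit$weights, data)
  model$epoch_qe <- fit$epoch_qe
  model
}

.quantization_error <- function(W, data) {
  d2 <- outer(rowSums(data * data), rowSums(W * W), `+`) -
    2 * data %*% t(W)
  mean(sqrt(pmax(apply(d2, 1, min), 0)))
}

#' Assign inputs to SOM clusters
#'
#' Each input's label is its BMU node index (row-major, 1-based); each grid
#' cell is a cluster. Deterministic given the model.
#'
#' @param model a trained `som_model`.
#' @param data numeric matrix, rows = inputs, columns matching the model
#'   dimension.
#' @return Integer vector of node labels, one per input.
#' @export
assign_clusters <- function(model, data) {
  data <- as.matrix(data)
  if (ncol(data) != ncol(model$weights))
    stop("input dimension ", ncol(data), " does not match model dimension ",
         ncol(model$weights))
  W <- model$weights
  d2 <- outer(rowSums(data * data), rowSums(W * W), `+`) - 2 * data %*% t(W)
  apply(d2, 1, which.min)
}
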