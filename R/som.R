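#' Train a self-organizing map
#'
#' Overclusters cells into `grid_x * grid_y` phenotypically homogeneous
#' partitions (default 8 x 8 = 64 nodes); batch correction is then applied
#' independently within each partition. Training is online competitive
#' learning on a rectangular grid with a Gaussian neighborhood; the
#' neighborhood radius and learning rate both decay linearly over
#' `epochs` passes through the data. The codebook is initialized from
#' data rows sampled under `seed`, and the presentation order is likewise
#' seeded, so training is deterministic given (values, grid, seed).
#'
#' Grid-size guidance: the grid should slightly overcluster the expected
#' heterogeneity — err on the side of overclustering, since correction
#' within an overly fine partition is harmless while a partition mixing
#' distinct populations lets the adjustment blur biology.
#'
#' @param values A `normalized_matrix` (from [normalize_batches()]) or a
#'   plain numeric matrix, cells x markers.
#' @param grid_x,grid_y Grid dimensions (default 8 x 8).
#' @param seed Integer seed controlling initialization and presentation
#'   order.
#' @param epochs Passes over the data (default 10).
#' @param alpha Learning rate start/end (default 0.05 to 0.01).
#' @param radius Neighborhood radius start/end; defaults to
#'   `max(grid_x, grid_y) / 2` decaying to 0.5.
#' @return An object of class `som_model`: list with `codebook`
#'   (nodes x markers), `grid_x`, `grid_y`, `seed` and `training_params`.
#' @export
train_som <- function(values, grid_x = 8, grid_y = 8, seed = 473,
                      epochs = 10, alpha = c(0.05, 0.01),
                      radius = NULL) {
  X <- if (inherits(values, "normalized_matrix")) values$values else
    as.matrix(values)
  if (nrow(X) == 0 || ncol(X) == 0) stop("empty input", call. = FALSE)
  if (!all(is.finite(X))) stop("non-finite values in SOM input",
                               call. = FALSE)
  grid_x <- as.integer(grid_x); grid_y <- as.integer(grid_y)
  if (grid_x < 2 || grid_y < 2) stop("grid dimensions must be >= 2",
                                     call. = FALSE)
  k <- grid_x * grid_y
  if (nrow(X) < k) {
    warning("fewer cells (", nrow(X), ") than SOM nodes (", k, ")",
            call. = FALSE)
  }
  if (is.null(radius)) radius <- c(max(grid_x, grid_y) / 2, 0.5)
  init_order <- NULL
  with_seed(seed, {
    init_idx <- sample.int(nrow(X), k, replace = nrow(X) < k)
    init_order <- list(
      init = init_idx,
      order = unlist(lapply(seq_len(epochs),
                            function(e) sample.int(nrow(X)))) - 1L
    )
  })
  codes <- X[init_order$init, , drop = FALSE]
  codes <- matrix(as.double(codes), nrow = k)
  codebook <- som_train_cpp(X, codes, init_order$order, grid_x, grid_y,
                            alpha[1], alpha[2], radius[1], radius[2])
  colnames(codebook) <- colnames(X)
  structure(
    list(codebook = codebook, grid_x = grid_x, grid_y = grid_y,
         seed = seed,
         training_params = list(epochs = epochs, alpha = alpha,
                                radius = radius)),
    class = "som_model"
  )
}

#' @export
print.som_model <- function(x, ...) {
  cat("<som_model> ", x$grid_x, " x ", x$grid_y, " grid, ",
      ncol(x$codebook), " markers, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Assign cells to SOM nodes
#'
#' Labels each cell with the Euclidean-nearest codebook row; ties break to
#' the lowest node index. Every cell receives exactly one label in
#' `[1, grid_x * grid_y]`.
#'
#' @param model A `som_model` from [train_som()].
#' @param values A `normalized_matrix` or numeric matrix with the same
#'   marker dimension the model was trained on.
#' @return Integer vector of node labels, aligned with the rows of
#'   `values`.
#' @export
assign_nodes <- function(model, values) {
  stopifnot(inherits(model, "som_model"))
  X <- if (inherits(values, "normalized_matrix")) values$values else
    as.matrix(values)
  if (ncol(X) != ncol(model$codebook)) {
    stop("marker dimension (", ncol(X), ") does not match codebook (",
         ncol(model$codebook), ")", call. = FALSE)
  }
  as.integer(som_map_cpp(X, model$codebook))
}

#' Serialize / restore a SOM model
#'
#' Small JSON representation (codebook included as numbers) sufficient to
#' reproduce node assignments.
#'
#' @param model A `som_model`.
#' @param path Output JSON path.
#' @return `path` invisibly; `read_som_model()` returns the `som_model`.
#' @export
write_som_model <- function(model, path) {
  stopifnot(inherits(model, "som_model"))
  obj <- list(codebook = model$codebook, grid_x = model$grid_x,
              grid_y = model$grid_y, seed = model$seed,
              training_params = model$training_params,
              marker_names = colnames(model$codebook))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_som_model
#' @export
read_som_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  codebook <- matrix(as.double(obj$codebook),
                     nrow = obj$grid_x * obj$grid_y)
  colnames(codebook) <- obj$marker_names
  structure(
    list(codebook = codebook, grid_x = as.integer(obj$grid_x),
         grid_y = as.integer(obj$grid_y), seed = obj$seed,
         training_params = obj$training_params),
    class = "som_model"
  )
}
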