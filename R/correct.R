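#' Correction configuration
#'
#' @param norm_method `"scale"` (per-batch Z-score) or `"rank"`.
#' @param grid_x,grid_y SOM grid (default 8 x 8, i.e. 64 clusters).
#' @param covariate Optional name of a `cell_meta` column (typically
#'   `"condition"`) whose biological effect must be preserved.
#' @param seed Integer seed for SOM training.
#' @param mean_only Adjust batch locations only, leaving scales.
#' @return A `correction_config` list.
#' @export
correction_config <- function(norm_method = c("scale", "rank"),
                              grid_x = 8, grid_y = 8, covariate = NULL,
                              seed = 473, mean_only = FALSE) {
  norm_method <- match.arg(norm_method)
  if (grid_x < 2 || grid_y < 2) {
    stop("grid dimensions must be >= 2", call. = FALSE)
  }
  structure(list(norm_method = norm_method, grid_x = as.integer(grid_x),
                 grid_y = as.integer(grid_y), covariate = covariate,
                 seed = as.integer(seed), mean_only = isTRUE(mean_only)),
            class = "correction_config")
}

#' Validate a batch-correction design
#'
#' A correctable design needs at least two batches, and — when a
#' condition covariate is to be preserved — a non-confounded
#' batch/condition structure: at least one condition from each batch
#' must be present in at least one other batch. Fully confounded designs
#' (e.g., every case in batch 1, every control in batch 2) leave the
#' batch and condition effects inseparable.
#'
#' @param dataset A [cyto_dataset()].
#' @param covariate Optional `cell_meta` column name.
#' @return List with `ok` (logical), `n_batches`, `offending_batches`
#'   and `message`. Invisibly; a failed check also raises a classed
#'   error (`cytofuse_confounding_error`) unless `error = FALSE`.
#' @param error Raise on failure (default TRUE).
#' @export
check_design <- function(dataset, covariate = NULL, error = TRUE) {
  stopifnot(inherits(dataset, "cyto_dataset"))
  b <- batch_ids(dataset)
  ub <- sort(unique(b))
  report <- list(ok = TRUE, n_batches = length(ub),
                 offending_batches = character(), message = "ok")
  if (length(ub) < 2) {
    report$ok <- FALSE
    report$message <- "batch correction requires at least 2 batches"
  } else if (!is.null(covariate)) {
    cond <- dataset$cell_meta[[covariate]]
    if (is.null(cond)) {
      stop("covariate column '", covariate, "' not found in cell_meta",
           call. = FALSE)
    }
    cond_by_batch <- lapply(ub, function(bb)
      unique(stats::na.omit(cond[b == bb])))
    names(cond_by_batch) <- ub
    bad <- vapply(ub, function(bb) {
      others <- unique(unlist(cond_by_batch[setdiff(ub, bb)]))
      !any(cond_by_batch[[bb]] %in% others)
    }, logical(1))
    if (any(bad)) {
      report$ok <- FALSE
      report$offending_batches <- ub[bad]
      report$message <- paste0(
        "batch and ", covariate, " are confounded: batch(es) ",
        paste(ub[bad], collapse = ", "),
        " share no condition with any other batch")
    }
  }
  if (!report$ok && error) stop_confounded(report$message)
  invisible(report)
}

#' Partition cells for per-cluster correction
#'
#' Normalizes per batch (Z-score or rank), trains the SOM on the
#' normalized values under the configured seed, and assigns every cell a
#' node label. Labels index rows of the original expression matrix; the
#' normalized values are discarded after clustering.
#'
#' @param dataset A [cyto_dataset()].
#' @param config A [correction_config()].
#' @return Integer vector of node labels in
#'   `[1, grid_x * grid_y]`, one per cell, with the trained `som_model`
#'   attached as attribute `"som_model"`.
#' @export
create_partition <- function(dataset, config = correction_config()) {
  norm <- normalize_batches(dataset, config$norm_method)
  model <- train_som(norm, grid_x = config$grid_x, grid_y = config$grid_y,
                     seed = config$seed)
  labels <- assign_nodes(model, norm)
  attr(labels, "som_model") <- model
  labels
}

#' Per-cluster batch correction
#'
#' Applies the empirical Bayes location/scale adjustment
#' ([combat_cluster()]) independently to the original ArcSinh values of
#' each SOM cluster (ascending node index; clusters are independent, so
#' results do not depend on processing order). Afterwards every marker
#' is capped to its global input range, so correction never extrapolates
#' beyond observed expression. Cell order, marker names and metadata are
#' unchanged.
#'
#' @param dataset A [cyto_dataset()].
#' @param labels Integer node labels aligned with `dataset` rows.
#' @param config A [correction_config()].
#' @return A corrected [cyto_dataset()]; attribute `"cluster_log"` holds
#'   per-cluster warning records `{cluster, message}`.
#' @export
batch_correct <- function(dataset, labels, config = correction_config()) {
  stopifnot(inherits(dataset, "cyto_dataset"))
  labels <- as.integer(labels)
  if (length(labels) != nrow(dataset$exprs)) {
    stop("labels must align with dataset rows", call. = FALSE)
  }
  Y <- dataset$exprs
  cov_vals <- if (!is.null(config$covariate)) {
    v <- dataset$cell_meta[[config$covariate]]
    if (is.null(v)) stop("covariate column '", config$covariate,
                         "' not found", call. = FALSE)
    v
  } else NULL
  corrected <- Y
  log <- list()
  for (node in sort(unique(labels))) {
    idx <- which(labels == node)
    res <- withCallingHandlers(
      combat_cluster(Y[idx, , drop = FALSE],
                     batches = batch_ids(dataset)[idx],
                     covariates = if (is.null(cov_vals)) NULL else
                       cov_vals[idx],
                     mean_only = config$mean_only),
      warning = function(w) {
        log[[length(log) + 1L]] <<- list(cluster = node,
                                         message = conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    corrected[idx, ] <- res
  }
  # cap per marker to the global input range
  lo <- apply(Y, 2, min)
  hi <- apply(Y, 2, max)
  corrected <- pmin(pmax(corrected,
                         matrix(lo, nrow(Y), ncol(Y), byrow = TRUE)),
                    matrix(hi, nrow(Y), ncol(Y), byrow = TRUE))
  out <- dataset
  out$exprs <- corrected
  attr(out, "cluster_log") <- log
  out
}

#' End-to-end batch correction
#'
#' Design validation, per-batch normalization, SOM partitioning and
#' per-cluster empirical Bayes adjustment in one call. Deterministic
#' given the dataset and config (the config seed drives the SOM).
#'
#' @param dataset A [cyto_dataset()].
#' @param config A [correction_config()].
#' @return List with `dataset` (corrected [cyto_dataset()]), `labels`
#'   (SOM node per cell) and `report` (config echo, cluster sizes,
#'   skipped-cluster log).
#' @export
correct <- function(dataset, config = correction_config()) {
  check_design(dataset, config$covariate)
  labels <- create_partition(dataset, config)
  corrected <- batch_correct(dataset, labels, config)
  log <- attr(corrected, "cluster_log")
  attr(corrected, "cluster_log") <- NULL
  report <- list(
    config = unclass(config),
    n_cells = nrow(dataset$exprs),
    n_markers = ncol(dataset$exprs),
    n_batches = length(unique(batch_ids(dataset))),
    cluster_sizes = as.list(table(labels)),
    warnings = log
  )
  list(dataset = corrected, labels = as.integer(labels), report = report)
}
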