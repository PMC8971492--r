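#' Per-batch normalization for co-clustering
#'
#' Before cells from different batches can be co-clustered, each batch's
#' marker distributions are put on a common scale. Two methods are
#' offered: Z-scores (`method = "scale"`), suited to low-variance batches
#' from the same instrument and panel, and scaled ranks
#' (`method = "rank"`), suited to high-variance or cross-platform batches
#' because ranks are invariant to any monotone distortion of a batch's
#' intensities. The normalized matrix is used only to train the
#' self-organizing map; corrected output is always computed from the
#' original ArcSinh values.
#'
#' @param dataset A [cyto_dataset()].
#' @param method `"scale"` (per-batch Z-score) or `"rank"` (per-batch
#'   average-tie ranks scaled to (0, 1]).
#' @return An object of class `normalized_matrix`: list with `values`
#'   (matrix aligned row-for-row with `dataset`) and `method`.
#' @export
normalize_batches <- function(dataset, method = c("scale", "rank")) {
  method <- match.arg(method)
  switch(method,
         scale = normalize_zscore(dataset),
         rank = normalize_rank(dataset))
}

new_normalized <- function(values, method) {
  structure(list(values = values, method = method),
            class = "normalized_matrix")
}

#' Per-batch Z-score normalization
#'
#' Within each batch, each marker is centered and scaled to unit standard
#' deviation (n-1 denominator). Markers constant within a batch, and
#' single-cell batches, map to zero.
#'
#' @inheritParams normalize_batches
#' @return A `normalized_matrix` with `method = "scale"`.
#' @export
normalize_zscore <- function(dataset) {
  stopifnot(inherits(dataset, "cyto_dataset"))
  ex <- dataset$exprs
  if (nrow(ex) == 0) stop("dataset has no cells", call. = FALSE)
  out <- ex
  for (b in unique(batch_ids(dataset))) {
    idx <- which(batch_ids(dataset) == b)
    sub <- ex[idx, , drop = FALSE]
    mu <- colMeans(sub)
    sdv <- apply(sub, 2, stats::sd)
    sdv[!is.finite(sdv) | sdv == 0] <- Inf  # constant or n=1 -> zeros
    out[idx, ] <- sweep(sweep(sub, 2, mu, "-"), 2, sdv, "/")
  }
  new_normalized(out, "scale")
}

#' Per-batch rank normalization
#'
#' Within each batch, each marker is replaced by its rank (average ranks
#' for ties), divided by the batch's cell count so values lie in (0, 1].
#'
#' @inheritParams normalize_batches
#' @return A `normalized_matrix` with `method = "rank"`.
#' @export
normalize_rank <- function(dataset) {
  stopifnot(inherits(dataset, "cyto_dataset"))
  ex <- dataset$exprs
  if (nrow(ex) == 0) stop("dataset has no cells", call. = FALSE)
  out <- ex
  for (b in unique(batch_ids(dataset))) {
    idx <- which(batch_ids(dataset) == b)
    n_b <- length(idx)
    out[idx, ] <- apply(ex[idx, , drop = FALSE], 2,
                        function(v) rank(v, ties.method = "average") / n_b)
  }
  new_normalized(out, "rank")
}
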