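#' Bin a marker distribution
#'
#' Fixed-width histogram over `[lo, hi]` (bin size 0.1 by default, on
#' the ArcSinh scale), normalized to total mass 1. Values outside the
#' range are clipped into the end bins.
#'
#' @param values Numeric vector (at least one value).
#' @param binsize Bin width.
#' @param range Length-2 numeric `c(lo, hi)`, `hi > lo`.
#' @return Numeric vector of bin masses summing to 1.
#' @export
bin_distribution <- function(values, binsize = 0.1, range) {
  if (length(values) == 0) stop("no values to bin", call. = FALSE)
  lo <- range[1]; hi <- range[2]
  if (!(hi > lo)) stop("range must satisfy hi > lo", call. = FALSE)
  n_bins <- max(1L, as.integer(ceiling((hi - lo) / binsize - 1e-9)))
  idx <- floor((values - lo) / binsize) + 1
  idx <- pmin(pmax(idx, 1), n_bins)
  tabulate(idx, nbins = n_bins) / length(values)
}

#' One-dimensional earth mover's distance between histograms
#'
#' Minimal transport cost between two histograms on a common grid of
#' bins, with ground distance equal to the number of bins apart. In one
#' dimension this equals the L1 distance between the cumulative
#' distributions, so the value is in bin units (1 bin = `binsize`
#' expression units).
#'
#' @param p,q Histograms over identical bins, each summing to 1.
#' @return Non-negative EMD in bin units.
#' @export
emd_1d <- function(p, q) {
  if (length(p) != length(q)) {
    stop("histograms must share the same bin structure", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    stop("histograms must each sum to 1", call. = FALSE)
  }
  sum(abs(cumsum(p - q)))
}

#' EMD reduction of a record table
#'
#' Summarizes an EMD table into the headline reduction statistic:
#' records where the uncorrected and corrected EMD are both below
#' `filter_threshold` are dropped (distributions already this close are
#' uninformative about correction), and over the surviving records
#' \deqn{reduction = \sum_i (EMD^{before}_i - EMD^{after}_i) /
#'       \sum_i EMD^{before}_i.}
#' A reduction of 1 means complete elimination of cross-batch EMD; 0
#' means none; negative values mean the correction increased it.
#'
#' @param emd_table Data frame with columns `emd_before`, `emd_after`.
#' @param filter_threshold Filter (default 2 bins); set 0 to keep all.
#' @return List with `reduction` (`NA` when no record survives the
#'   filter, flagged by `defined = FALSE`), `defined`, `n_used`.
#' @export
emd_reduction_score <- function(emd_table, filter_threshold = 2) {
  keep <- !(emd_table$emd_before < filter_threshold &
              emd_table$emd_after < filter_threshold)
  kept <- emd_table[keep, , drop = FALSE]
  if (nrow(kept) == 0) {
    return(list(reduction = NA_real_, defined = FALSE, n_used = 0L))
  }
  list(reduction = sum(kept$emd_before - kept$emd_after) /
         sum(kept$emd_before),
       defined = TRUE, n_used = nrow(kept))
}

#' MAD score of a record table
#'
#' Median over all records of the absolute change in median absolute
#' deviation: `median_i |MAD_before_i - MAD_after_i|`. A score of 0
#' means within-batch variability — the biological variance — is fully
#' preserved by the correction.
#'
#' @param mad_table Data frame with columns `mad_before`, `mad_after`.
#' @return The MAD score (numeric scalar).
#' @export
mad_score_from_table <- function(mad_table) {
  if (nrow(mad_table) == 0) return(NA_real_)
  stats::median(abs(mad_table$mad_before - mad_table$mad_after))
}

#' Cross-batch EMD evaluation of a correction
#'
#' For every SOM node x marker x unordered batch pair with cells on both
#' sides, computes the earth mover's distance between the two batches'
#' marker distributions in the uncorrected and the corrected data, then
#' summarizes with [emd_reduction_score()]. Histograms for a marker use
#' one common bin range (the global min/max over both datasets), so all
#' of that marker's comparisons are on identical bins.
#'
#' @param before,after Row-aligned [cyto_dataset()] objects
#'   (uncorrected / corrected).
#' @param labels SOM node labels shared by both (per the evaluation
#'   protocol, derived from the corrected data; see
#'   [evaluate_correction()]).
#' @param binsize Histogram bin width (default 0.1).
#' @param filter_threshold Drop records where both EMDs fall below this
#'   (default 2 bins).
#' @param min_cells Minimum cells per batch per node for a record.
#' @return List with `table` (record data frame), `reduction`,
#'   `defined`, `n_used`.
#' @export
evaluate_emd <- function(before, after, labels, binsize = 0.1,
                         filter_threshold = 2, min_cells = 1) {
  check_aligned(before, after, labels)
  b <- batch_ids(before)
  ub <- sort(unique(b))
  mk <- markers(before)
  recs <- list()
  for (m in mk) {
    rng <- range(c(before$exprs[, m], after$exprs[, m]))
    if (rng[2] <= rng[1]) rng[2] <- rng[1] + binsize
    for (node in sort(unique(labels))) {
      in_node <- labels == node
      for (i in seq_len(length(ub) - 1)) {
        for (j in seq((i + 1), length(ub))) {
          ci <- in_node & b == ub[i]
          cj <- in_node & b == ub[j]
          if (sum(ci) < min_cells || sum(cj) < min_cells) next
          eb <- emd_1d(
            bin_distribution(before$exprs[ci, m], binsize, rng),
            bin_distribution(before$exprs[cj, m], binsize, rng))
          ea <- emd_1d(
            bin_distribution(after$exprs[ci, m], binsize, rng),
            bin_distribution(after$exprs[cj, m], binsize, rng))
          recs[[length(recs) + 1L]] <- data.frame(
            node = node, marker = m, batch_i = ub[i], batch_j = ub[j],
            emd_before = eb, emd_after = ea, stringsAsFactors = FALSE)
        }
      }
    }
  }
  tab <- if (length(recs)) do.call(rbind, recs) else
    data.frame(node = integer(), marker = character(),
               batch_i = character(), batch_j = character(),
               emd_before = numeric(), emd_after = numeric())
  score <- emd_reduction_score(tab, filter_threshold)
  list(table = tab, reduction = score$reduction, defined = score$defined,
       n_used = score$n_used)
}

#' Within-batch MAD evaluation of a correction
#'
#' For every SOM node x marker x batch, computes the median absolute
#' deviation (consistency constant 1.4826) of the marker's expression
#' before and after correction, then summarizes with
#' [mad_score_from_table()]. Where the EMD reduction quantifies how much
#' inter-batch distance was removed, the MAD score quantifies how much
#' intra-batch (biological) variability was altered.
#'
#' @inheritParams evaluate_emd
#' @param mad_constant Scale constant passed to [stats::mad()].
#' @return List with `table` (records) and `score`.
#' @export
evaluate_mad <- function(before, after, labels, min_cells = 1,
                         mad_constant = 1.4826) {
  check_aligned(before, after, labels)
  b <- batch_ids(before)
  recs <- list()
  for (m in markers(before)) {
    for (node in sort(unique(labels))) {
      in_node <- labels == node
      for (bb in sort(unique(b))) {
        idx <- in_node & b == bb
        if (sum(idx) < min_cells) next
        recs[[length(recs) + 1L]] <- data.frame(
          node = node, marker = m, batch = bb,
          mad_before = stats::mad(before$exprs[idx, m],
                                  constant = mad_constant),
          mad_after = stats::mad(after$exprs[idx, m],
                                 constant = mad_constant),
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- if (length(recs)) do.call(rbind, recs) else
    data.frame(node = integer(), marker = character(),
               batch = character(), mad_before = numeric(),
               mad_after = numeric())
  list(table = tab, score = mad_score_from_table(tab))
}

check_aligned <- function(before, after, labels) {
  stopifnot(inherits(before, "cyto_dataset"),
            inherits(after, "cyto_dataset"))
  if (nrow(before$exprs) != nrow(after$exprs) ||
      !identical(markers(before), markers(after))) {
    stop("before/after datasets must be row-aligned with identical ",
         "markers", call. = FALSE)
  }
  if (length(labels) != nrow(before$exprs)) {
    stop("labels must align with dataset rows", call. = FALSE)
  }
  if (!identical(batch_ids(before), batch_ids(after))) {
    stop("before/after batch labels differ", call. = FALSE)
  }
}

#' Evaluate a correction with the standard protocol
#'
#' Convenience wrapper implementing the evaluation protocol: a fresh SOM
#' (default 8 x 8) is trained on the *corrected* expression, its labels
#' are transferred to the uncorrected data so each cell carries the same
#' label in both, and the EMD reduction and MAD score are computed over
#' those shared labels.
#'
#' @param before,after Row-aligned [cyto_dataset()] objects.
#' @param grid_x,grid_y Evaluation SOM grid.
#' @param seed Integer seed for the evaluation SOM.
#' @param binsize,filter_threshold Passed to [evaluate_emd()].
#' @return List with `emd` (from [evaluate_emd()]), `mad` (from
#'   [evaluate_mad()]), `labels`.
#' @export
evaluate_correction <- function(before, after, grid_x = 8, grid_y = 8,
                                seed = 473, binsize = 0.1,
                                filter_threshold = 2) {
  model <- train_som(after$exprs, grid_x = grid_x, grid_y = grid_y,
                     seed = seed)
  labels <- assign_nodes(model, after$exprs)
  list(emd = evaluate_emd(before, after, labels, binsize,
                          filter_threshold),
       mad = evaluate_mad(before, after, labels),
       labels = labels)
}
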