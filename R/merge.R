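#' Plan a two-panel merge
#'
#' Computes the shared and panel-specific markers (by canonical,
#' case-sensitive marker key) and bundles the imputation settings.
#'
#' @param markers_a,markers_b Marker names of the two panels.
#' @param grid_x,grid_y SOM grid used for the merge clustering.
#' @param min_donors Minimum donor cells a node needs before its values
#'   are trusted for imputation (default 50; below it, recipients get
#'   `NA`).
#' @param seed Integer seed for the merge SOM and donor draws.
#' @return A `merge_plan` list with `overlap_markers`, `missing_in_a`,
#'   `missing_in_b` and the settings.
#' @export
find_marker_overlap <- function(markers_a, markers_b, grid_x = 8,
                                grid_y = 8, min_donors = 50, seed = 473) {
  overlap <- intersect(markers_a, markers_b)
  if (length(overlap) == 0) {
    stop("panels share no markers; imputation is impossible",
         call. = FALSE)
  }
  if (min_donors < 1) stop("min_donors must be >= 1", call. = FALSE)
  structure(list(overlap_markers = sort(overlap),
                 missing_in_a = sort(setdiff(markers_b, markers_a)),
                 missing_in_b = sort(setdiff(markers_a, markers_b)),
                 grid_x = as.integer(grid_x), grid_y = as.integer(grid_y),
                 min_donors = as.integer(min_donors),
                 seed = as.integer(seed)),
            class = "merge_plan")
}

# Silverman's rule-of-thumb kernel bandwidth; exactly 0 for zero-spread
# donors so degenerate nodes impute the shared value verbatim
silverman_bw <- function(x) {
  n <- length(x)
  if (n < 2) return(0)
  a <- min(stats::sd(x), stats::IQR(x) / 1.34)
  if (!is.finite(a) || a <= 0) return(0)
  0.9 * a * n^(-1 / 5)
}

# draw one donor per recipient and add per-marker Gaussian kernel noise;
# a single donor supplies all missing markers jointly, preserving their
# co-expression
impute_node <- function(donor_vals, n_recipients) {
  n_d <- nrow(donor_vals)
  draws <- sample.int(n_d, n_recipients, replace = TRUE)
  imputed <- donor_vals[draws, , drop = FALSE]
  for (j in seq_len(ncol(donor_vals))) {
    bw <- silverman_bw(donor_vals[, j])
    if (bw > 0) {
      imputed[, j] <- imputed[, j] + stats::rnorm(n_recipients, 0, bw)
    }
  }
  imputed
}

#' Impute non-overlapping markers across two panels
#'
#' Merges two datasets measured with different antibody panels on split
#' samples. One SOM is trained on the pooled overlap-marker expression
#' of both datasets (the panels are assumed co-corrected on those
#' markers beforehand; no re-normalization is applied). Within each
#' node, every cell's missing markers are filled from a single donor
#' cell drawn uniformly at random (with replacement) from the other
#' dataset's cells in the same node, simulating a draw from a
#' multi-dimensional kernel density estimate: each imputed value is the
#' donor value plus Normal(0, bandwidth) noise, with the bandwidth
#' computed per marker on the node's donor cells (Silverman's rule).
#' Nodes with fewer than `plan$min_donors` donors yield `NA` for all of
#' that side's missing markers, since imputation there is unreliable.
#'
#' Measured values are never modified, and per-node cell counts of each
#' panel are unchanged, so subtype frequencies are maintained. Imputed
#' values are intended for visualization and co-clustering, not for
#' differential-expression testing of the imputed markers.
#'
#' @param ds_a,ds_b [cyto_dataset()] objects (batch-corrected on the
#'   overlap markers).
#' @param plan A [find_marker_overlap()] plan.
#' @return A merged [cyto_dataset()] covering the union of markers, with
#'   elements `is_imputed` (logical cells x markers mask) and
#'   `cell_meta$panel` recording the source panel (`"A"`/`"B"`).
#' @export
impute_across_panels <- function(ds_a, ds_b, plan) {
  stopifnot(inherits(ds_a, "cyto_dataset"), inherits(ds_b, "cyto_dataset"),
            inherits(plan, "merge_plan"))
  ov <- plan$overlap_markers
  if (!all(ov %in% markers(ds_a)) || !all(ov %in% markers(ds_b))) {
    stop("plan overlap markers not present in both datasets",
         call. = FALSE)
  }
  n_a <- nrow(ds_a$exprs)
  n_b <- nrow(ds_b$exprs)
  pooled <- rbind(ds_a$exprs[, ov, drop = FALSE],
                  ds_b$exprs[, ov, drop = FALSE])
  model <- train_som(pooled, grid_x = plan$grid_x, grid_y = plan$grid_y,
                     seed = plan$seed)
  labels <- assign_nodes(model, pooled)
  lab_a <- labels[seq_len(n_a)]
  lab_b <- labels[n_a + seq_len(n_b)]
  all_markers <- c(ov, plan$missing_in_b, plan$missing_in_a)
  ex_a <- matrix(NA_real_, n_a, length(all_markers),
                 dimnames = list(NULL, all_markers))
  ex_b <- matrix(NA_real_, n_b, length(all_markers),
                 dimnames = list(NULL, all_markers))
  ex_a[, markers(ds_a)] <- ds_a$exprs
  ex_b[, markers(ds_b)] <- ds_b$exprs
  imp_a <- matrix(FALSE, n_a, length(all_markers),
                  dimnames = list(NULL, all_markers))
  imp_b <- matrix(FALSE, n_b, length(all_markers),
                  dimnames = list(NULL, all_markers))
  with_seed(plan$seed + 1L, {
    for (node in sort(unique(labels))) {
      ra <- which(lab_a == node)   # recipients in A, donors in B
      rb <- which(lab_b == node)
      if (length(ra) && length(plan$missing_in_a)) {
        imp_a[ra, plan$missing_in_a] <- TRUE
        if (length(rb) >= plan$min_donors) {
          donors <- ds_b$exprs[rb, plan$missing_in_a, drop = FALSE]
          ex_a[ra, plan$missing_in_a] <- impute_node(donors, length(ra))
        }  # else: stays NA (unreliable node)
      }
      if (length(rb) && length(plan$missing_in_b)) {
        imp_b[rb, plan$missing_in_b] <- TRUE
        if (length(ra) >= plan$min_donors) {
          donors <- ds_a$exprs[ra, plan$missing_in_b, drop = FALSE]
          ex_b[rb, plan$missing_in_b] <- impute_node(donors, length(rb))
        }
      }
    }
  })
  meta_a <- ds_a$cell_meta
  meta_a$panel <- "A"
  meta_b <- ds_b$cell_meta
  meta_b$panel <- "B"
  cols <- union(names(meta_a), names(meta_b))
  for (cl in setdiff(cols, names(meta_a))) meta_a[[cl]] <- NA
  for (cl in setdiff(cols, names(meta_b))) meta_b[[cl]] <- NA
  out <- cyto_dataset_na(rbind(ex_a, ex_b),
                         rbind(meta_a[cols], meta_b[cols]),
                         cofactor = ds_a$transform$cofactor)
  out$is_imputed <- rbind(imp_a, imp_b)
  out$merge_labels <- as.integer(labels)
  out
}

# variant constructor for merged data, where NA imputation sentinels are
# legitimate (write_fcs still refuses them)
cyto_dataset_na <- function(expression, cell_meta, cofactor = NA_real_) {
  expression <- as.matrix(expression)
  storage.mode(expression) <- "double"
  if (any(is.infinite(expression))) {
    stop("expression values must not be infinite", call. = FALSE)
  }
  filled <- expression
  filled[is.na(filled)] <- 0
  out <- cyto_dataset(filled, cell_meta, cofactor = cofactor)
  out$exprs <- `dimnames<-`(expression, dimnames(out$exprs))
  out
}

#' Salvage a mis-stained channel across batches
#'
#' Replaces one marker's values in selected bad batches by per-node
#' donor draws from the remaining (good) batches of the same dataset —
#' the same kernel-density imputation as [impute_across_panels()], but
#' intra-dataset. Clustering is performed on all other markers. All
#' other values are untouched.
#'
#' @param dataset A [cyto_dataset()].
#' @param marker The mis-stained marker name.
#' @param bad_batches Batches whose `marker` values are to be replaced.
#' @param grid_x,grid_y SOM grid.
#' @param seed Integer seed.
#' @param min_donors Minimum good-batch cells per node (default 50).
#' @return The dataset with `marker` replaced in `bad_batches` (NA where
#'   a node lacks donors) and an `is_imputed` mask.
#' @export
salvage_channel <- function(dataset, marker, bad_batches, grid_x = 8,
                            grid_y = 8, seed = 473, min_donors = 50) {
  stopifnot(inherits(dataset, "cyto_dataset"))
  if (!marker %in% markers(dataset)) {
    stop("unknown marker: ", marker, call. = FALSE)
  }
  b <- batch_ids(dataset)
  if (!all(bad_batches %in% b)) {
    stop("bad_batches not all present in dataset", call. = FALSE)
  }
  if (all(unique(b) %in% bad_batches)) {
    stop("at least one good batch is required as donor", call. = FALSE)
  }
  if (length(bad_batches) == 0) return(dataset)
  other <- setdiff(markers(dataset), marker)
  model <- train_som(dataset$exprs[, other, drop = FALSE],
                     grid_x = grid_x, grid_y = grid_y, seed = seed)
  labels <- assign_nodes(model, dataset$exprs[, other, drop = FALSE])
  bad <- b %in% bad_batches
  ex <- dataset$exprs
  imp <- matrix(FALSE, nrow(ex), ncol(ex),
                dimnames = dimnames(ex))
  with_seed(seed + 1L, {
    for (node in sort(unique(labels[bad]))) {
      rec <- which(bad & labels == node)
      don <- which(!bad & labels == node)
      imp[rec, marker] <- TRUE
      if (length(don) >= min_donors) {
        ex[rec, marker] <- impute_node(
          ex[don, marker, drop = FALSE], length(rec))
      } else {
        ex[rec, marker] <- NA_real_
      }
    }
  })
  out <- cyto_dataset_na(ex, dataset$cell_meta,
                         cofactor = dataset$transform$cofactor)
  out$transform <- dataset$transform
  out$is_imputed <- imp
  out
}
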