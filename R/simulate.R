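#' Simulation configuration
#'
#' Describes a synthetic cytometry experiment: a Gaussian mixture of
#' cell populations over markers on the ArcSinh scale, per-batch
#' per-marker location/scale distortions (the family of technical
#' effects the correction model targets), optional zero-inflation to
#' emulate dropout, and condition-dependent population abundances so
#' covariate preservation can be tested at the composition level.
#'
#' Default magnitudes reflect a typical pre-gated CyTOF experiment after
#' ArcSinh (cofactor 5): positive populations near 3.5, negative near
#' 0.5, within-population marker noise 0.3, batch shifts with sd 0.3
#' and multiplicative (log-scale) distortions with sd 0.1.
#'
#' @param n_populations,n_markers,n_batches,cells_per_batch Integers.
#' @param population_means Optional populations x markers matrix of
#'   ArcSinh-scale means; generated from a bimodal positive/negative
#'   marker pattern under `seed` when `NULL`.
#' @param abundance Population frequencies: a probability vector
#'   (single condition) or a named list of vectors, one per condition
#'   (each summing to 1). Conditions are split evenly within each batch.
#' @param batch_shift_sd Sd of per-batch per-marker additive shifts.
#' @param batch_scale_sd Sd of per-batch per-marker log-scale factors.
#' @param noise_sd Within-population marker standard deviation.
#' @param zero_inflation Probability a value is zeroed (dropout).
#' @param seed Integer seed; the whole simulation is deterministic
#'   given the config.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_populations = 4, n_markers = 15,
                              n_batches = 2, cells_per_batch = 20000,
                              population_means = NULL,
                              abundance = NULL,
                              batch_shift_sd = 0.3,
                              batch_scale_sd = 0.1,
                              noise_sd = 0.3,
                              zero_inflation = 0,
                              seed = 473) {
  if (is.null(abundance)) {
    abundance <- list(A = rep(1 / n_populations, n_populations))
  }
  if (!is.list(abundance)) abundance <- list(A = abundance)
  if (is.null(names(abundance))) {
    names(abundance) <- LETTERS[seq_along(abundance)]
  }
  for (a in abundance) {
    if (length(a) != n_populations || abs(sum(a) - 1) > 1e-8 ||
        any(a < 0)) {
      stop("each condition's abundances must be ", n_populations,
           " non-negative values summing to 1", call. = FALSE)
    }
  }
  if (batch_shift_sd < 0 || batch_scale_sd < 0 || noise_sd < 0 ||
      zero_inflation < 0 || zero_inflation > 1) {
    stop("invalid noise/distortion settings", call. = FALSE)
  }
  if (!is.null(population_means)) {
    population_means <- as.matrix(population_means)
    if (!all(dim(population_means) == c(n_populations, n_markers))) {
      stop("population_means must be n_populations x n_markers",
           call. = FALSE)
    }
  }
  structure(list(n_populations = as.integer(n_populations),
                 n_markers = as.integer(n_markers),
                 n_batches = as.integer(n_batches),
                 cells_per_batch = as.integer(cells_per_batch),
                 population_means = population_means,
                 abundance = abundance,
                 batch_shift_sd = batch_shift_sd,
                 batch_scale_sd = batch_scale_sd,
                 noise_sd = noise_sd,
                 zero_inflation = zero_inflation,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# bimodal positive/negative population phenotypes: each population is
# positive (around 3.5) or negative (around 0.5) for each marker, with
# jitter, guaranteeing multi-marker separation between populations
generate_population_means <- function(n_pop, n_markers) {
  repeat {
    on_off <- matrix(stats::runif(n_pop * n_markers) < 0.5, n_pop,
                     n_markers)
    if (n_pop == 1 || min(stats::dist(on_off * 1)) > 0) break
  }
  base <- ifelse(on_off, 3.5, 0.5)
  base + matrix(stats::rnorm(n_pop * n_markers, 0, 0.2), n_pop,
                n_markers)
}

#' Simulate a cytometry dataset with known ground truth
#'
#' Cells are drawn per batch and condition from the population mixture
#' with Gaussian marker noise, then per-batch technical distortions are
#' applied per marker: `value * exp(log_scale) + shift` with
#' `shift ~ N(0, batch_shift_sd)` and `log_scale ~ N(0, batch_scale_sd)`.
#' Optional zero-inflation zeroes values at random afterwards.
#'
#' @param config A [simulation_config()].
#' @return List with `dataset` (a [cyto_dataset()]) and `truth`: per-cell
#'   `population`, per-batch x marker `shift` and `scale` matrices
#'   actually drawn, and the `population_means` used.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  res <- with_seed(config$seed, {
    pm <- config$population_means
    if (is.null(pm)) {
      pm <- generate_population_means(config$n_populations,
                                      config$n_markers)
    }
    shifts <- matrix(stats::rnorm(config$n_batches * config$n_markers, 0,
                                  config$batch_shift_sd),
                     config$n_batches, config$n_markers)
    scales <- matrix(exp(stats::rnorm(config$n_batches * config$n_markers,
                                      0, config$batch_scale_sd)),
                     config$n_batches, config$n_markers)
    conds <- names(config$abundance)
    rows <- list()
    meta <- list()
    pops <- list()
    for (bi in seq_len(config$n_batches)) {
      n_b <- config$cells_per_batch
      per_cond <- diff(round(seq(0, n_b, length.out = length(conds) + 1)))
      for (ci in seq_along(conds)) {
        n_c <- per_cond[ci]
        if (n_c == 0) next
        pop <- sample.int(config$n_populations, n_c, replace = TRUE,
                          prob = config$abundance[[ci]])
        vals <- pm[pop, , drop = FALSE] +
          matrix(stats::rnorm(n_c * config$n_markers, 0, config$noise_sd),
                 n_c, config$n_markers)
        vals <- sweep(vals, 2, scales[bi, ], "*")
        vals <- sweep(vals, 2, shifts[bi, ], "+")
        if (config$zero_inflation > 0) {
          drop_mask <- matrix(
            stats::runif(n_c * config$n_markers) < config$zero_inflation,
            n_c, config$n_markers)
          vals[drop_mask] <- 0
        }
        rows[[length(rows) + 1L]] <- vals
        pops[[length(pops) + 1L]] <- pop
        meta[[length(meta) + 1L]] <- data.frame(
          sample_id = sprintf("batch%d_%s", bi, conds[ci]),
          batch_id = sprintf("batch%d", bi),
          condition = conds[ci], stringsAsFactors = FALSE)
      }
    }
    ex <- do.call(rbind, rows)
    colnames(ex) <- sprintf("m%02d", seq_len(config$n_markers))
    colnames(shifts) <- colnames(scales) <- colnames(ex)
    rownames(shifts) <- rownames(scales) <-
      sprintf("batch%d", seq_len(config$n_batches))
    meta_df <- do.call(rbind, lapply(seq_along(meta), function(i) {
      meta[[i]][rep(1, nrow(rows[[i]])), , drop = FALSE]
    }))
    list(dataset = cyto_dataset(ex, meta_df, cofactor = 5),
         truth = list(population = unlist(pops), shift = shifts,
                      scale = scales, population_means = pm))
  })
  res
}

#' Inject batch distortions into an existing dataset
#'
#' Applies specified per-batch per-marker distortions
#' (`value * scale + shift`) to a dataset, for reproducibly distorting
#' real or simulated data. A zero spec is the identity.
#'
#' @param dataset A [cyto_dataset()].
#' @param shift,scale Matrices batches x markers (row names = batch ids,
#'   column names = marker names); `NULL` means no shift / unit scale.
#' @return The distorted [cyto_dataset()].
#' @export
apply_batch_effects <- function(dataset, shift = NULL, scale = NULL) {
  stopifnot(inherits(dataset, "cyto_dataset"))
  ub <- sort(unique(batch_ids(dataset)))
  mk <- markers(dataset)
  as_mat <- function(x, fill) {
    if (is.null(x)) {
      return(matrix(fill, length(ub), length(mk),
                    dimnames = list(ub, mk)))
    }
    x <- as.matrix(x)
    if (!all(ub %in% rownames(x)) || !all(mk %in% colnames(x))) {
      stop("distortion spec must cover every batch (rows) and marker ",
           "(columns)", call. = FALSE)
    }
    x[ub, mk, drop = FALSE]
  }
  shift <- as_mat(shift, 0)
  scale <- as_mat(scale, 1)
  ex <- dataset$exprs
  b <- batch_ids(dataset)
  for (bb in ub) {
    idx <- b == bb
    ex[idx, ] <- sweep(sweep(ex[idx, , drop = FALSE], 2, scale[bb, ],
                             "*"), 2, shift[bb, ], "+")
  }
  out <- dataset
  out$exprs <- ex
  out
}

#' Write a dataset as FCS fixtures plus a sample sheet
#'
#' One FCS 3.1 file per sample (raw-scale intensities, i.e. the inverse
#' ArcSinh of the stored expression when a cofactor is recorded) and a
#' `samples.csv` sheet with `sample_id`, `batch_id`, `condition` and
#' `file`. Re-ingesting with [read_fcs()] + [assemble_dataset()]
#' reproduces the dataset to float precision.
#'
#' @param dataset A [cyto_dataset()].
#' @param directory Output directory (created if needed).
#' @return Paths of the files written, invisibly.
#' @export
write_fixture_fcs <- function(dataset, directory) {
  stopifnot(inherits(dataset, "cyto_dataset"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  cofactor <- dataset$transform$cofactor
  meta <- dataset$cell_meta
  sids <- unique(meta$sample_id)
  files <- character()
  rows <- list()
  for (sid in sids) {
    idx <- meta$sample_id == sid
    ev <- dataset$exprs[idx, , drop = FALSE]
    if (!is.na(cofactor)) ev <- inverse_arcsinh(ev, cofactor)
    fn <- paste0(gsub("[^A-Za-z0-9_.-]", "_", sid), ".fcs")
    write_fcs(raw_sample(ev, markers(dataset), source_path = sid),
              file.path(directory, fn))
    files <- c(files, file.path(directory, fn))
    first <- which(idx)[1]
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sid, batch_id = meta$batch_id[first],
      condition = if (is.null(meta$condition)) NA_character_ else
        meta$condition[first],
      file = fn, stringsAsFactors = FALSE)
  }
  sheet <- file.path(directory, "samples.csv")
  utils::write.csv(do.call(rbind, rows), sheet, row.names = FALSE)
  invisible(c(files, sheet))
}
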