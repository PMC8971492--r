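#' Construct a cytometry dataset
#'
#' The central container of cytofuse: an ArcSinh-scale expression matrix
#' (cells x markers) plus per-cell metadata. All pipeline stages (`correct()`,
#' `impute_across_panels()`, `evaluate_emd()`, ...) consume and produce this
#' class.
#'
#' @param expression Numeric matrix, cells in rows, markers in columns.
#'   Column names are taken as marker names when `marker_names` is `NULL`.
#' @param cell_meta Data frame with one row per cell. Must contain
#'   `sample_id` and `batch_id`; may contain `condition`. A stable
#'   `original_index` column is added when absent.
#' @param marker_names Character vector of unique marker names.
#' @param cofactor ArcSinh cofactor the expression values were transformed
#'   with (`NA` when the values were supplied already transformed).
#' @param derandomized Logical, whether count de-randomization was applied.
#'
#' @return An object of class `cyto_dataset`: a list with elements
#'   `exprs` (matrix), `cell_meta` (data.frame) and `transform`
#'   (list with `cofactor`, `derandomized`).
#' @export
cyto_dataset <- function(expression, cell_meta, marker_names = NULL,
                         cofactor = NA_real_, derandomized = FALSE) {
  expression <- as.matrix(expression)
  storage.mode(expression) <- "double"
  if (is.null(marker_names)) marker_names <- colnames(expression)
  if (is.null(marker_names)) {
    marker_names <- paste0("marker", seq_len(ncol(expression)))
  }
  marker_names <- as.character(marker_names)
  if (length(marker_names) != ncol(expression)) {
    stop("length(marker_names) must equal ncol(expression)", call. = FALSE)
  }
  if (anyDuplicated(marker_names)) {
    stop("marker names must be unique", call. = FALSE)
  }
  if (!all(is.finite(expression))) {
    stop("expression values must all be finite", call. = FALSE)
  }
  colnames(expression) <- marker_names
  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  if (nrow(cell_meta) != nrow(expression)) {
    stop("cell_meta must have one row per cell", call. = FALSE)
  }
  for (col in c("sample_id", "batch_id")) {
    if (is.null(cell_meta[[col]])) {
      stop("cell_meta must contain a '", col, "' column", call. = FALSE)
    }
    cell_meta[[col]] <- as.character(cell_meta[[col]])
  }
  if (anyNA(cell_meta$batch_id)) {
    stop("every cell must have a batch_id", call. = FALSE)
  }
  if (is.null(cell_meta$original_index)) {
    cell_meta$original_index <- seq_len(nrow(cell_meta))
  }
  rownames(expression) <- NULL
  rownames(cell_meta) <- NULL
  structure(
    list(
      exprs = expression,
      cell_meta = cell_meta,
      transform = list(cofactor = cofactor, derandomized = derandomized)
    ),
    class = "cyto_dataset"
  )
}

#' @export
print.cyto_dataset <- function(x, ...) {
  cat("<cyto_dataset> ", nrow(x$exprs), " cells x ", ncol(x$exprs),
      " markers\n", sep = "")
  cat("  batches:  ", paste(sort(unique(x$cell_meta$batch_id)),
                            collapse = ", "), "\n", sep = "")
  cat("  samples:  ", length(unique(x$cell_meta$sample_id)), "\n", sep = "")
  if (!is.null(x$cell_meta$condition)) {
    cat("  conditions: ",
        paste(sort(unique(stats::na.omit(x$cell_meta$condition))),
              collapse = ", "), "\n", sep = "")
  }
  cat("  cofactor: ", x$transform$cofactor,
      "  derandomized: ", x$transform$derandomized, "\n", sep = "")
  invisible(x)
}

#' @export
dim.cyto_dataset <- function(x) dim(x$exprs)

#' Marker names of a dataset
#' @param dataset A `cyto_dataset`.
#' @return Character vector of marker names.
#' @export
markers <- function(dataset) colnames(dataset$exprs)

#' Expression matrix of a dataset
#' @param dataset A `cyto_dataset`.
#' @return Numeric matrix, cells x markers, ArcSinh scale.
#' @export
exprs <- function(dataset) dataset$exprs

#' Per-cell batch labels
#' @param dataset A `cyto_dataset`.
#' @return Character vector, one entry per cell.
#' @export
batch_ids <- function(dataset) dataset$cell_meta$batch_id

#' Subset a dataset by cell and/or marker
#'
#' @param dataset A `cyto_dataset`.
#' @param cells Integer or logical index over cells (rows).
#' @param select_markers Character vector of marker names to keep.
#' @return A `cyto_dataset` with the selected cells/markers; metadata rows
#'   follow the cell selection, `original_index` is preserved.
#' @export
subset_cells <- function(dataset, cells = NULL, select_markers = NULL) {
  stopifnot(inherits(dataset, "cyto_dataset"))
  ex <- dataset$exprs
  meta <- dataset$cell_meta
  if (!is.null(cells)) {
    ex <- ex[cells, , drop = FALSE]
    meta <- meta[cells, , drop = FALSE]
  }
  if (!is.null(select_markers)) {
    missing <- setdiff(select_markers, colnames(ex))
    if (length(missing)) {
      stop("unknown markers: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    ex <- ex[, select_markers, drop = FALSE]
  }
  out <- dataset
  out$exprs <- ex
  out$cell_meta <- `rownames<-`(meta, NULL)
  out
}

#' Bind two datasets by row
#'
#' Markers must agree (order is canonicalized to the first dataset's order).
#' @param a,b `cyto_dataset` objects.
#' @return Combined `cyto_dataset`.
#' @export
bind_datasets <- function(a, b) {
  stopifnot(inherits(a, "cyto_dataset"), inherits(b, "cyto_dataset"))
  if (!setequal(markers(a), markers(b))) {
    stop("datasets have different marker sets", call. = FALSE)
  }
  ex <- rbind(a$exprs, b$exprs[, markers(a), drop = FALSE])
  cols <- union(names(a$cell_meta), names(b$cell_meta))
  ma <- a$cell_meta
  mb <- b$cell_meta
  for (cl in setdiff(cols, names(ma))) ma[[cl]] <- NA
  for (cl in setdiff(cols, names(mb))) mb[[cl]] <- NA
  meta <- rbind(ma[cols], mb[cols])
  cyto_dataset(ex, meta, cofactor = a$transform$cofactor,
               derandomized = a$transform$derandomized &&
                 b$transform$derandomized)
}

# internal: run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
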