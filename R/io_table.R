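#' Read / write a dataset as a flat CSV
#'
#' Flat interchange format used by the command-line interface: one row
#' per cell, metadata columns (`sample_id`, `batch_id`, `condition`,
#' `original_index`, any others) followed by one column per marker.
#' Values are assumed to be on the ArcSinh scale already.
#'
#' @param dataset A [cyto_dataset()].
#' @param path CSV path.
#' @return `write_dataset_csv()`: `path` invisibly;
#'   `read_dataset_csv()`: a [cyto_dataset()].
#' @export
write_dataset_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "cyto_dataset"))
  df <- cbind(dataset$cell_meta, as.data.frame(dataset$exprs))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  meta_cols <- intersect(c("sample_id", "batch_id", "condition",
                           "original_index", "panel"), names(df))
  marker_cols <- setdiff(names(df), meta_cols)
  ex <- as.matrix(df[marker_cols])
  if (anyNA(ex)) {
    cyto_dataset_na(ex, df[meta_cols])
  } else {
    cyto_dataset(ex, df[meta_cols])
  }
}
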