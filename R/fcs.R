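#' Raw cytometry sample
#'
#' One sample's untransformed event matrix as read from an FCS file or a
#' delimited table, prior to de-randomization and ArcSinh transformation.
#'
#' @param events Numeric matrix, events x channels, finite values.
#' @param channel_names Unique channel identifiers (FCS `$PnN` short names,
#'   the canonical key for matching channels across files).
#' @param marker_names Optional display names (FCS `$PnS` stain names).
#' @param source_path Origin of the data, for provenance.
#' @return An object of class `raw_sample`.
#' @export
raw_sample <- function(events, channel_names, marker_names = NULL,
                       source_path = NA_character_) {
  events <- as.matrix(events)
  storage.mode(events) <- "double"
  channel_names <- as.character(channel_names)
  if (ncol(events) != length(channel_names)) {
    stop("channel count must equal channel name count", call. = FALSE)
  }
  if (anyDuplicated(channel_names)) {
    stop("channel names must be unique", call. = FALSE)
  }
  if (!all(is.finite(events))) {
    stop("event intensities must all be finite", call. = FALSE)
  }
  colnames(events) <- channel_names
  structure(list(events = events, channel_names = channel_names,
                 marker_names = marker_names, source_path = source_path),
            class = "raw_sample")
}

#' @export
print.raw_sample <- function(x, ...) {
  cat("<raw_sample> ", nrow(x$events), " events x ",
      length(x$channel_names), " channels (", x$source_path, ")\n", sep = "")
  invisible(x)
}

# 58-byte FCS header: 6-byte version, 4 spaces, six 8-byte ASCII offsets
.fcs_header_len <- 58L

#' Read an FCS file
#'
#' Parses FCS 3.0 and 3.1 files in list mode, data types F (float), D
#' (double) and I (integer). Channel names are taken from the `$PnN`
#' keywords; `$PnS` stain names, when present, are attached as display
#' aliases. No gating or compensation is performed: the file is assumed
#' pre-gated.
#'
#' @param path Path to an FCS file.
#' @return A [raw_sample()].
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, .fcs_header_len, useBytes = TRUE)
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop("not an FCS 3.0/3.1 file: ", path, " (version '", version, "')",
         call. = FALSE)
  }
  offs <- suppressWarnings(as.integer(substring(
    header, 11 + 8 * (0:5), 18 + 8 * (0:5))))
  if (anyNA(offs[1:2])) stop("malformed FCS header in ", path, call. = FALSE)
  text_start <- offs[1]; text_end <- offs[2]
  seek(con, text_start)
  text_raw <- readChar(con, text_end - text_start + 1, useBytes = TRUE)
  delim <- substr(text_raw, 1, 1)
  parts <- strsplit(substring(text_raw, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- as.list(stats::setNames(
    parts[seq(2, length(parts), by = 2)],
    toupper(trimws(parts[seq(1, length(parts), by = 2)]))))
  need <- function(key) {
    v <- kw[[key]]
    if (is.null(v)) stop("FCS file missing required keyword ", key,
                         call. = FALSE)
    v
  }
  n_par <- as.integer(need("$PAR"))
  n_tot <- as.integer(need("$TOT"))
  dtype <- toupper(need("$DATATYPE"))
  byteord <- need("$BYTEORD")
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  mode <- toupper(need("$MODE"))
  if (mode != "L") stop("only list-mode ($MODE L) FCS files are supported",
                        call. = FALSE)
  data_start <- offs[3]; data_end <- offs[4]
  if (is.na(data_start) || data_start == 0L) {
    data_start <- as.integer(need("$BEGINDATA"))
    data_end <- as.integer(need("$ENDDATA"))
  }
  bits <- as.integer(vapply(seq_len(n_par),
                            function(i) need(sprintf("$P%dB", i)), ""))
  if (length(unique(bits)) != 1L) {
    stop("mixed per-parameter bit widths are not supported", call. = FALSE)
  }
  size <- bits[1] %/% 8L
  what <- switch(dtype,
                 F = "numeric", D = "numeric", I = "integer",
                 stop("unsupported $DATATYPE ", dtype, call. = FALSE))
  if (dtype == "F" && size != 4L) stop("$DATATYPE F requires $PnB 32",
                                       call. = FALSE)
  if (dtype == "D" && size != 8L) stop("$DATATYPE D requires $PnB 64",
                                       call. = FALSE)
  n_values <- n_par * n_tot
  expected <- n_values * size
  if (!is.na(data_end) && data_end - data_start + 1L < expected) {
    stop("FCS data segment shorter than $PAR x $TOT events", call. = FALSE)
  }
  seek(con, data_start)
  vals <- readBin(con, what, n = n_values, size = size, endian = endian,
                  signed = TRUE)
  if (length(vals) < n_values) {
    stop("truncated FCS data segment in ", path, call. = FALSE)
  }
  events <- matrix(as.double(vals), nrow = n_tot, ncol = n_par, byrow = TRUE)
  ch <- vapply(seq_len(n_par), function(i) need(sprintf("$P%dN", i)), "")
  stains <- vapply(seq_len(n_par), function(i) {
    v <- kw[[sprintf("$P%dS", i)]]
    if (is.null(v)) NA_character_ else v
  }, "")
  raw_sample(events, ch,
             marker_names = if (all(is.na(stains))) NULL else stains,
             source_path = path)
}

#' Write an FCS 3.1 file
#'
#' Emits a single-dataset FCS 3.1 file in list mode with float storage
#' (`$DATATYPE F`, `$PnB 32`, little-endian). Values must be finite:
#' datasets carrying imputation sentinels (`NA`) are rejected so that
#' missing values are never silently materialized on disk.
#'
#' @param x A [raw_sample()] or [cyto_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(x, path) {
  if (inherits(x, "cyto_dataset")) {
    events <- x$exprs
    ch <- markers(x)
    stains <- NULL
  } else if (inherits(x, "raw_sample")) {
    events <- x$events
    ch <- x$channel_names
    stains <- x$marker_names
  } else {
    stop("x must be a raw_sample or cyto_dataset", call. = FALSE)
  }
  if (anyNA(events) || !all(is.finite(events))) {
    stop("cannot write non-finite values to FCS; drop or fill missing ",
         "(e.g., imputation sentinels) first", call. = FALSE)
  }
  n_tot <- nrow(events); n_par <- ncol(events)
  delim <- rawToChar(as.raw(12L))
  pnr <- pmax(1, ceiling(apply(events, 2, function(v)
    if (length(v)) max(v, 1) else 1)))
  kv <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "%BD%", "$ENDDATA", "%ED%",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0",
          "$PAR", as.character(n_par), "$TOT", as.character(n_tot))
  for (i in seq_len(n_par)) {
    kv <- c(kv, sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dN", i), ch[i],
            sprintf("$P%dR", i), as.character(pnr[i]))
    if (!is.null(stains) && !is.na(stains[i])) {
      kv <- c(kv, sprintf("$P%dS", i), stains[i])
    }
  }
  if (any(grepl(delim, kv, fixed = TRUE))) {
    stop("channel names must not contain the TEXT delimiter byte",
         call. = FALSE)
  }
  # fixed-width data offsets keep TEXT length independent of their values
  text_of <- function(bd, ed) {
    body <- kv
    body[body == "%BD%"] <- sprintf("%010d", bd)
    body[body == "%ED%"] <- sprintf("%010d", ed)
    paste0(delim, paste0(body, delim, collapse = ""))
  }
  text_len <- nchar(text_of(0L, 0L), type = "bytes")
  text_start <- .fcs_header_len
  text_end <- text_start + text_len - 1L
  data_start <- text_end + 1L
  data_end <- data_start + 4L * n_tot * n_par - 1L
  if (n_tot == 0L) data_end <- 0L
  fmt8 <- function(v) formatC(v, width = 8, format = "d")
  header <- paste0("FCS3.1    ",
                   fmt8(text_start), fmt8(text_end),
                   fmt8(if (n_tot) data_start else 0L),
                   fmt8(data_end), fmt8(0L), fmt8(0L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL, useBytes = TRUE)
  writeChar(text_of(if (n_tot) data_start else 0L, data_end), con,
            eos = NULL, useBytes = TRUE)
  if (n_tot > 0L) {
    writeBin(as.vector(t(events)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' De-randomize CyTOF ion counts
#'
#' CyTOF acquisition software randomizes integer ion counts by adding
#' uniform(-1, 0) noise; the ceiling exactly inverts this, recovering the
#' original integers.
#'
#' @param counts Numeric matrix of randomized counts (all values > -1).
#' @return Integer-valued matrix of the same shape.
#' @export
derandomize <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts <= -1)) {
    stop("values <= -1 found: input does not look like randomized ",
         "CyTOF counts", call. = FALSE)
  }
  ceiling(counts)
}

#' ArcSinh transform
#'
#' Variance-stabilizing transform `asinh(x / cofactor)`. Recommended
#' cofactors: 5 for mass cytometry (CyTOF), 150 for conventional flow
#' cytometry, 6000 for spectral flow cytometry.
#'
#' @param x Numeric matrix or vector.
#' @param cofactor Positive scale divisor.
#' @return Transformed values, same shape as `x`.
#' @seealso [inverse_arcsinh()]
#' @export
arcsinh_transform <- function(x, cofactor = 5) {
  if (!is.numeric(cofactor) || length(cofactor) != 1 || !is.finite(cofactor)
      || cofactor <= 0) {
    stop("cofactor must be a single positive number", call. = FALSE)
  }
  asinh(x / cofactor)
}

#' Inverse ArcSinh transform
#' @param y Transformed values.
#' @param cofactor The cofactor used in the forward transform.
#' @return `sinh(y) * cofactor`.
#' @export
inverse_arcsinh <- function(y, cofactor = 5) {
  if (cofactor <= 0) stop("cofactor must be positive", call. = FALSE)
  sinh(y) * cofactor
}

#' Assemble a multi-sample dataset
#'
#' Concatenates samples into a single ArcSinh-scale [cyto_dataset()],
#' restricted to the channels shared by all samples (canonical order:
#' sorted channel key). Optional de-randomization is applied before the
#' transform, so integer counts are transformed.
#'
#' @param samples Named list of [raw_sample()] objects; names are sample ids.
#' @param metadata Data frame with columns `sample_id`, `batch_id` and
#'   optionally `condition`; every sample must appear.
#' @param cofactor ArcSinh cofactor (default 5, mass cytometry).
#' @param derandomize_counts Apply [derandomize()] per sample first.
#' @return A [cyto_dataset()] with per-cell sample/batch/condition labels.
#' @export
assemble_dataset <- function(samples, metadata, cofactor = 5,
                             derandomize_counts = FALSE) {
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    stop("samples must be a named list (names are sample ids)",
         call. = FALSE)
  }
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  missing <- setdiff(names(samples), metadata$sample_id)
  if (length(missing)) {
    stop("samples missing from metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  shared <- Reduce(intersect, lapply(samples, function(s) s$channel_names))
  if (length(shared) == 0) {
    stop("samples share no channels", call. = FALSE)
  }
  shared <- sort(shared)
  mats <- vector("list", length(samples))
  metas <- vector("list", length(samples))
  offset <- 0L
  for (i in seq_along(samples)) {
    sid <- names(samples)[i]
    ev <- samples[[i]]$events[, shared, drop = FALSE]
    if (derandomize_counts) ev <- derandomize(ev)
    mats[[i]] <- arcsinh_transform(ev, cofactor)
    row <- metadata[match(sid, metadata$sample_id), ]
    metas[[i]] <- data.frame(
      sample_id = rep(sid, nrow(ev)),
      batch_id = rep(as.character(row$batch_id), nrow(ev)),
      condition = rep(if (is.null(row$condition)) NA_character_ else
        as.character(row$condition), nrow(ev)),
      original_index = offset + seq_len(nrow(ev)),
      stringsAsFactors = FALSE
    )
    offset <- offset + nrow(ev)
  }
  cyto_dataset(do.call(rbind, mats), do.call(rbind, metas),
               cofactor = cofactor, derandomized = derandomize_counts)
}

#' Read an expression table
#'
#' Alternative ingestion path for non-FCS data (e.g., CITE-seq antibody
#' counts): a delimited text file whose header row holds marker names.
#'
#' @param path Path to a CSV/TSV file.
#' @param sep Field separator; `NULL` guesses from the file extension.
#' @return A [raw_sample()].
#' @export
read_expression_table <- function(path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t"
    else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  raw_sample(as.matrix(tab), colnames(tab), source_path = path)
}

#' Read a sample sheet
#'
#' @param path CSV with columns `sample_id`, `batch_id` and optionally
#'   `condition` (plus any extra columns, carried through).
#' @return Data frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  for (col in c("sample_id", "batch_id")) {
    if (is.null(sheet[[col]])) {
      stop("sample sheet must contain a '", col, "' column", call. = FALSE)
    }
  }
  sheet
}
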