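#' Read an expression matrix from TSV
#'
#' Expects the first column to hold probe ids and every remaining column
#' one instance profile; values are interpreted as amplitudes (difference
#' versus control) unless the caller ranks raw values deliberately.
#'
#' @param path File path.
#' @return Tibble: `probe_id` plus one numeric column per instance.
#' @export
read_expression_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl)[1L] <- "probe_id"
  tbl$probe_id <- as.character(tbl$probe_id)
  as_expression_matrix(tbl)  # validate
  tbl
}

#' Read a GCT 1.2 expression file
#'
#' Broad-compatible input: a `#1.2` version line, a `m n` dimension line,
#' then a table whose `Name` column holds probe ids and whose
#' `Description` column is dropped. Read-only; package outputs are plain
#' TSV.
#'
#' @param path File path.
#' @return Tibble: `probe_id` plus one numeric column per instance.
#' @export
read_gct <- function(path) {
  header <- readLines(path, n = 2L)
  if (length(header) < 2L || trimws(header[1L]) != "#1.2") {
    stop("not a GCT 1.2 file (missing #1.2 header): ", path, call. = FALSE)
  }
  dims <- as.integer(strsplit(trimws(header[2L]), "\t")[[1L]][1:2])
  tbl <- readr::read_tsv(path, skip = 2L, show_col_types = FALSE,
                         progress = FALSE)
  if (!all(c("Name", "Description") %in% names(tbl)[1:2])) {
    stop("GCT file lacks Name/Description columns: ", path, call. = FALSE)
  }
  out <- dplyr::rename(tbl, probe_id = "Name")
  out <- dplyr::select(out, -"Description")
  if (nrow(out) != dims[1L] || ncol(out) - 1L != dims[2L]) {
    stop(sprintf("GCT dimension line says %d x %d but table is %d x %d",
                 dims[1L], dims[2L], nrow(out), ncol(out) - 1L),
         call. = FALSE)
  }
  out$probe_id <- as.character(out$probe_id)
  as_expression_matrix(out)  # validate
  out
}

#' Read an instance metadata table from TSV
#'
#' Requires `instance_id`, `name`, `class` columns; `subclass`,
#' `vehicle`, `batch`, `mol` are expected for barrier evaluation and any
#' unknown columns are preserved.
#'
#' @param path File path.
#' @return Metadata tibble.
#' @export
read_metadata_tsv <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  as_metadata(meta)
}

#' Write / read a similarity matrix as TSV
#'
#' The TSV dialect has instance ids in the header row and the first
#' column; rows are queries, columns targets. Values are written with 17
#' significant digits so a write-read round trip reproduces every double
#' bit-exactly. Reading an indirect matrix checks symmetry to 1e-9.
#'
#' @param x A `ks_matrix` or `i2r_matrix` (or plain named square matrix).
#' @param path File path.
#' @return `write_similarity_tsv` returns `path` invisibly;
#'   `read_similarity_tsv` returns the matrix with the requested class.
#' @export
write_similarity_tsv <- function(x, path) {
  mat <- unclass(x)
  attr(mat, "method") <- NULL
  out <- cbind(instance_id = rownames(mat),
               matrix(sprintf("%.17g", mat), nrow(mat), ncol(mat)))
  colnames(out) <- c("instance_id", colnames(mat))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_similarity_tsv
#' @param type `"ks"` (asymmetric, direct) or `"i2r"` (symmetric
#'   indirect; symmetry enforced on load).
#' @export
read_similarity_tsv <- function(path, type = c("ks", "i2r")) {
  type <- match.arg(type)
  # base parser: strtod round-trips 17-significant-digit decimals exactly
  tbl <- utils::read.delim(path, check.names = FALSE)
  ids <- as.character(tbl[[1L]])
  mat <- as.matrix(tbl[, -1L, drop = FALSE])
  rownames(mat) <- ids
  if (nrow(mat) != ncol(mat) || !identical(rownames(mat), colnames(mat))) {
    stop("similarity TSV is not a square id-matched matrix: ", path,
         call. = FALSE)
  }
  if (type == "i2r") {
    if (max(abs(mat - t(mat))) > 1e-9) {
      stop("indirect similarity matrix is not symmetric (tolerance 1e-9): ",
           path, call. = FALSE)
    }
    new_sim_matrix(mat, "i2r_matrix", method = "indirect")
  } else {
    new_sim_matrix(mat, "ks_matrix", method = "direct")
  }
}

#' Write an expression or metadata tibble as TSV
#'
#' Numeric columns are written at 17 significant digits for lossless round
#' trips.
#'
#' @param tbl Tibble to write.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(tbl, path) {
  out <- dplyr::mutate(tbl, dplyr::across(
    dplyr::where(is.double), ~ sprintf("%.17g", .x)
  ))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
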