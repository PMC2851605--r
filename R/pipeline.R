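#' Run the full similarity and evaluation pipeline
#'
#' Ranks the database, extracts signatures, computes the direct KS matrix
#' and the indirect I2R matrix, and evaluates retrieval (recall report)
#' plus per-sample average ranks for both methods. Inputs may be file
#' paths (TSV, or GCT for the matrix) or in-memory tibbles. When
#' `out_dir` is given, matrices and reports are written as TSV; partial
#' outputs are removed if a later stage fails.
#'
#' @param expression Expression tibble or path to a TSV/GCT file.
#' @param metadata Metadata tibble or path to a TSV file.
#' @param k Signature size per side.
#' @param eval_k Retrieval depth for the recall report (default 10).
#' @param barrier Barrier mode for the recall report.
#' @param min_group_size Minimum class size evaluated (default 10).
#' @param vote_k Majority-vote neighbourhood (default 11); classification
#'   is skipped when `vote_k >= n`.
#' @param out_dir Optional output directory.
#' @param quiet Suppress progress messages.
#' @return List with `ks`, `i2r`, `recall` (tibble), `average_ranks`
#'   (tibble with a `method` column), `classification` (tibble or NULL).
#' @export
run_pipeline <- function(expression, metadata, k, eval_k = 10,
                         barrier = "vehicle+batch", min_group_size = 10,
                         vote_k = 11, out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  expr <- if (is.character(expression)) {
    if (grepl("\\.gct$", expression, ignore.case = TRUE)) {
      read_gct(expression)
    } else {
      read_expression_tsv(expression)
    }
  } else {
    expression
  }
  meta <- if (is.character(metadata)) read_metadata_tsv(metadata) else
    as_metadata(metadata)

  inst <- setdiff(names(expr), "probe_id")
  extra <- setdiff(inst, meta$instance_id)
  orphan <- setdiff(meta$instance_id, inst)
  if (length(extra) > 0L || length(orphan) > 0L) {
    stop("expression/metadata instance mismatch; in matrix only: [",
         paste(extra, collapse = ", "), "], in metadata only: [",
         paste(orphan, collapse = ", "), "]", call. = FALSE)
  }
  meta <- meta[match(inst, meta$instance_id), ]

  say(sprintf("database: %d probes x %d instances", nrow(expr), length(inst)))
  say("computing direct KS matrix (k = ", k, ") ...")
  ks <- ks_similarity(expr, k = k)
  say("computing indirect I2R matrix ...")
  i2r <- i2r_similarity(ks)
  say("evaluating recall at k = ", eval_k, " across barrier '", barrier, "' ...")
  recall <- recall_report(ks, i2r, meta, k = eval_k, barrier = barrier,
                          min_group_size = min_group_size)
  avg <- dplyr::bind_rows(
    dplyr::mutate(average_ranks(ks, meta), method = "direct"),
    dplyr::mutate(average_ranks(i2r, meta), method = "indirect")
  )
  classification <- NULL
  if (vote_k < length(inst)) {
    classification <- dplyr::bind_rows(
      dplyr::mutate(classify_majority(ks, meta, vote_k = vote_k),
                    method = "direct"),
      dplyr::mutate(classify_majority(i2r, meta, vote_k = vote_k),
                    method = "indirect")
    )
  }
  result <- list(ks = ks, i2r = i2r, recall = recall,
                 average_ranks = avg, classification = classification)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    written <- character()
    tryCatch({
      p <- file.path(out_dir, "ks_matrix.tsv")
      write_similarity_tsv(ks, p); written <- c(written, p)
      p <- file.path(out_dir, "i2r_matrix.tsv")
      write_similarity_tsv(i2r, p); written <- c(written, p)
      p <- file.path(out_dir, "recall_report.tsv")
      write_table_tsv(recall, p); written <- c(written, p)
      p <- file.path(out_dir, "average_ranks.tsv")
      write_table_tsv(avg, p); written <- c(written, p)
      if (!is.null(classification)) {
        p <- file.path(out_dir, "classification.tsv")
        write_table_tsv(classification, p); written <- c(written, p)
      }
    }, error = function(e) {
      unlink(written)
      stop(e)
    })
    say("wrote ", length(written), " files to ", out_dir)
  }
  invisible(result)
}
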