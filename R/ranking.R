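#' Rank every profile of an expression database
#'
#' Converts a probes-by-instances value table into per-instance rankings.
#' Rank 1 is assigned to the probe with the largest value (the most
#' up-expressed probe relative to control); rank `m` to the smallest.
#' Values are usually amplitudes (expression difference versus a
#' vehicle/batch-matched control), which is the recommended basis because it
#' measures the treatment effect; passing raw expression values instead
#' ranks on those.
#'
#' Ties are broken deterministically by `probe_id` in lexicographic order so
#' that every ranking is a bijection onto `1:m` (the truncated KS statistic
#' requires unique positions).
#'
#' @param expr A data frame whose first column (`probe_id`) holds unique
#'   probe identifiers and whose remaining columns hold one numeric profile
#'   per instance.
#' @return A tibble with the same shape: `probe_id` plus one integer rank
#'   column per instance.
#' @examples
#' expr <- tibble::tibble(probe_id = c("p1", "p2", "p3"),
#'                        A = c(5, -3, 0.5), B = c(0, 1, 1))
#' rank_profiles(expr)
#' @export
rank_profiles <- function(expr) {
  mat <- as_expression_matrix(expr)
  m <- nrow(mat)
  if (m < 2) {
    stop("a profile needs at least 2 probes to be ranked", call. = FALSE)
  }
  ids <- rownames(mat)
  ranks <- apply(mat, 2L, function(v) {
    ord <- order(-v, ids)
    r <- integer(m)
    r[ord] <- seq_len(m)
    r
  })
  out <- tibble::as_tibble(as.data.frame(ranks, optional = TRUE))
  dplyr::bind_cols(tibble::tibble(probe_id = ids), out)
}

#' Extract the two-sided signature of every ranked profile
#'
#' The signature of a profile is its `k` uptags (probes ranked `1:k`, the
#' most up-expressed) and `k` downtags (probes ranked `(m-k+1):m`, the most
#' down-expressed). `k` is the user's choice; `2k` must not exceed the probe
#' count or the two tag sets would overlap.
#'
#' @param ranks A ranked database as returned by [rank_profiles()].
#' @param k Number of probes per signature side.
#' @return A tibble with columns `instance_id`, `direction` (`"up"` or
#'   `"down"`), `tag_rank` (1..k within the side, in rank order) and
#'   `probe_id`.
#' @export
extract_signatures <- function(ranks, k) {
  mat <- as_expression_matrix(ranks)
  m <- nrow(mat)
  check_signature_size(k, m)
  ids <- rownames(mat)
  purrr::map_dfr(colnames(mat), function(inst) {
    r <- mat[, inst]
    up <- ids[order(r)][seq_len(k)]
    down <- ids[order(r)][(m - k + 1):m]
    tibble::tibble(
      instance_id = inst,
      direction = rep(c("up", "down"), each = k),
      tag_rank = rep(seq_len(k), 2L),
      probe_id = c(up, down)
    )
  })
}

check_signature_size <- function(k, m) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k != floor(k)) {
    stop("`k` must be a single positive integer", call. = FALSE)
  }
  if (2 * k > m) {
    stop(sprintf(
      "signature size k = %d too large for m = %d probes: uptags and downtags would overlap (need 2k <= m)",
      as.integer(k), m
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Convert an expression (or rank) tibble to a probes-by-instances matrix
#'
#' Validates the database invariants: unique probe ids, all-finite numeric
#' values, at least one instance column.
#'
#' @param expr Data frame with `probe_id` first column, or an already-named
#'   numeric matrix (returned unchanged after validation).
#' @return Numeric matrix with probe ids as rownames and instance ids as
#'   colnames.
#' @keywords internal
#' @export
as_expression_matrix <- function(expr) {
  if (is.matrix(expr)) {
    mat <- expr
    if (is.null(rownames(mat)) || is.null(colnames(mat))) {
      stop("expression matrix must carry probe rownames and instance colnames",
           call. = FALSE)
    }
  } else {
    expr <- as.data.frame(expr)
    if (ncol(expr) < 2L) {
      stop("expression table needs a probe_id column plus at least one instance",
           call. = FALSE)
    }
    probe_id <- as.character(expr[[1L]])
    mat <- as.matrix(expr[, -1L, drop = FALSE])
    rownames(mat) <- probe_id
  }
  if (anyDuplicated(rownames(mat))) {
    dup <- unique(rownames(mat)[duplicated(rownames(mat))])
    stop("duplicate probe_id: ", paste(utils::head(dup, 5L), collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(mat)) {
    stop("expression values must be numeric", call. = FALSE)
  }
  bad <- which(!is.finite(mat), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-finite value for probe ", rownames(mat)[bad[1L, 1L]],
         " in instance ", colnames(mat)[bad[1L, 2L]], call. = FALSE)
  }
  mat
}
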