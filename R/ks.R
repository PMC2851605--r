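#' One-sided truncated Kolmogorov-Smirnov enrichment score
#'
#' Measures where a tag set (for example a query's uptags) falls within a
#' target instance's full probe ranking. Let `V(1) < ... < V(t)` be the
#' target ranks of the `t` tags, sorted ascending, out of `m` probes. With
#' \deqn{a = \max_j (j/t - V(j)/m), \qquad b = \max_j (V(j)/m - (j-1)/t),}
#' the score is `a` if `a > b` and `-b` otherwise. It lies in (-1, 1]:
#' close to 1 when the tags cluster at the top of the target ranking, close
#' to -1 when they cluster at the bottom, near 0 when they are dispersed.
#'
#' @param tags Character vector of probe ids (a set; input order is
#'   irrelevant because the statistic sorts by target rank).
#' @param target_ranks Named integer vector: the target instance's full
#'   ranking, `rank 1 = most up-expressed` (one column of
#'   [rank_profiles()] output, named by probe).
#' @return A single number in (-1, 1].
#' @seealso [ks_score()] for the two-sided combination.
#' @export
ks_side <- function(tags, target_ranks) {
  if (is.null(names(target_ranks))) {
    stop("`target_ranks` must be named by probe_id", call. = FALSE)
  }
  missing <- setdiff(tags, names(target_ranks))
  if (length(missing) > 0L) {
    stop("tag probe not present in target ranking: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  m <- length(target_ranks)
  v <- sort(unname(target_ranks[tags]))
  ks_side_from_positions(v, m)
}

# core statistic on sorted tag positions v (ascending) among m probes
ks_side_from_positions <- function(v, m) {
  t <- length(v)
  j <- seq_len(t)
  a <- max(j / t - v / m)
  b <- max(v / m - (j - 1) / t)
  if (a > b) a else -b
}

#' Two-sided direct (connectivity-map style) KS score
#'
#' Combines the uptag and downtag one-sided scores of a query signature
#' against a target ranking. `ks_up` and `ks_down` are [ks_side()] applied
#' to the query's uptags and downtags. When both sides have the same sign
#' (both tag sets shifted toward the same end of the target ranking) the
#' distributions are not cleanly separated and the combined score is 0;
#' otherwise the combined score is `ks_up - ks_down`, which lies in
#' \eqn{[-2, 2]}. A side that is exactly 0 does not trigger the same-sign
#' rule.
#'
#' @param uptags,downtags Character vectors of probe ids (the query's
#'   signature sides).
#' @inheritParams ks_side
#' @return A list with elements `ks_up`, `ks_down`, `ks`.
#' @export
ks_score <- function(uptags, downtags, target_ranks) {
  ku <- ks_side(uptags, target_ranks)
  kd <- ks_side(downtags, target_ranks)
  list(ks_up = ku, ks_down = kd, ks = combine_ks(ku, kd))
}

combine_ks <- function(ks_up, ks_down) {
  if (ks_up * ks_down > 0) 0 else ks_up - ks_down
}

#' All pairwise direct KS scores of a database
#'
#' Extracts each instance's signature once, then scores every ordered
#' (query, target) pair, self-pairs included. Row `q` of the result is the
#' query's KS vector against the whole database, the input consumed by
#' [i2r_similarity()]. The matrix is not symmetric in general:
#' `scores[q, t]` uses q's signature against t's full ranking.
#'
#' @param expr Expression database: data frame with `probe_id` first column
#'   and one numeric column per instance (values ranked internally), or the
#'   output of [rank_profiles()] when `ranked = TRUE`.
#' @param k Signature size per side; `2k <= m`.
#' @param ranked Set to `TRUE` when `expr` already holds ranks.
#' @return A `ks_matrix`: an n-by-n numeric matrix with instance ids as
#'   dimnames, queries in rows, targets in columns.
#' @examples
#' db <- simulate_database(sim_config(m = 60, n_per_class = 3, classes = 2,
#'                                    sig_size = 5, seed = 1))
#' ks <- ks_similarity(db$expression, k = 5)
#' ks[1:3, 1:3]
#' @export
ks_similarity <- function(expr, k, ranked = FALSE) {
  mat <- as_expression_matrix(expr)
  if (ncol(mat) < 2L) {
    stop("need at least 2 instances for pairwise scores", call. = FALSE)
  }
  rk <- if (ranked) mat else rank_matrix(mat)
  m <- nrow(rk)
  n <- ncol(rk)
  check_signature_size(k, m)

  # signature row indices per instance, extracted once and reused
  ord <- apply(rk, 2L, order)           # ord[j, q] = row index of rank j in q
  up_idx <- ord[seq_len(k), , drop = FALSE]
  dn_idx <- ord[(m - k + 1):m, , drop = FALSE]

  scores <- matrix(0, n, n, dimnames = list(dimnames(rk)[[2L]], dimnames(rk)[[2L]]))
  jk <- seq_len(k)
  for (q in seq_len(n)) {
    pu <- rk[up_idx[, q], , drop = FALSE]   # k x n positions of q's uptags
    pd <- rk[dn_idx[, q], , drop = FALSE]
    if (k > 1L) {
      pu <- apply(pu, 2L, sort)
      pd <- apply(pd, 2L, sort)
    }
    au <- apply(jk / k - pu / m, 2L, max)
    bu <- apply(pu / m - (jk - 1) / k, 2L, max)
    ku <- ifelse(au > bu, au, -bu)
    ad <- apply(jk / k - pd / m, 2L, max)
    bd <- apply(pd / m - (jk - 1) / k, 2L, max)
    kd <- ifelse(ad > bd, ad, -bd)
    scores[q, ] <- ifelse(ku * kd > 0, 0, ku - kd)
  }
  new_sim_matrix(scores, "ks_matrix", method = "direct")
}

# column-wise ranking with the same tie-break as rank_profiles()
rank_matrix <- function(mat) {
  ids <- rownames(mat)
  m <- nrow(mat)
  apply(mat, 2L, function(v) {
    ord <- order(-v, ids)
    r <- integer(m)
    r[ord] <- seq_len(m)
    r
  })
}

new_sim_matrix <- function(x, class, method) {
  structure(x, class = c(class, "sim_matrix", class(x)), method = method)
}

#' @export
print.sim_matrix <- function(x, ...) {
  cat(sprintf("<%s> %d x %d instances (%s similarity)\n",
              class(x)[1L], nrow(x), ncol(x), attr(x, "method")))
  y <- unclass(x)
  attr(y, "method") <- NULL
  print(utils::head(y[, seq_len(min(5L, ncol(y))), drop = FALSE], 5L), ...)
  if (nrow(x) > 5L) cat("...\n")
  invisible(x)
}

#' Turn a similarity matrix into a long tibble
#'
#' @param x A `ks_matrix` or `i2r_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `query_id`, `target_id`, `score`.
#' @method tidy sim_matrix
#' @export
tidy.sim_matrix <- function(x, ...) {
  tibble::tibble(
    query_id = rep(rownames(x), times = ncol(x)),
    target_id = rep(colnames(x), each = nrow(x)),
    score = as.vector(unclass(x))
  )
}
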