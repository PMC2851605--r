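#' Spearman rank correlation with explicit tie handling
#'
#' When neither vector contains ties, uses the classical shortcut
#' \deqn{\rho = 1 - 6 \sum d_i^2 / (n(n^2-1))}
#' with `d_i` the per-position rank differences. With ties in either
#' vector, falls back to the Pearson correlation of average (fractional)
#' ranks; the two paths agree exactly on tie-free input. KS score vectors
#' contain many exact zeros, so the tie path is the effective default
#' downstream.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, finite, not
#'   constant.
#' @return Correlation in \eqn{[-1, 1]}.
#' @export
spearman_rank <- function(x, y) {
  n <- length(x)
  if (length(y) != n) {
    stop("`x` and `y` must have the same length", call. = FALSE)
  }
  if (n < 3L) {
    stop("need at least 3 observations", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  if (!anyDuplicated(x) && !anyDuplicated(y)) {
    d <- rx - ry
    1 - 6 * sum(d^2) / (n * (n^2 - 1))
  } else {
    stats::cor(rx, ry)
  }
}

#' Indirect similarity of one instance pair
#'
#' The indirect two-sided relative ranking score I2R(t, q) is the Spearman
#' correlation between q's and t's full vectors of direct KS scores against
#' every instance in the database, self-scores included: two instances are
#' indirectly similar when they rank the whole database the same way. The
#' score is symmetric in (q, t).
#'
#' @param ks A [ks_similarity()] matrix (queries in rows).
#' @param q,t Instance ids present in `ks`.
#' @return Correlation in \eqn{[-1, 1]}; exactly 1 when `q == t`.
#' @export
i2r_score <- function(ks, q, t) {
  ids <- rownames(ks)
  for (id in c(q, t)) {
    if (!id %in% ids) stop("unknown instance id: ", id, call. = FALSE)
  }
  if (q == t) return(1)
  spearman_rank(unclass(ks)[q, ], unclass(ks)[t, ])
}

#' Full indirect similarity matrix
#'
#' Correlates every pair of rows of the direct KS matrix, reusing the one
#' KS pass for all n^2 correlations (no direct score is recomputed). Each
#' row is rank-transformed once (average ranks for ties) and the n x n
#' Pearson correlation of the rank rows is taken, which is the Spearman
#' correlation with the tie handling of [spearman_rank()].
#'
#' A constant KS row (possible on degenerate data, every score identical)
#' has no defined correlation; its off-diagonal entries are recorded as 0
#' (neutral similarity) with a warning so downstream rankings stay total.
#'
#' @param ks A [ks_similarity()] matrix, `n >= 3`.
#' @return An `i2r_matrix`: symmetric n-by-n matrix, unit diagonal, entries
#'   in \eqn{[-1, 1]}.
#' @export
i2r_similarity <- function(ks) {
  s <- unclass(ks)
  attr(s, "method") <- NULL
  if (!is.matrix(s) || nrow(s) != ncol(s)) {
    stop("`ks` must be a complete square KS matrix", call. = FALSE)
  }
  n <- nrow(s)
  if (n < 3L) {
    stop("indirect scores need at least 3 instances", call. = FALSE)
  }
  rk <- t(apply(s, 1L, rank))            # fractional ranks within each row
  constant <- apply(rk, 1L, function(r) all(r == r[1L]))
  if (any(constant)) {
    warning("constant KS row(s), indirect score set to 0 for: ",
            paste(rownames(s)[constant], collapse = ", "), call. = FALSE)
    rk[constant, ] <- 0
  }
  out <- suppressWarnings(stats::cor(t(rk)))
  out <- (out + t(out)) / 2          # enforce exact symmetry
  out[constant, ] <- 0
  out[, constant] <- 0
  diag(out) <- 1
  out[out > 1] <- 1
  out[out < -1] <- -1
  dimnames(out) <- dimnames(s)
  new_sim_matrix(out, "i2r_matrix", method = "indirect")
}
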