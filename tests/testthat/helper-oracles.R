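# Independent oracles and small fixture builders shared across tests.

# Brute-force one-sided truncated KS: maximise the signed gap between the
# tags' empirical CDF and the uniform line over every probe position,
# scanning all m positions rather than only the tag jump points.
oracle_ks_side <- function(positions, m) {
  t <- length(positions)
  a <- -Inf
  b <- -Inf
  for (pos in seq_len(m)) {
    ecdf_at <- sum(positions <= pos) / t      # fraction of tags at rank <= pos
    ecdf_before <- sum(positions < pos) / t
    a <- max(a, ecdf_at - pos / m)
    b <- max(b, pos / m - ecdf_before)
  }
  if (a > b) a else -b
}

# Pearson correlation of fractional ranks, written out by hand.
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  mx <- mean(rx)
  my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Named rank vector for a target whose probes p1..pm sit at the given ranks.
ranks_named <- function(r) {
  stats::setNames(as.integer(r), paste0("p", seq_along(r)))
}

# Random expression database tibble (distinct values, no structure).
random_expr <- function(m, n, seed = 1) {
  withr::with_seed(seed, {
    vals <- matrix(stats::rnorm(m * n), m, n)
    tbl <- tibble::as_tibble(as.data.frame(vals))
    names(tbl) <- sprintf("s%02d", seq_len(n))
    dplyr::bind_cols(tibble::tibble(probe_id = sprintf("p%03d", seq_len(m))), tbl)
  })
}

# Random asymmetric KS-like matrix wrapped as a ks_matrix.
random_ks_matrix <- function(n, seed = 1) {
  withr::with_seed(seed, {
    s <- matrix(stats::runif(n * n, -2, 2), n, n)
    dimnames(s) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
    i2r:::new_sim_matrix(s, "ks_matrix", method = "direct")
  })
}

# Hand-built similarity matrix from a dense score table (square, ids on both
# dims); used for retrieval fixtures where scores are chosen by hand.
sim_from_matrix <- function(s, type = "ks_matrix") {
  i2r:::new_sim_matrix(s, type, method = if (type == "ks_matrix") "direct" else "indirect")
}

# 6-instance fixture: 2 classes x 2 batches, scores set so that for the two
# queries of classA/batch1 the rank-1 target is the same-class instance from
# batch2 (hand-enumerable recall).
fixture_sim_meta <- function() {
  ids <- c("a1", "a2", "a3", "b1", "b2", "b3")
  s <- matrix(0, 6, 6, dimnames = list(ids, ids))
  s["a1", ] <- c(0, 0.2, 0.9, 0.1, 0.1, 0.1)
  s["a2", ] <- c(0.2, 0, 0.9, 0.1, 0.1, 0.1)
  s["a3", ] <- c(0.5, 0.4, 0, 0.1, 0.1, 0.1)
  s["b1", ] <- c(0.1, 0.1, 0.1, 0, 0.3, 0.8)
  s["b2", ] <- c(0.1, 0.1, 0.1, 0.3, 0, 0.8)
  s["b3", ] <- c(0.1, 0.1, 0.1, 0.6, 0.5, 0)
  diag(s) <- 2
  meta <- tibble::tibble(
    instance_id = ids,
    class = rep(c("A", "B"), each = 3),
    vehicle = c("water", "water", "DMSO", "water", "water", "DMSO"),
    batch = c("b1", "b1", "b2", "b1", "b1", "b2")
  )
  list(sim = sim_from_matrix(s), meta = meta)
}

# Two-class block-structured similarity: within-class score hi, between lo.
block_sim <- function(classes, hi = 1, lo = 0) {
  n <- length(classes)
  s <- matrix(lo, n, n)
  for (i in seq_len(n)) {
    s[i, classes == classes[i]] <- hi
  }
  diag(s) <- hi
  ids <- sprintf("s%02d", seq_len(n))
  dimnames(s) <- list(ids, ids)
  sim_from_matrix(s)
}
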