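#' Permutation test for the indirect cohesion of an instance set
#'
#' Tests whether a set of instances (replicates, or members of one
#' therapeutic group) is more indirectly similar to each other than a
#' random set of the same size would be. The observed statistic `I2R_0` is
#' the average indirect score of the set; each of `r` trials draws the
#' same number of instances uniformly without replacement and computes the
#' same average `I2R_r`. The number of trials `s` with `I2R_r > I2R_0`
#' (strict) gives the p-value `s / r`.
#'
#' The default statistic averages I2R over all unordered within-set pairs
#' (self-pairs excluded). `statistic = "reference"` instead averages each
#' member's score to a fixed reference instance, an alternative reading of
#' set cohesion useful when one query anchors the set. An optional
#' `(s + 1) / (r + 1)` smoothed p-value is available; the unsmoothed `s/r`
#' is the default and can be exactly 0.
#'
#' @param i2r An [i2r_similarity()] matrix.
#' @param instance_set Character vector of at least 2 instance ids.
#' @param trials Number of random draws `r`.
#' @param seed Integer seed; results are fully reproducible given
#'   (matrix, set, trials, seed).
#' @param statistic `"pairs"` (default) or `"reference"`.
#' @param reference Instance id anchoring the `"reference"` statistic.
#' @param smoothing Use the `(s + 1) / (r + 1)` estimator.
#' @return Object of class `i2r_permutation` with fields `observed`,
#'   `trials`, `exceed_count`, `p_value`, `seed`; [glance()] method
#'   available.
#' @export
permutation_test <- function(i2r, instance_set, trials = 1000, seed = 1,
                             statistic = c("pairs", "reference"),
                             reference = NULL, smoothing = FALSE) {
  statistic <- match.arg(statistic)
  ids <- rownames(i2r)
  n <- length(ids)
  t_size <- length(instance_set)
  if (t_size < 2L) {
    stop("instance_set needs at least 2 members (no pairs otherwise)",
         call. = FALSE)
  }
  if (t_size >= n) stop("instance_set must be a strict subset", call. = FALSE)
  unknown <- setdiff(instance_set, ids)
  if (length(unknown) > 0L) {
    stop("unknown instance id(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  if (trials < 1) stop("trials must be >= 1", call. = FALSE)
  s_mat <- unclass(i2r)

  stat <- if (statistic == "pairs") {
    function(idx) {
      sub <- s_mat[idx, idx, drop = FALSE]
      mean(sub[upper.tri(sub)])
    }
  } else {
    if (is.null(reference) || !reference %in% ids) {
      stop("`reference` must name an instance for statistic = \"reference\"",
           call. = FALSE)
    }
    function(idx) mean(s_mat[reference, setdiff(idx, reference)])
  }

  observed <- stat(instance_set)
  draws <- withr::with_seed(as.integer(seed), {
    replicate(trials, stat(sample(ids, t_size)))
  })
  s <- sum(draws > observed)
  p <- if (smoothing) (s + 1) / (trials + 1) else s / trials
  structure(
    list(observed = observed, trials = as.integer(trials),
         exceed_count = as.integer(s), p_value = p,
         seed = as.integer(seed), statistic = statistic),
    class = "i2r_permutation"
  )
}

#' @export
print.i2r_permutation <- function(x, ...) {
  cat(sprintf(
    "Permutation test (%s statistic): observed I2R_0 = %.4f, %d/%d trials exceeded, p = %.4g\n",
    x$statistic, x$observed, x$exceed_count, x$trials, x$p_value
  ))
  invisible(x)
}

#' @method glance i2r_permutation
#' @export
glance.i2r_permutation <- function(x, ...) {
  tibble::tibble(observed = x$observed, trials = x$trials,
                 exceed_count = x$exceed_count, p_value = x$p_value,
                 seed = x$seed, statistic = x$statistic)
}
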