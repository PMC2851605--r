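#' Majority-vote classification from a similarity matrix
#'
#' Classifies each instance by the modal class among its `vote_k` nearest
#' neighbours (self excluded). An odd `vote_k` (default 11) avoids
#' two-class ties; residual multi-class ties are resolved by the larger
#' summed similarity among the tied classes, then by class name ascending.
#'
#' @param sim Similarity matrix.
#' @param labels Named character vector or tibble (`instance_id`, `class`)
#'   giving the true class of every instance.
#' @param vote_k Neighbourhood size, at most `n - 1`.
#' @return Tibble with columns `instance_id`, `class` (true),
#'   `predicted`, `correct`.
#' @export
classify_majority <- function(sim, labels, vote_k = 11) {
  labels <- as_labels(labels, rownames(sim))
  if (vote_k > nrow(sim) - 1L) {
    stop("vote_k exceeds the number of available neighbours", call. = FALSE)
  }
  purrr::map_dfr(rownames(sim), function(q) {
    hits <- top_hits(sim, q, vote_k)
    cls <- labels[hits$target_id]
    votes <- table(cls)
    winners <- names(votes)[votes == max(votes)]
    if (length(winners) > 1L) {
      sums <- vapply(winners, function(cl) sum(hits$score[cls == cl]), 0)
      winners <- winners[sums == max(sums)]
      winners <- sort(winners)
    }
    tibble::tibble(instance_id = q, class = unname(labels[q]),
                   predicted = winners[1L],
                   correct = winners[1L] == unname(labels[q]))
  })
}

#' Average retrieval rank of same-class instances
#'
#' For each instance, ranks all other instances by similarity (score
#' descending, id-ascending tie-break) and averages the 1-based ranks of
#' those sharing its class. Lower is better: a method that retrieves
#' class-mates early has a small average rank. This is the per-sample
#' quantity used to compare methods when there are too few groups for a
#' recall analysis.
#'
#' @inheritParams classify_majority
#' @return Tibble with columns `instance_id`, `class`, `average_rank`.
#' @export
average_ranks <- function(sim, labels) {
  labels <- as_labels(labels, rownames(sim))
  purrr::map_dfr(rownames(sim), function(q) {
    ord <- retrieval_order(sim, q)
    same <- ord$rank[labels[ord$target_id] == labels[q]]
    if (length(same) == 0L) {
      stop("no other instance of class ", labels[q], " for ", q,
           call. = FALSE)
    }
    tibble::tibble(instance_id = q, class = unname(labels[q]),
                   average_rank = mean(same))
  })
}

#' Ranks of true positives for every query of a group
#'
#' For each query instance of `group`, the retrieval rank of every other
#' same-group instance (one row per (query, true-positive) pair). These
#' paired per-method rank lists feed [paired_rank_ttest()].
#'
#' @inheritParams recall_at_k
#' @return Tibble with columns `query_id`, `target_id`, `rank`.
#' @export
true_positive_ranks <- function(sim, meta, group, barrier = "none") {
  mode <- barrier_mode(barrier)
  meta <- as_metadata(meta)
  check_barrier_metadata(meta, mode)
  queries <- meta$instance_id[meta$class == group]
  meta_by_id <- split(meta, meta$instance_id)
  purrr::map_dfr(queries, function(q) {
    ord <- retrieval_order(sim, q)
    keep <- vapply(ord$target_id, function(t) {
      mt <- meta_by_id[[t]]
      !is.null(mt) && mt$class == group && barrier_ok(mode, meta_by_id[[q]], mt)
    }, TRUE)
    tibble::tibble(query_id = q, target_id = ord$target_id[keep],
                   rank = ord$rank[keep])
  })
}

#' Paired t-test on true-positive retrieval ranks
#'
#' Compares how early two methods retrieve the same true positives. Pairs
#' where neither method places the true positive within `threshold`
#' (default 100) are dropped — differences that far down the list have no
#' practical interest — but if either method is within the threshold the
#' pair is kept so that method gets credit. Differences are
#' `rank_direct - rank_indirect`, so a positive mean improvement means the
#' indirect method ranked true positives better. The classic paired t
#' statistic with `n_pairs - 1` degrees of freedom and a two-sided p-value
#' is used. All-zero differences are degenerate with p = 1; a constant
#' non-zero difference has no finite t statistic and is flagged with
#' p = NA.
#'
#' @param ranks_direct,ranks_indirect Equal-length numeric vectors of
#'   retrieval ranks, paired per (query, true-positive).
#' @param threshold Search depth for the inclusion rule.
#' @return Object of class `rank_ttest` with fields `t_value`, `p_value`,
#'   `n_pairs`, `mean_improvement`, `sd_improvement`, `degenerate`;
#'   [tidy()] and [glance()] methods available.
#' @export
paired_rank_ttest <- function(ranks_direct, ranks_indirect, threshold = 100) {
  if (length(ranks_direct) != length(ranks_indirect)) {
    stop("rank lists must be paired (equal length)", call. = FALSE)
  }
  keep <- pmin(ranks_direct, ranks_indirect) <= threshold
  d <- ranks_direct[keep] - ranks_indirect[keep]
  n <- length(d)
  if (n < 2L) {
    stop("fewer than 2 pairs retained within the search threshold",
         call. = FALSE)
  }
  if (stats::sd(d) == 0) {
    res <- list(
      t_value = if (all(d == 0)) 0 else Inf * sign(d[1L]),
      p_value = if (all(d == 0)) 1 else NA_real_,
      n_pairs = n, mean_improvement = mean(d), sd_improvement = 0,
      degenerate = TRUE
    )
  } else {
    tt <- stats::t.test(d, mu = 0, alternative = "two.sided")
    res <- list(
      t_value = unname(tt$statistic), p_value = tt$p.value, n_pairs = n,
      mean_improvement = mean(d), sd_improvement = stats::sd(d),
      degenerate = FALSE
    )
  }
  structure(res, class = "rank_ttest")
}

#' @export
print.rank_ttest <- function(x, ...) {
  cat(sprintf(
    "Paired rank t-test: n = %d, mean improvement = %.2f (sd %.2f), t = %.2f, p = %.4g%s\n",
    x$n_pairs, x$mean_improvement, x$sd_improvement, x$t_value, x$p_value,
    if (x$degenerate) " [degenerate: zero-variance differences]" else ""
  ))
  invisible(x)
}

#' @method tidy rank_ttest
#' @export
tidy.rank_ttest <- function(x, ...) {
  tibble::tibble(estimate = x$mean_improvement, statistic = x$t_value,
                 p.value = x$p_value, parameter = x$n_pairs - 1L)
}

#' @method glance rank_ttest
#' @export
glance.rank_ttest <- function(x, ...) {
  tibble::tibble(n_pairs = x$n_pairs, mean_improvement = x$mean_improvement,
                 sd_improvement = x$sd_improvement, t_value = x$t_value,
                 p_value = x$p_value, degenerate = x$degenerate)
}

#' Area under the ROC curve by the rank-sum identity
#'
#' AUC equals the Mann-Whitney probability that a random positive pair
#' scores above a random negative pair; tied scores contribute 1/2.
#'
#' @param scores Numeric scores, higher = more likely positive.
#' @param positive Logical vector, `TRUE` for positive pairs.
#' @return AUC in \eqn{[0, 1]}.
#' @export
roc_auc <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) {
    stop("both positive and negative pairs are required", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pooled pairwise rank scores for ROC analysis
#'
#' Pools every ordered (query, target) pair (q != t) and scores it by the
#' negative retrieval rank of the target in the query's list, so that
#' higher scores mean earlier retrieval; the positive label marks
#' same-class pairs. This turns the retrieval ranks underlying the paired
#' t-tests into a classifier score for ROC/AUC comparison of methods.
#'
#' @inheritParams classify_majority
#' @return Tibble with columns `query_id`, `target_id`, `score`
#'   (`-rank`), `same_class`.
#' @export
pair_rank_scores <- function(sim, labels) {
  labels <- as_labels(labels, rownames(sim))
  purrr::map_dfr(rownames(sim), function(q) {
    ord <- retrieval_order(sim, q)
    tibble::tibble(query_id = q, target_id = ord$target_id,
                   score = -ord$rank,
                   same_class = labels[ord$target_id] == labels[q])
  })
}

#' DeLong test for the difference of two correlated AUCs
#'
#' Two-sided comparison of the AUCs of two score vectors computed on the
#' same labelled pairs, using the DeLong structural-components covariance
#' estimator for paired ROC curves (via \pkg{pROC}).
#'
#' @param scores_a,scores_b Numeric score vectors over the same pairs.
#' @param positive Logical labels shared by both score vectors.
#' @return List with `auc_a`, `auc_b`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, positive) {
  positive <- as.logical(positive)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(positive)) {
    stop("score vectors and labels must have equal length", call. = FALSE)
  }
  if (!any(positive) || all(positive)) {
    stop("both classes must be present", call. = FALSE)
  }
  ra <- pROC::roc(response = positive, predictor = scores_a,
                  levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  rb <- pROC::roc(response = positive, predictor = scores_b,
                  levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  if (identical(rank(scores_a), rank(scores_b))) {
    # identical ROC curves: zero AUC difference with zero variance
    return(list(auc_a = as.numeric(pROC::auc(ra)),
                auc_b = as.numeric(pROC::auc(rb)), p_value = 1))
  }
  tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  p <- tst$p.value
  if (!is.finite(p)) {
    stop("degenerate variance: DeLong test has insufficient data",
         call. = FALSE)
  }
  list(auc_a = as.numeric(pROC::auc(ra)), auc_b = as.numeric(pROC::auc(rb)),
       p_value = p)
}

as_labels <- function(labels, ids) {
  if (is.data.frame(labels)) {
    labels <- as_metadata(labels)
    lab <- stats::setNames(as.character(labels$class), labels$instance_id)
  } else {
    lab <- labels
  }
  missing <- setdiff(ids, names(lab))
  if (length(missing) > 0L) {
    stop("no class label for instance(s): ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  lab[ids]
}
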