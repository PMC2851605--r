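#' Top-k retrieval list for one query
#'
#' Ranks all other instances by similarity to the query, score descending,
#' the query itself excluded. Ties are broken by `target_id` ascending so
#' retrieval lists are stable across runs.
#'
#' @param sim Similarity matrix (`ks_matrix` or `i2r_matrix`); row `query`
#'   holds the query's scores against every target.
#' @param query Instance id of the query.
#' @param k How many hits to return; at most `n - 1`.
#' @return Tibble with columns `target_id`, `score`, `rank` (1-based).
#' @export
top_hits <- function(sim, query, k) {
  ord <- retrieval_order(sim, query)
  if (k > length(ord$target_id)) {
    stop(sprintf("k = %d exceeds the %d available targets", k,
                 length(ord$target_id)), call. = FALSE)
  }
  ord[seq_len(k), ]
}

# full retrieval ordering for a query: all non-self targets, score desc,
# id-ascending tie-break, 1-based rank
retrieval_order <- function(sim, query) {
  ids <- rownames(sim)
  if (!query %in% ids) stop("unknown instance id: ", query, call. = FALSE)
  scores <- unclass(sim)[query, ]
  targets <- setdiff(ids, query)
  s <- scores[targets]
  ord <- order(-s, targets)
  tibble::tibble(
    target_id = targets[ord],
    score = unname(s[ord]),
    rank = seq_along(ord)
  )
}

#' Experimental-barrier predicate
#'
#' Barriers restrict which retrieved instances count as recalled: only
#' targets screened under different experimental conditions than the query
#' demonstrate that a method sees through the confounder. Modes:
#' `"none"` (no restriction), `"vehicle"` (different delivery vehicle),
#' `"batch"` (different processing batch), `"vehicle+batch"` (both differ).
#'
#' @param mode One of `"none"`, `"vehicle"`, `"batch"`, `"vehicle+batch"`.
#' @return The matched mode string (validated).
#' @keywords internal
barrier_mode <- function(mode) {
  match.arg(mode, c("none", "vehicle", "batch", "vehicle+batch"))
}

barrier_fields <- function(mode) {
  switch(mode,
    none = character(),
    vehicle = "vehicle",
    batch = "batch",
    `vehicle+batch` = c("vehicle", "batch")
  )
}

check_barrier_metadata <- function(meta, mode) {
  for (f in barrier_fields(mode)) {
    if (!f %in% names(meta)) {
      stop("metadata lacks the `", f, "` column required by barrier ", mode,
           call. = FALSE)
    }
    bad <- meta$instance_id[is.na(meta[[f]]) | meta[[f]] == ""]
    if (length(bad) > 0L) {
      stop("missing ", f, " for instance(s): ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

barrier_ok <- function(mode, meta_q, meta_t) {
  ok <- TRUE
  for (f in barrier_fields(mode)) {
    ok <- ok && (meta_q[[f]] != meta_t[[f]])
  }
  ok
}

#' Recall at rank k for one therapeutic group
#'
#' Queries the database with every instance of the group and counts, summed
#' over the queries, the targets among each query's top `k` that belong to
#' the same group and satisfy the barrier against that query. The query
#' instance itself is never counted. This is the retrieval score a
#' signature-matching engine is judged by: how many known same-indication
#' treatments it surfaces despite the confounder.
#'
#' @inheritParams top_hits
#' @param meta Instance metadata tibble with columns `instance_id`,
#'   `class`, and `vehicle`/`batch` when a barrier needs them.
#' @param group Class label defining the query group.
#' @param k Retrieval depth (default 10).
#' @param barrier Barrier mode, see [barrier_mode()].
#' @return Integer count of recalled same-class instances.
#' @export
recall_at_k <- function(sim, meta, group, k = 10, barrier = "none") {
  mode <- barrier_mode(barrier)
  meta <- as_metadata(meta)
  check_barrier_metadata(meta, mode)
  queries <- meta$instance_id[meta$class == group]
  queries <- intersect(queries, rownames(sim))
  if (length(queries) == 0L) {
    stop("group has no instances in the similarity matrix: ", group,
         call. = FALSE)
  }
  meta_by_id <- split(meta, meta$instance_id)
  total <- 0L
  for (q in queries) {
    hits <- top_hits(sim, q, k)
    mq <- meta_by_id[[q]]
    for (t in hits$target_id) {
      mt <- meta_by_id[[t]]
      if (!is.null(mt) && mt$class == group && barrier_ok(mode, mq, mt)) {
        total <- total + 1L
      }
    }
  }
  total
}

#' Percent improvement of indirect recall over direct recall
#'
#' `100 * (indirect - direct) / direct`. A baseline of zero makes the
#' percentage meaningless, so `direct = 0` returns a special-case marker
#' carrying the indirect count instead of a number; such groups are
#' reported separately and excluded from improvement averages.
#'
#' @param indirect,direct Recall counts (non-negative integers).
#' @return A number, or a `special_case` object when `direct == 0` (test
#'   with [is_special_case()]).
#' @examples
#' percent_improvement(3, 2)  # 50
#' percent_improvement(3, 1)  # 200
#' percent_improvement(8, 0)  # special case
#' @export
percent_improvement <- function(indirect, direct) {
  if (indirect < 0 || direct < 0) {
    stop("recall counts must be non-negative", call. = FALSE)
  }
  if (direct == 0) {
    return(special_case(indirect))
  }
  100 * (indirect - direct) / direct
}

special_case <- function(indirect) {
  structure(list(indirect = indirect), class = "i2r_special_case")
}

#' @rdname percent_improvement
#' @param x Object to test.
#' @export
is_special_case <- function(x) inherits(x, "i2r_special_case")

#' @export
print.i2r_special_case <- function(x, ...) {
  cat(sprintf("special case: direct recall 0, indirect recall %d\n",
              x$indirect))
  invisible(x)
}

#' Positive predictive value of a retrieval run
#'
#' Recalled true positives divided by the total retrieved slots
#' (`queries * k`). Group-level PPVs are averaged unweighted across groups
#' by the report generator.
#'
#' @param recalled_true True positives recalled over all queries of the
#'   group.
#' @param queries Number of queries issued.
#' @param k Retrieval depth per query.
#' @return Proportion in \eqn{[0, 1]}.
#' @export
ppv <- function(recalled_true, queries, k) {
  if (queries < 1 || k < 1) stop("queries and k must be >= 1", call. = FALSE)
  if (recalled_true > queries * k) {
    stop("recalled_true cannot exceed queries * k", call. = FALSE)
  }
  recalled_true / (queries * k)
}

#' Direct-versus-indirect recall report across groups
#'
#' Runs the barrier recall evaluation for every eligible class with both
#' similarity matrices and tabulates counts, percent improvement (with the
#' zero-baseline special case flagged) and PPVs. Groups smaller than
#' `min_group_size` instances are dropped to avoid unrepresentative
#' small-sample results (default 10).
#'
#' @param direct,indirect Similarity matrices over the same instances
#'   (typically [ks_similarity()] and [i2r_similarity()] output).
#' @inheritParams recall_at_k
#' @param min_group_size Minimum instances for a class to be evaluated.
#' @return Tibble with one row per group: `group`, `n_instances`, `k`,
#'   `barrier`, `direct_count`, `indirect_count`, `improvement_pct`
#'   (`NA` for special cases), `special_case`, `ppv_direct`,
#'   `ppv_indirect`.
#' @export
recall_report <- function(direct, indirect, meta, k = 10,
                          barrier = "vehicle+batch", min_group_size = 10) {
  mode <- barrier_mode(barrier)
  meta <- as_metadata(meta)
  sizes <- table(meta$class)
  groups <- sort(names(sizes)[sizes >= min_group_size])
  if (length(groups) == 0L) {
    stop("no group reaches min_group_size = ", min_group_size, call. = FALSE)
  }
  purrr::map_dfr(groups, function(g) {
    nq <- sum(meta$class == g)
    dc <- recall_at_k(direct, meta, g, k = k, barrier = mode)
    ic <- recall_at_k(indirect, meta, g, k = k, barrier = mode)
    imp <- percent_improvement(ic, dc)
    tibble::tibble(
      group = g,
      n_instances = nq,
      k = as.integer(k),
      barrier = mode,
      direct_count = dc,
      indirect_count = ic,
      improvement_pct = if (is_special_case(imp)) NA_real_ else imp,
      special_case = is_special_case(imp),
      ppv_direct = ppv(dc, nq, k),
      ppv_indirect = ppv(ic, nq, k)
    )
  })
}

#' Recall as a function of retrieval depth
#'
#' Computes group recall for both methods over a range of `k`, the data
#' behind a recall-vs-k comparison curve.
#'
#' @inheritParams recall_report
#' @param group Single class label.
#' @param k_values Integer vector of retrieval depths.
#' @return Tibble with columns `k`, `method`, `recall`.
#' @export
recall_curve <- function(direct, indirect, meta, group,
                         k_values = seq(10, 100, by = 10),
                         barrier = "vehicle+batch") {
  purrr::map_dfr(k_values, function(kk) {
    tibble::tibble(
      k = as.integer(kk),
      method = c("direct", "indirect"),
      recall = c(recall_at_k(direct, meta, group, k = kk, barrier = barrier),
                 recall_at_k(indirect, meta, group, k = kk, barrier = barrier))
    )
  })
}

as_metadata <- function(meta) {
  meta <- tibble::as_tibble(meta)
  if (!all(c("instance_id", "class") %in% names(meta))) {
    stop("metadata needs `instance_id` and `class` columns", call. = FALSE)
  }
  if (anyDuplicated(meta$instance_id)) {
    stop("duplicate instance_id in metadata", call. = FALSE)
  }
  meta
}
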