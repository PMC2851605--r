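test_that("block databases classify perfectly by majority vote", {
  classes <- rep(c("A", "B"), each = 8)
  sim <- block_sim(classes)
  meta <- tibble::tibble(instance_id = rownames(sim), class = classes)
  res <- classify_majority(sim, meta, vote_k = 11)
  expect_true(all(res$correct))
  expect_equal(res$predicted, classes)
})

test_that("vote_k = 1 is nearest-neighbour labelling", {
  withr::with_seed(20, {
    n <- 12
    s <- matrix(stats::runif(n * n), n, n)
    ids <- sprintf("s%02d", 1:n)
    dimnames(s) <- list(ids, ids)
    sim <- sim_from_matrix(s)
    classes <- stats::setNames(rep(c("A", "B", "C"), 4), ids)
    res <- classify_majority(sim, classes, vote_k = 1)
    for (i in seq_len(n)) {
      nn <- top_hits(sim, ids[i], 1)$target_id
      expect_equal(res$predicted[i], unname(classes[nn]))
    }
  })
})

test_that("multi-class vote ties resolve by summed similarity", {
  # 12 instances; query q sees 5 A's, 5 B's and 1 C in its top 11, with the
  # B neighbours scoring higher in total: the 5/5 tie must go to B
  ids <- c("q", paste0("a", 1:5), paste0("b", 1:5), "c1")
  n <- length(ids)
  s <- matrix(0, n, n, dimnames = list(ids, ids))
  s["q", paste0("a", 1:5)] <- c(0.90, 0.80, 0.70, 0.60, 0.50)
  s["q", paste0("b", 1:5)] <- c(0.95, 0.85, 0.75, 0.65, 0.55)
  s["q", "c1"] <- 0.40
  s[lower.tri(s)] <- t(s)[lower.tri(s)]
  diag(s) <- 1
  sim <- sim_from_matrix(s)
  labels <- stats::setNames(c("C", rep("A", 5), rep("B", 5), "C"), ids)
  res <- classify_majority(sim, labels, vote_k = 11)
  expect_equal(res$predicted[res$instance_id == "q"], "B")
  expect_error(classify_majority(sim, labels, vote_k = 12), "neighbours")
})

test_that("average rank of a leading class block is (c+1)/2", {
  classes <- rep(c("A", "B"), each = 6)
  sim <- block_sim(classes)
  meta <- tibble::tibble(instance_id = rownames(sim), class = classes)
  ar <- average_ranks(sim, meta)
  # each query's 5 class-mates occupy ranks 1..5 -> mean 3
  expect_equal(ar$average_rank, rep(3, 12))
})

test_that("average rank matches a brute-force lookup on random data", {
  withr::with_seed(8, {
    n <- 15
    s <- matrix(stats::runif(n * n), n, n)
    ids <- sprintf("s%02d", 1:n)
    dimnames(s) <- list(ids, ids)
    sim <- sim_from_matrix(s)
    classes <- stats::setNames(sample(c("A", "B", "C"), n, TRUE), ids)
    while (min(table(classes)) < 2) {
      classes <- stats::setNames(sample(c("A", "B", "C"), n, TRUE), ids)
    }
    ar <- average_ranks(sim, classes)
    for (q in ids) {
      others <- setdiff(ids, q)
      ord <- others[order(-s[q, others], others)]
      expected <- mean(which(classes[ord] == classes[q]))
      expect_equal(ar$average_rank[ar$instance_id == q], expected)
    }
  })
})

test_that("single same-class instance at rank r gives average rank r", {
  ids <- paste0("s", 1:8)
  s <- matrix(0, 8, 8, dimnames = list(ids, ids))
  s["s1", ] <- c(0, 8:2) / 10
  s["s1", "s8"] <- 0.15   # s8 lands at rank 7 of s1's list
  sim <- sim_from_matrix(s)
  labels <- stats::setNames(c("X", rep("Y", 6), "X"), ids)
  ar <- average_ranks(sim, labels)
  expect_equal(ar$average_rank[ar$instance_id == "s1"], 7)
  expect_error(average_ranks(sim, stats::setNames(c("X", rep("Y", 7)), ids)),
               "no other instance")
})

test_that("true_positive_ranks pairs each query with its class-mates", {
  fx <- fixture_sim_meta()
  tp <- true_positive_ranks(fx$sim, fx$meta, "A")
  expect_equal(nrow(tp), 6L)  # 3 queries x 2 class-mates
  a1 <- tp[tp$query_id == "a1", ]
  expect_equal(a1$rank[a1$target_id == "a3"], 1L)
  expect_equal(a1$rank[a1$target_id == "a2"], 2L)
})

test_that("paired rank t-test applies the inclusion rule and degenerate contracts", {
  expect_error(paired_rank_ttest(1:3, 1:4), "paired")

  same <- c(3, 8, 15)
  res <- paired_rank_ttest(same, same)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  expect_equal(res$mean_improvement, 0)

  shifted <- paired_rank_ttest(rep(10, 10) + 5, rep(10, 10))
  expect_true(shifted$degenerate)
  expect_equal(shifted$mean_improvement, 5)
  expect_true(is.na(shifted$p_value))

  # pairs beyond the threshold on both sides are dropped; one method inside
  # the threshold keeps the pair even when the other is far outside
  d <- c(5, 300, 20, 400)
  i <- c(10, 350, 90, 80)
  res <- paired_rank_ttest(d, i, threshold = 100)
  expect_equal(res$n_pairs, 3L)  # (300,350) dropped, (400,80) kept
  expect_equal(res$mean_improvement, mean(c(-5, -70, 320)))

  # non-degenerate path matches stats::t.test
  withr::with_seed(2, {
    rd <- sample(1:80, 20, TRUE)
    ri <- sample(1:80, 20, TRUE)
    res <- paired_rank_ttest(rd, ri, threshold = 100)
    tt <- stats::t.test(rd, ri, paired = TRUE)
    expect_equal(res$t_value, unname(tt$statistic))
    expect_equal(res$p_value, tt$p.value)
    expect_equal(glance(res)$n_pairs, 20L)
  })
})

test_that("roc_auc counts concordant pairs exactly", {
  expect_equal(roc_auc(c(4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(c(4, 3, 2, 1), c(TRUE, FALSE, TRUE, FALSE)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE)), 0)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both")
})

test_that("roc_auc matches pROC and flips under score negation", {
  withr::with_seed(40, {
    scores <- stats::rnorm(60)
    labels <- stats::runif(60) < 0.4
    labels[1] <- TRUE; labels[2] <- FALSE
    a <- roc_auc(scores, labels)
    b <- as.numeric(pROC::auc(pROC::roc(labels, scores,
                                        levels = c(FALSE, TRUE),
                                        direction = "<", quiet = TRUE)))
    expect_equal(a, b, tolerance = 1e-12)
    expect_equal(roc_auc(-scores, labels), 1 - a, tolerance = 1e-12)
  })
})

test_that("pair_rank_scores pools ordered pairs with negative-rank scores", {
  fx <- fixture_sim_meta()
  pr <- pair_rank_scores(fx$sim, fx$meta)
  expect_equal(nrow(pr), 6L * 5L)
  a1 <- pr[pr$query_id == "a1", ]
  expect_equal(a1$score[a1$target_id == "a3"], -1)
  expect_true(a1$same_class[a1$target_id == "a2"])
  expect_false(a1$same_class[a1$target_id == "b1"])
})

test_that("delong_test contracts: identical scores give p = 1, separation wins", {
  withr::with_seed(60, {
    labels <- rep(c(TRUE, FALSE), each = 100)
    perfect <- ifelse(labels, 1, 0) + stats::rnorm(200, 0, 0.05)
    noise <- stats::rnorm(200)
    same <- delong_test(noise, noise, labels)
    expect_equal(same$p_value, 1)
    comp <- delong_test(perfect, noise, labels)
    expect_lt(comp$p_value, 0.01)
    expect_gt(comp$auc_a, 0.95)
    expect_error(delong_test(noise, noise, rep(TRUE, 200)), "both classes")
  })
})
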