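test_that("the generator is deterministic given a seed", {
  cfg <- sim_config(m = 100, n_per_class = 4, classes = 2, sig_size = 10,
                    seed = 99)
  db1 <- simulate_database(cfg)
  db2 <- simulate_database(cfg)
  expect_identical(db1, db2)
  db3 <- simulate_database(sim_config(m = 100, n_per_class = 4, classes = 2,
                                      sig_size = 10, seed = 100))
  expect_false(identical(db1$expression, db3$expression))
})

test_that("dimensions, metadata and signature layout match the config", {
  cfg <- sim_config(m = 150, n_per_class = 5, classes = 3, batches = 2,
                    vehicles = 2, sig_size = 10, seed = 1)
  db <- simulate_database(cfg)
  expect_equal(dim(db$expression), c(150L, 16L))
  expect_equal(nrow(db$metadata), 15L)
  expect_equal(sort(unique(db$metadata$class)),
               c("class01", "class02", "class03"))
  expect_equal(sort(unique(db$metadata$batch)), c("batch01", "batch02"))
  expect_length(unique(db$metadata$instance_id), 15L)
  # crossed design: every class spans every batch
  tab <- table(db$metadata$class, db$metadata$batch)
  expect_true(all(tab > 0))
  # disjoint class signatures
  expect_equal(anyDuplicated(db$signatures$probe_id), 0L)
  expect_equal(nrow(db$signatures), 3L * 2L * 10L)
})

test_that("nested confounding ties class to batch", {
  db <- simulate_database(sim_config(m = 100, n_per_class = 4, classes = 2,
                                     batches = 2, sig_size = 5,
                                     confounding = "nested", seed = 2))
  tab <- table(db$metadata$class, db$metadata$batch)
  expect_equal(sum(tab > 0), 2L)  # one batch per class
})

test_that("marginal amplitude variance decomposes additively", {
  cfg <- sim_config(m = 2000, n_per_class = 30, classes = 2, batches = 10,
                    vehicles = 5, effect_size = 1, sig_size = 100,
                    batch_sd = 1.2, vehicle_sd = 0.7, noise_sd = 0.5,
                    seed = 33)
  db <- simulate_database(cfg)
  mat <- as_expression_matrix(db$expression)
  sig_probes <- unique(db$signatures$probe_id)
  is_sig <- rownames(mat) %in% sig_probes
  nuisance_var <- 1.2^2 + 0.7^2 + 0.5^2
  v_bg <- stats::var(as.vector(mat[!is_sig, ]))
  # a signature probe carries +/-delta only in its own class's columns
  # (1/g of them), adding delta^2/g to the pooled variance
  v_sig <- stats::var(as.vector(mat[is_sig, ]))
  expect_equal(v_bg, nuisance_var, tolerance = 0.1 * nuisance_var)
  expect_equal(v_sig, nuisance_var + 1 / 2,
               tolerance = 0.1 * (nuisance_var + 1 / 2))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(m = 100, classes = 3, sig_size = 20), "overlap")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(batch_sd = -1), ">= 0")
  expect_error(sim_config(m = 1, n_per_class = 1, classes = 1, sig_size = 0),
               "positive|overlap|m >= 2")
})

test_that("the noise-free limit gives perfect recall for both methods", {
  db <- simulate_database(sim_config(m = 200, n_per_class = 4, classes = 2,
                                     batches = 2, sig_size = 20,
                                     effect_size = 2, batch_sd = 1e-9,
                                     vehicle_sd = 1e-9, noise_sd = 1e-6,
                                     seed = 12))
  ks <- ks_similarity(db$expression, k = 20)
  i2 <- i2r_similarity(ks)
  for (g in c("class01", "class02")) {
    expect_equal(recall_at_k(ks, db$metadata, g, k = 3, barrier = "none"), 12L)
    expect_equal(recall_at_k(i2, db$metadata, g, k = 3, barrier = "none"), 12L)
  }
})

test_that("class labels carry no signal when the effect size is zero", {
  # with delta = 0 the expected same-class fraction of any top-k list is the
  # chance level (n/g - 1)/(n - 1), whatever batch/vehicle structure exists,
  # because labels are independent of the profiles
  frac <- vapply(1:10, function(s) {
    db <- simulate_database(sim_config(m = 100, n_per_class = 20, classes = 2,
                                       batches = 2, sig_size = 10,
                                       effect_size = 0, batch_sd = 0.5,
                                       noise_sd = 0.5, seed = s))
    ks <- ks_similarity(db$expression, k = 10)
    tot <- sum(vapply(c("class01", "class02"), function(g) {
      recall_at_k(ks, db$metadata, g, k = 5, barrier = "none")
    }, 0L))
    tot / (40 * 5)   # recalled fraction of retrieval slots
  }, 0)
  expect_lt(abs(mean(frac) - 19 / 39), 0.1)
})

test_that("strong batch effects batch-dominate direct neighbourhoods while
           indirect keeps above-chance class recall", {
  db <- simulate_database(sim_config(m = 300, n_per_class = 15, classes = 2,
                                     batches = 3, sig_size = 20,
                                     effect_size = 1, batch_sd = 8,
                                     vehicle_sd = 0, noise_sd = 0.5,
                                     seed = 21))
  ks <- ks_similarity(db$expression, k = 20)
  i2 <- i2r_similarity(ks)
  meta <- db$metadata
  same_batch_frac <- mean(vapply(meta$instance_id, function(q) {
    hits <- top_hits(ks, q, 5)
    qb <- meta$batch[meta$instance_id == q]
    mean(meta$batch[match(hits$target_id, meta$instance_id)] == qb)
  }, 0))
  expect_gt(same_batch_frac, 0.9)
  total <- sum(vapply(c("class01", "class02"), function(g) {
    recall_at_k(i2, meta, g, k = 5, barrier = "none")
  }, 0L))
  # chance level: 5 slots x 14/29 same-class fraction x 30 queries
  expect_gt(total, 5 * 14 / 29 * 30)
})
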