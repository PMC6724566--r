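test_that("ARI closed forms: perfect agreement and maximal disagreement", {
  true <- rep(c("a", "b", "c"), each = 4)
  expect_equal(adjusted_rand_index(true, true), 1)
  # same partition under different names is still perfect
  relabeled <- rep(c("x", "y", "z"), each = 4)
  expect_equal(adjusted_rand_index(true, relabeled), 1)
  # one cluster vs all singletons: numerator and expectation both zero
  n <- 10
  expect_equal(adjusted_rand_index(rep("a", n), as.character(seq_len(n))), 0)
  expect_error(adjusted_rand_index(c("a", "b"), "a"), "equal length")
  expect_error(adjusted_rand_index(character(0), character(0)), "non-empty")
  expect_message(adjusted_rand_index("a", "b"), "degenerate")
})

test_that("ARI agrees exactly with brute-force pair counting", {
  set.seed(606)
  for (rep_i in 1:40) {
    n <- sample(6:25, 1)
    true <- sample(letters[1:4], n, replace = TRUE)
    pred <- sample(letters[1:4], n, replace = TRUE)
    expect_equal(adjusted_rand_index(true, pred), oracle_ari(true, pred))
  }
})

test_that("ARI is invariant under relabeling either partition", {
  set.seed(607)
  true <- sample(letters[1:5], 40, replace = TRUE)
  pred <- sample(letters[1:5], 40, replace = TRUE)
  base <- adjusted_rand_index(true, pred)
  relab <- setNames(LETTERS[1:5], letters[1:5])
  expect_equal(adjusted_rand_index(unname(relab[true]), pred), base)
  expect_equal(adjusted_rand_index(true, unname(relab[pred])), base)
})

test_that("ARI of an independent cross-check implementation agrees", {
  skip_if_not_installed("mclust")
  set.seed(608)
  for (rep_i in 1:20) {
    true <- sample(letters[1:4], 60, replace = TRUE)
    pred <- sample(letters[1:4], 60, replace = TRUE)
    expect_equal(adjusted_rand_index(true, pred),
                 mclust::adjustedRandIndex(true, pred), tolerance = 1e-12)
  }
})

test_that("evaluation reports accuracy, ARI and a bootstrap interval", {
  true <- rep(c("x", "y"), each = 10)
  pred <- true
  ev <- evaluate_predictions(true, pred, n_boot = 200, seed = 1)
  expect_s3_class(ev, "tcr_evaluation")
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$ari, 1)
  expect_equal(ev$boot$lower, 1)
  expect_equal(ev$boot$upper, 1)
  expect_equal(ev$n_abstained, 0L)
  expect_equal(sum(ev$confusion), 20)
})

test_that("bootstrap percentiles bracket the point estimate", {
  set.seed(609)
  true <- sample(letters[1:3], 60, replace = TRUE)
  pred <- ifelse(runif(60) < 0.7, true, sample(letters[1:3], 60,
                                               replace = TRUE))
  ev <- evaluate_predictions(true, pred, n_boot = 500, seed = 2)
  expect_lte(ev$boot$lower, ev$ari)
  expect_gte(ev$boot$upper, ev$ari)
})

test_that("evaluation is deterministic under a fixed seed", {
  set.seed(610)
  true <- sample(letters[1:3], 50, replace = TRUE)
  pred <- sample(letters[1:3], 50, replace = TRUE)
  ev1 <- evaluate_predictions(true, pred, n_boot = 300, seed = 99)
  ev2 <- evaluate_predictions(true, pred, n_boot = 300, seed = 99)
  expect_identical(ev1$boot, ev2$boot)
  # and restores the caller's RNG stream
  set.seed(42); before <- runif(1)
  set.seed(42); invisible(evaluate_predictions(true, pred, n_boot = 10,
                                               seed = 5))
  expect_identical(runif(1), before)
})

test_that("abstentions are excluded from ARI but counted", {
  true <- rep(c("x", "y"), each = 5)
  pred <- true
  pred[c(2, 7)] <- NA
  ev <- evaluate_predictions(true, pred, n_boot = 50, seed = 3)
  expect_equal(ev$n_abstained, 2L)
  expect_equal(ev$n_predictions, 8L)
  expect_equal(ev$accuracy, 1)
  strict <- evaluate_predictions(true, pred, n_boot = 50, seed = 3,
                                 strict = TRUE)
  expect_equal(strict$accuracy, 0.8)
  expect_error(evaluate_predictions(true, rep(NA_character_, 10)),
               "abstained")
})

test_that("benchmark_curve emits one scored row per threshold", {
  cfg <- synth_config(n_epitopes = 3, tcrs_per_epitope = 4,
                      mutation_rate = 0.05, seed = 611)
  synth <- generate_repertoire(cfg)
  curve <- suppressWarnings(
    benchmark_curve(synth$repertoire, "CDR(1:1:1-1:1:1)",
                    thresholds = c(99, 90), n_boot = 50, seed = 4))
  expect_equal(nrow(curve), 2L)
  expect_equal(curve$threshold, c(99, 90))
  expect_true(all(curve$ari_lower <= curve$ari + 1e-12))
  expect_true(all(curve$ari_upper >= curve$ari - 1e-12))
  # a duplicate-free repertoire scores identically at 100 and 99
  curve2 <- suppressWarnings(
    benchmark_curve(synth$repertoire, "CDR(1:1:1-1:1:1)",
                    thresholds = c(100, 99), n_boot = 50, seed = 4))
  expect_equal(curve2$ari[1], curve2$ari[2])
  expect_equal(curve2$accuracy[1], curve2$accuracy[2])
})
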