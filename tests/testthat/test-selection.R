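test_that("ANOVA-F scores match stats::aov on small cases", {
  fps <- make_fps(n_per_class = 6,
                  shifts = matrix(c(0, 0.5, 0.2, 1.2, 0.8, 0.2), nrow = 2),
                  noise_sd = 0.3, seed = 13)
  scores <- kbest_scores(fps)
  for (f in c("F1", "F2")) {
    fit <- stats::aov(fps[[f]] ~ factor(fps$class_label))
    f_oracle <- summary(fit)[[1]][["F value"]][1]
    expect_equal(unname(scores$score[scores$feature == f]), f_oracle,
                 tolerance = 1e-10)
  }
})

test_that("KBest ranks a separating feature first and ties average", {
  fps <- make_fps(n_per_class = 8,
                  shifts = matrix(c(0, 0, 1, 0, 2, 0), nrow = 2),
                  noise_sd = 0.05, seed = 2)
  # F1 tracks the class index, F2 is pure noise
  sc <- kbest_scores(fps)
  expect_equal(sc$rank[sc$feature == "F1"], 1)
  expect_equal(sc$rank[sc$feature == "F2"], 2)

  # duplicated feature -> identical scores, average ranks
  fps$F3 <- fps$F1
  sc3 <- kbest_scores(fps)
  expect_equal(sc3$score[sc3$feature == "F1"], sc3$score[sc3$feature == "F3"])
  expect_equal(sort(sc3$rank[sc3$feature %in% c("F1", "F3")]), c(1.5, 1.5))
})

test_that("zero within-class variance scores Inf; constant features score 0", {
  fps <- tibble::tibble(
    sample_id = sprintf("s%d", 1:8),
    class_label = rep(c("a", "b"), each = 4),
    sep = rep(c(0, 1), each = 4),   # perfect separator, no noise
    flat = rep(0.5, 8),             # fully constant
    ok = c(0.1, 0.2, 0.15, 0.12, 0.8, 0.9, 0.85, 0.82)
  )
  expect_warning(sc <- kbest_scores(fps), "Inf")
  expect_identical(sc$score[sc$feature == "sep"], Inf)
  expect_identical(sc$rank[sc$feature == "sep"], 1)
  expect_identical(sc$score[sc$feature == "flat"], 0)
})

test_that("pure-noise features land in the bottom quartile of the ranking", {
  shifts <- rbind(matrix(rep((0:4) * 0.3, each = 6), nrow = 6),
                  matrix(0, 2, 5)) # features 7, 8 carry no signal
  hit <- vapply(1:20, function(s) {
    fps <- make_fps(n_per_class = 6, shifts = shifts, noise_sd = 0.15, seed = s)
    sc <- kbest_scores(fps)
    all(sc$rank[sc$feature %in% c("F7", "F8")] > 6)
  }, logical(1))
  expect_gte(mean(hit), 0.8)
})

test_that("permutation importance behaves at its fixed points", {
  fps <- make_fps(n_per_class = 10,
                  shifts = matrix(c(0, 0.5, 1, 0.5), nrow = 2),
                  noise_sd = 0.03, seed = 5)
  fps$F2 <- 0.5 # constant: shuffling it cannot change predictions
  spec <- classifier_spec("linear_discriminant_analysis")
  # lda rejects constant columns, so score the constant feature with knn
  spec_k <- classifier_spec("k_nearest_neighbours")
  imp <- permutation_importance(fps, spec_k, n_permutations = 20, seed = 3)
  expect_equal(imp$score[imp$feature == "F2"], 0)

  # sole perfectly predictive feature: importance ~ accuracy - chance
  solo <- fps[c("sample_id", "class_label", "F1")]
  imp_solo <- permutation_importance(solo, spec, n_permutations = 100, seed = 4)
  expect_gt(imp_solo$score[imp_solo$feature == "F1"], 30)

  # seed determinism
  i1 <- permutation_importance(fps, spec_k, n_permutations = 10, seed = 7)
  i2 <- permutation_importance(fps, spec_k, n_permutations = 10, seed = 7)
  expect_identical(i1, i2)
  expect_error(permutation_importance(fps, spec, n_permutations = 0), "at least 1")
})

test_that("tree importance finds the informative feature and is reproducible", {
  fps <- make_fps(n_per_class = 10,
                  shifts = matrix(c(0, 0.5, 1, 0.5), nrow = 2),
                  noise_sd = 0.05, seed = 6)
  t1 <- tree_importance(fps, n_trees = 200, seed = 9)
  t2 <- tree_importance(fps, n_trees = 200, seed = 9)
  expect_identical(t1, t2)
  expect_equal(t1$rank[t1$feature == "F1"], 1)
})

test_that("combined rank sums per-method ranks with the stated tie-breaks", {
  mk <- function(feature, score, rank) tibble::tibble(
    feature = feature, score = score, rank = rank)
  kb <- mk(c("a", "b", "c"), c(30, 20, 10), c(1, 2, 3))
  tr <- mk(c("a", "b", "c"), c(5, 9, 1), c(2, 1, 3))
  pm <- mk(c("a", "b", "c"), c(9, 1, 5), c(1, 3, 2))
  cr <- combined_rank(kb, tr, pm)
  expect_equal(cr$combined_rank, c(4, 6, 8))
  expect_equal(cr$feature, c("a", "b", "c"))

  # permutation-invariance to method order is inherent in a sum; combined
  # rank equality breaks ties by kbest rank, then identifier
  kb2 <- mk(c("x", "y"), c(1, 2), c(2, 1))
  tr2 <- mk(c("x", "y"), c(2, 1), c(1, 2))
  pm2 <- mk(c("x", "y"), c(1, 1), c(1.5, 1.5))
  cr2 <- combined_rank(kb2, tr2, pm2)
  expect_equal(cr2$combined_rank, c(4.5, 4.5))
  expect_equal(cr2$feature[1], "y") # better kbest rank wins the tie

  expect_error(combined_rank(kb, tr, mk("z", 1, 1)), "same feature set")
})

test_that("all methods agreeing gives the common order; planted barrels are recovered", {
  fps <- make_fps(n_per_class = 8,
                  shifts = matrix(c(0, 0, 0, 1.5, 0.5, 0, 0.2, 1, 0.1), nrow = 3),
                  noise_sd = 0.1, seed = 3)
  rk <- rank_barrels(fps, n_trees = 200, n_permutations = 20, seed = 10)
  expect_s3_class(rk, "bs_ranking")
  # every method puts F1 (largest spread) on top -> combined order agrees
  expect_equal(rk$feature[1], "F1")
  expect_equal(top_features(rk, 2), rk$feature[1:2])
  expect_error(top_features(rk, 99))
})
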