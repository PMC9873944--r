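test_that("stratified folds are disjoint, covering, and class-balanced", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      n_class <- sample(2:4, 1)
      sizes <- sample(4:12, n_class, replace = TRUE)
      labels <- rep(paste0("c", seq_len(n_class)), sizes)
      k <- sample(2:4, 1)
      folds <- stratified_folds(labels, k)
      k_eff <- attr(folds, "k")
      expect_setequal(unique(folds), seq_len(k_eff))
      tab <- table(labels, folds)
      # per-fold class counts deviate from proportionality by at most 1
      expect_true(all(apply(tab, 1, function(r) max(r) - min(r)) <= 1))
    }
  })
})

test_that("minimal balanced case puts one sample of each class in each fold", {
  folds <- stratified_folds(c("a", "a", "b", "b"), k = 2, seed = 1)
  expect_equal(as.vector(table(c("a", "a", "b", "b"), folds)), c(1, 1, 1, 1))
})

test_that("fold assignment is seed-deterministic and k is reduced for tiny classes", {
  labels <- rep(c("a", "b", "c"), c(6, 6, 6))
  expect_identical(stratified_folds(labels, 3, seed = 42),
                   stratified_folds(labels, 3, seed = 42))
  expect_false(identical(stratified_folds(labels, 3, seed = 1),
                         stratified_folds(labels, 3, seed = 2)))
  expect_error(stratified_folds(labels, 1), "at least 2")
  expect_warning(f <- stratified_folds(c("a", rep("b", 9)), 5), "reducing k")
  expect_identical(attr(f, "k"), 2L)
})

test_that("metrics match hand-computed values", {
  # perfect prediction
  m <- compute_metrics(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(c(m$accuracy, m$precision, m$f1), c(100, 100, 100))

  # all one class on a balanced 3-class set
  m2 <- compute_metrics(rep(c("a", "b", "c"), each = 2), rep("a", 6))
  expect_equal(m2$accuracy, 100 / 3)

  # binary confusion with TP=3 FP=1 FN=1 TN=5 (positive class "pos")
  true <- c(rep("pos", 4), rep("neg", 6))
  pred <- c("pos", "pos", "pos", "neg", "pos", rep("neg", 5))
  m3 <- compute_metrics(true, pred)
  cm <- m3$confusion
  expect_equal(cm["pos", "pos"], 3)
  expect_equal(cm["neg", "pos"], 1)
  expect_equal(cm["pos", "neg"], 1)
  expect_equal(cm["neg", "neg"], 5)
  # positive-class precision and F1 are 75%
  expect_equal(100 * cm["pos", "pos"] / sum(cm[, "pos"]), 75)
  prec_pos <- 3 / 4; rec_pos <- 3 / 4
  expect_equal(100 * 2 * prec_pos * rec_pos / (prec_pos + rec_pos), 75)
  # macro values averaged by hand over both classes
  expect_equal(m3$accuracy, 80)
  expect_equal(m3$precision, 100 * mean(c(5 / 6, 3 / 4)))
  f1_neg <- 2 * (5 / 6) * (5 / 6) / ((5 / 6) + (5 / 6))
  expect_equal(m3$f1, 100 * mean(c(f1_neg, 0.75)))

  expect_error(compute_metrics(character(0), character(0)), "Empty")
  expect_error(compute_metrics(c("a"), c("a", "b")), "equal length")
})

test_that("nested CV separates well-separated classes and is reproducible", {
  shifts <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0.5, 0.5), nrow = 2)
  fps <- make_fps(n_per_class = 8, shifts = shifts, noise_sd = 0.05, seed = 3)
  for (alg in c("gaussian_naive_bayes", "k_nearest_neighbours",
                "linear_discriminant_analysis", "svc_rbf")) {
    cv <- nested_cv(fps, classifier_spec(alg), seed = 11)
    expect_gte(glance(cv)$accuracy, 90)
  }
  # boosted stumps on an easy axis-aligned 2-class problem
  fps2 <- make_fps(n_per_class = 8, shifts = matrix(c(0, 0, 1, 1), nrow = 2),
                   noise_sd = 0.05, seed = 5)
  expect_gte(glance(nested_cv(fps2, classifier_spec("adaboost"),
                              seed = 11))$accuracy, 90)
  cv1 <- nested_cv(fps, classifier_spec("svc_linear"), seed = 11)
  cv2 <- nested_cv(fps, classifier_spec("svc_linear"), seed = 11)
  expect_identical(cv1$predictions, cv2$predictions)
})

test_that("pooled-confusion accuracy equals the sample-weighted fold mean", {
  shifts <- matrix(c(0, 0.3, 0.6, 0.2, 0.9, 0.1), nrow = 2)
  fps <- make_fps(n_per_class = 7, shifts = shifts, noise_sd = 0.25, seed = 4)
  cv <- nested_cv(fps, classifier_spec("gaussian_naive_bayes"), seed = 2)
  pooled_acc <- 100 * sum(diag(cv$confusion)) / sum(cv$confusion)
  fm <- tidy(cv)
  expect_equal(pooled_acc, sum(fm$accuracy * fm$n) / sum(fm$n))
  # confusion row sums equal per-class test counts
  expect_equal(as.vector(rowSums(cv$confusion)),
               as.vector(table(cv$predictions$true)))
})

test_that("dummy baselines sit at chance and constant features beat nobody", {
  shifts <- matrix(c(0, 1, 0.5, 0.5), nrow = 2) # 2 classes
  fps <- make_fps(n_per_class = 10, shifts = shifts, noise_sd = 0.05, seed = 6)
  accs <- vapply(1:10, function(s)
    glance(nested_cv(fps, classifier_spec("dummy_uniform"), seed = s))$accuracy,
    numeric(1))
  expect_lt(abs(mean(accs) - 50), 10)

  # constant features: no classifier can beat chance systematically
  flat <- fps
  flat$F1 <- 0.5
  flat$F2 <- 0.5
  for (alg in c("k_nearest_neighbours", "svc_linear")) {
    accs_flat <- vapply(1:10, function(s)
      glance(nested_cv(flat, classifier_spec(alg), seed = s))$accuracy,
      numeric(1))
    expect_lt(mean(accs_flat), 65)
  }
})

test_that("hyperparameter selection never touches the outer test fold", {
  shifts <- matrix(c(0, 0.4, 0.8, 0.4, 0.2, 0.9), nrow = 2)
  fps <- make_fps(n_per_class = 8, shifts = shifts, noise_sd = 0.2, seed = 8)
  cv_ref <- nested_cv(fps, classifier_spec("svc_linear"), seed = 21)
  # corrupt the *feature values* of fold 1's test samples; those samples are
  # training data for the other folds (so those may change), but fold 1's own
  # inner loop never sees its test fold, so its hyperparameter choice must be
  # unchanged, as must fold membership (which depends only on labels)
  test_ids <- cv_ref$predictions$sample_id[cv_ref$predictions$fold == 1]
  corrupted <- fps
  corrupted[corrupted$sample_id %in% test_ids, c("F1", "F2")] <- 99
  cv_cor <- nested_cv(corrupted, classifier_spec("svc_linear"), seed = 21)
  expect_identical(cv_ref$chosen_params[[1]], cv_cor$chosen_params[[1]])
  expect_identical(cv_ref$predictions[c("sample_id", "fold")],
                   cv_cor$predictions[c("sample_id", "fold")])
})

test_that("group prediction votes by majority with the stated tie-break", {
  cv <- structure(list(predictions = tibble::tibble(
    sample_id = sprintf("s%d", 1:12),
    true = rep(c("A", "B"), each = 6),
    predicted = c("A", "A", "A", "A", "B", "B", # group g1: A 4, B 2
                  "A", "A", "A", "B", "B", "B"), # group g2: 3-3 tie
    fold = 1L
  )), class = "bs_cv")
  groups <- setNames(rep(c("g1", "g2"), each = 6), sprintf("s%d", 1:12))
  gp <- group_prediction(cv, groups)
  expect_equal(gp$predicted[gp$group == "g1"], "A")
  expect_false(gp$tie[gp$group == "g1"])
  # tie: A and B are globally equally frequent (7 vs 5 -> A more frequent)
  expect_equal(gp$predicted[gp$group == "g2"], "A")
  expect_true(gp$tie[gp$group == "g2"])

  expect_error(group_prediction(cv, groups[-1]), "Unmapped")
})

test_that("a separable simulation yields perfect group-level prediction", {
  shifts <- matrix(c(0, 0, 1, 1), nrow = 2)
  fps <- make_fps(n_per_class = 8, shifts = shifts, noise_sd = 0.03, seed = 9)
  cv <- nested_cv(fps, classifier_spec("linear_discriminant_analysis"), seed = 3)
  # two "brands" per class, four samples each
  groups <- setNames(paste0(rep(c("brandA1", "brandA2", "brandB1", "brandB2"),
                                each = 4)), fps$sample_id)
  gp <- group_prediction(cv, groups)
  expect_true(all(gp$correct))
})
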