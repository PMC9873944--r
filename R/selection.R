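#' Per-feature one-way ANOVA F scores (KBest)
#'
#' Scores each barrel by the one-way ANOVA F statistic of its normalized
#' values across classes: between-class mean square over within-class mean
#' square. Higher scores mark more class-discriminative barrels. A feature
#' with zero within-class variance but non-zero between-class variance
#' separates perfectly and receives `Inf` (ranked first); a fully constant
#' feature scores 0.
#'
#' @param fingerprints Fingerprint tibble with `class_label`.
#' @return A tibble: `feature`, `score` (F statistic), `rank` (1 = best,
#'   average ranks on ties).
#' @export
#' @examples
#' fps <- tibble::tibble(sample_id = as.character(1:6),
#'                       class_label = rep(c("a", "b"), each = 3),
#'                       good = c(0, 0.1, -0.1, 5, 5.1, 4.9),
#'                       noise = c(0.2, -0.3, 0.1, 0.0, 0.2, -0.1))
#' kbest_scores(fps)
kbest_scores <- function(fingerprints) {
  parts <- fingerprint_parts(fingerprints)
  if (is.null(parts$class_label)) abort("`fingerprints` must have class_label.")
  y <- factor(parts$class_label)
  if (nlevels(y) < 2) abort("KBest scoring needs at least 2 classes.")
  x <- parts$x
  n <- nrow(x)
  k <- nlevels(y)

  grand <- colMeans(x)
  ss_between <- numeric(ncol(x))
  ss_within <- numeric(ncol(x))
  for (lev in levels(y)) {
    rows <- y == lev
    m <- colMeans(x[rows, , drop = FALSE])
    ss_between <- ss_between + sum(rows) * (m - grand)^2
    ss_within <- ss_within +
      colSums(sweep(x[rows, , drop = FALSE], 2, m)^2)
  }
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  # 0/0 (fully constant feature) carries no signal; x/0 separates perfectly.
  f[ss_within == 0 & ss_between == 0] <- 0
  zero_within <- ss_within == 0 & ss_between > 0
  f[zero_within] <- Inf
  if (any(zero_within)) {
    warn(sprintf("Feature(s) with zero within-class variance scored Inf: %s",
                 paste(colnames(x)[zero_within], collapse = ", ")))
  }

  tibble::tibble(feature = colnames(x), score = unname(f),
                 rank = unname(rank_desc(f)))
}

#' Extremely-randomized-trees feature importance
#'
#' Impurity importance from a forest of extremely randomized trees (random
#' split points, no bootstrap), the tree-based leg of the three-method
#' importance analysis.
#'
#' @param fingerprints Fingerprint tibble with `class_label`.
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed.
#' @return A tibble: `feature`, `score`, `rank` (1 = best).
#' @export
tree_importance <- function(fingerprints, n_trees = 500, seed = NULL) {
  parts <- fingerprint_parts(fingerprints)
  if (is.null(parts$class_label)) abort("`fingerprints` must have class_label.")
  df <- data.frame(parts$x, check.names = FALSE)
  df$.y <- factor(parts$class_label)
  with_seed_if(seed, {
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = df,
      num.trees = n_trees, splitrule = "extratrees",
      replace = FALSE, sample.fraction = 1,
      importance = "impurity", num.threads = 1,
      seed = sample.int(.Machine$integer.max, 1)
    )
    imp <- fit$variable.importance[parts$features]
    tibble::tibble(feature = parts$features, score = unname(imp),
                   rank = rank_desc(unname(imp)))
  })
}

#' Permutation feature importance
#'
#' Fits the given classifier on a stratified training split and measures, for
#' each feature, the mean drop in held-out accuracy when that feature's
#' column is shuffled (`n_permutations` independent shuffles). Importances
#' can be negative for features whose noise happens to mislead the model.
#'
#' @param fingerprints Fingerprint tibble with `class_label`.
#' @param spec A [classifier_spec()]; fitted once with its first grid point.
#' @param n_permutations Shuffles per feature (default 50).
#' @param test_fraction Held-out fraction of the stratified split
#'   (default 1/3).
#' @param seed Integer seed.
#' @return A tibble: `feature`, `score` (mean accuracy drop, in percentage
#'   points), `rank` (1 = best).
#' @export
permutation_importance <- function(fingerprints, spec, n_permutations = 50,
                                   test_fraction = 1 / 3, seed = NULL) {
  stopifnot(inherits(spec, "bs_classifier_spec"))
  if (n_permutations < 1) abort("`n_permutations` must be at least 1.")
  parts <- fingerprint_parts(fingerprints)
  if (is.null(parts$class_label)) abort("`fingerprints` must have class_label.")
  x <- parts$x
  y <- factor(parts$class_label)

  with_seed_if(seed, {
    k_split <- max(2L, round(1 / test_fraction))
    folds <- stratified_folds(y, k_split, seed = NULL)
    test_idx <- which(folds == 1L)
    train_idx <- which(folds != 1L)

    model <- fit_classifier(spec$algorithm, x[train_idx, , drop = FALSE],
                            droplevels(y[train_idx]), grid_points(spec$grid)[[1]])
    x_test <- x[test_idx, , drop = FALSE]
    y_test <- as.character(y[test_idx])
    base_acc <- mean(predict_classifier(model, x_test) == y_test)

    score <- vapply(parts$features, function(f) {
      drops <- vapply(seq_len(n_permutations), function(p) {
        xp <- x_test
        xp[, f] <- xp[sample.int(nrow(xp)), f]
        base_acc - mean(predict_classifier(model, xp) == y_test)
      }, numeric(1))
      100 * mean(drops)
    }, numeric(1))

    tibble::tibble(feature = parts$features, score = unname(score),
                   rank = rank_desc(unname(score)))
  })
}

#' Combine three importance rankings by summed rank
#'
#' Sums each feature's ranks from the ANOVA-F, tree-importance and
#' permutation analyses into one overall ranking (lower combined rank =
#' more important). Ordering ties are broken by the ANOVA-F rank, then by
#' feature identifier; the combined rank value itself is the plain sum.
#'
#' @param kbest,tree,permutation Ranking tibbles (`feature`, `score`,
#'   `rank`) from [kbest_scores()], [tree_importance()] and
#'   [permutation_importance()]. All three must cover the same feature set.
#' @return An object of class `bs_ranking`: a tibble with per-method scores
#'   and ranks, `combined_rank`, and the final `order` (1 = most important).
#' @export
combined_rank <- function(kbest, tree, permutation) {
  for (r in list(kbest, tree, permutation)) {
    if (!all(c("feature", "score", "rank") %in% names(r))) {
      abort("Each ranking needs feature, score and rank columns.")
    }
  }
  feats <- sort(kbest$feature)
  if (!identical(sort(tree$feature), feats) ||
      !identical(sort(permutation$feature), feats)) {
    abort("The three rankings must cover the same feature set.")
  }
  out <- kbest |>
    dplyr::rename(kbest_score = "score", kbest_rank = "rank") |>
    dplyr::left_join(dplyr::rename(tree, tree_score = "score",
                                   tree_rank = "rank"),
                     by = "feature") |>
    dplyr::left_join(dplyr::rename(permutation, perm_score = "score",
                                   perm_rank = "rank"),
                     by = "feature") |>
    dplyr::mutate(combined_rank = .data$kbest_rank + .data$tree_rank +
                    .data$perm_rank) |>
    dplyr::arrange(.data$combined_rank, .data$kbest_rank, .data$feature) |>
    dplyr::mutate(order = dplyr::row_number())
  class(out) <- c("bs_ranking", class(out))
  out
}

#' Top-k features of a combined ranking
#'
#' @param ranking A [combined_rank()] result.
#' @param k Number of features.
#' @return Character vector of the k most important feature ids.
#' @export
top_features <- function(ranking, k) {
  stopifnot(inherits(ranking, "bs_ranking"), k >= 1, k <= nrow(ranking))
  ranking$feature[seq_len(k)]
}

#' Rank a panel's barrels by all three importance methods
#'
#' Convenience wrapper running [kbest_scores()], [tree_importance()] and
#' [permutation_importance()] and aggregating them with [combined_rank()].
#'
#' @inheritParams permutation_importance
#' @param n_trees Trees for the forest leg.
#' @return A `bs_ranking` tibble.
#' @export
rank_barrels <- function(fingerprints,
                         spec = classifier_spec("linear_discriminant_analysis"),
                         n_trees = 500, n_permutations = 50, seed = NULL) {
  with_seed_if(seed, {
    kb <- kbest_scores(fingerprints)
    tr <- tree_importance(fingerprints, n_trees = n_trees, seed = NULL)
    pm <- permutation_importance(fingerprints, spec,
                                 n_permutations = n_permutations, seed = NULL)
    combined_rank(kb, tr, pm)
  })
}
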