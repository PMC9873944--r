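#' Stratified fold assignment
#'
#' Partitions samples into `k` folds preserving class proportions: within
#' each class the (shuffled) members are dealt out round-robin, with the
#' starting fold rotated between classes so overall fold sizes stay balanced.
#' Per-fold class counts differ from exact proportionality by at most one.
#' If some class has fewer than `k` members, `k` is reduced to the smallest
#' class size with a warning (a fold must never lose a class entirely).
#'
#' @param labels Vector of class labels.
#' @param k Number of folds (at least 2).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Integer vector of fold ids (1..k), one per sample, with the
#'   effective `k` as attribute `"k"`.
#' @export
#' @examples
#' table(stratified_folds(rep(c("a", "b"), each = 6), k = 3, seed = 1),
#'       rep(c("a", "b"), each = 6))
stratified_folds <- function(labels, k, seed = NULL) {
  if (k < 2) abort("`k` must be at least 2.")
  labels <- as.character(labels)
  min_class <- min(table(labels))
  if (min_class < k) {
    warn(sprintf("Smallest class has %d member(s); reducing k from %d to %d.",
                 min_class, k, max(2L, min_class)))
    k <- max(2L, min_class)
  }
  k <- as.integer(k)
  with_seed_if(seed, {
    folds <- integer(length(labels))
    start <- 0L
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
      start <- start + length(idx)
    }
    structure(folds, k = k)
  })
}

#' Classification metrics from true and predicted labels
#'
#' Accuracy, macro-averaged precision and macro-averaged F1 (all in percent)
#' plus the confusion matrix (rows = true classes, columns = predicted).
#' Per-class precision with no predictions for that class, and per-class F1
#' with zero precision + recall, are counted as 0 before macro-averaging.
#'
#' @param true,predicted Equal-length label vectors.
#' @return A list: `accuracy`, `precision`, `f1` (percent), and `confusion`
#'   (a table).
#' @export
#' @examples
#' compute_metrics(c("a", "a", "b"), c("a", "b", "b"))$accuracy
compute_metrics <- function(true, predicted) {
  if (length(true) == 0) abort("Empty label vectors.")
  if (length(true) != length(predicted)) {
    abort("`true` and `predicted` must have equal length.")
  }
  lev <- sort(unique(c(as.character(true), as.character(predicted))))
  true <- factor(as.character(true), levels = lev)
  predicted <- factor(as.character(predicted), levels = lev)
  confusion <- table(true = true, predicted = predicted)

  tp <- diag(confusion)
  pred_n <- colSums(confusion)
  true_n <- rowSums(confusion)
  present <- true_n > 0 # macro-average over classes that actually occur
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(true_n > 0, tp / true_n, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)

  list(
    accuracy = 100 * sum(tp) / length(true),
    precision = 100 * mean(precision[present]),
    f1 = 100 * mean(f1[present]),
    confusion = confusion
  )
}

#' Nested stratified cross-validation of one classifier
#'
#' Estimates out-of-sample performance with an outer stratified k-fold loop;
#' inside each outer training set, an inner stratified k-fold loop picks the
#' hyperparameter combination with the best inner CV accuracy (ties go to
#' the first grid point). The outer test fold is touched exactly once, by
#' the final per-fold model — feature subsetting (via `features`) and
#' hyperparameter selection never see it. Dummy baselines bypass the inner
#' loop. Metrics are macro-averaged percentages reported as mean and
#' standard deviation across outer folds, alongside the pooled confusion
#' matrix.
#'
#' @param fingerprints Fingerprint tibble with `sample_id`, `class_label`
#'   and numeric feature columns.
#' @param spec A [classifier_spec()].
#' @param k_outer,k_inner Outer and inner fold counts (defaults 5 and 3).
#' @param seed Integer seed governing fold assignment and any stochastic
#'   classifier.
#' @param features Optional character vector restricting the feature columns
#'   used (e.g. a reduced sensor panel).
#' @param scale If `TRUE`, z-score each feature using training-fold
#'   statistics (off by default: normalized fingerprints are already on a
#'   common scale).
#' @return An object of class `bs_cv`: `predictions` (tibble `sample_id`,
#'   `true`, `predicted`, `fold`), `fold_metrics`, `metrics` (mean and sd of
#'   accuracy/precision/F1 across folds), `confusion` (pooled),
#'   `chosen_params`, `skipped_folds`, `spec`, `seed`. [generics::tidy()]
#'   gives per-fold metrics, [generics::glance()] the aggregate row.
#' @export
#' @examples
#' panel <- sim_panel(n_barrels = 8, n_classes = 2, n_informative = 4,
#'                    fold_change = 6, seed = 1)
#' sim <- simulate_raw_plates(panel, sim_config(n_samples_per_class = 8,
#'                                              n_technical_reps = 2, seed = 1))
#' fps <- preprocess_plates(sim$readings)
#' cv <- nested_cv(fps, classifier_spec("linear_discriminant_analysis"), seed = 1)
#' glance(cv)
nested_cv <- function(fingerprints, spec, k_outer = 5, k_inner = 3,
                      seed = NULL, features = NULL, scale = FALSE) {
  stopifnot(inherits(spec, "bs_classifier_spec"))
  parts <- fingerprint_parts(fingerprints)
  if (is.null(parts$class_label)) {
    abort("`fingerprints` must have a class_label column for classification.")
  }
  if (length(unique(parts$class_label)) < 2) {
    abort("Classification needs at least 2 classes.")
  }
  x <- parts$x
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(x))
    if (length(missing) > 0) {
      abort(sprintf("Unknown feature(s): %s.", paste(missing, collapse = ", ")))
    }
    x <- x[, features, drop = FALSE]
  }
  y <- factor(parts$class_label)

  with_seed_if(seed, {
    folds <- stratified_folds(y, k_outer, seed = NULL)
    k_outer <- attr(folds, "k")

    predictions <- list()
    fold_metrics <- list()
    chosen <- list()
    skipped <- integer(0)

    for (j in seq_len(k_outer)) {
      test_idx <- which(folds == j)
      train_idx <- which(folds != j)
      y_train <- droplevels(y[train_idx])
      if (nlevels(y_train) < 2) {
        skipped <- c(skipped, j)
        next
      }
      x_train <- x[train_idx, , drop = FALSE]
      x_test <- x[test_idx, , drop = FALSE]
      if (scale) {
        mu <- colMeans(x_train)
        sdev <- apply(x_train, 2, sd)
        sdev[sdev == 0] <- 1
        x_train <- sweep(sweep(x_train, 2, mu), 2, sdev, "/")
        x_test <- sweep(sweep(x_test, 2, mu), 2, sdev, "/")
      }

      points <- grid_points(spec$grid)
      best <- points[[1]]
      if (!spec$is_dummy && length(points) > 1) {
        inner_folds <- stratified_folds(y_train, k_inner, seed = NULL)
        k_in <- attr(inner_folds, "k")
        inner_acc <- vapply(points, function(params) {
          correct <- 0L
          total <- 0L
          for (i in seq_len(k_in)) {
            it <- which(inner_folds != i)
            iv <- which(inner_folds == i)
            y_it <- droplevels(y_train[it])
            if (nlevels(y_it) < 2) next
            m <- fit_classifier(spec$algorithm, x_train[it, , drop = FALSE],
                                y_it, params)
            p <- predict_classifier(m, x_train[iv, , drop = FALSE])
            correct <- correct + sum(p == as.character(y_train[iv]))
            total <- total + length(iv)
          }
          if (total == 0) return(NA_real_)
          correct / total
        }, numeric(1))
        if (!all(is.na(inner_acc))) {
          best <- points[[which.max(inner_acc)]]
        }
      }

      model <- fit_classifier(spec$algorithm, x_train, y_train, best)
      pred <- predict_classifier(model, x_test)

      predictions[[j]] <- tibble::tibble(
        sample_id = parts$sample_id[test_idx],
        true = as.character(y[test_idx]),
        predicted = pred,
        fold = j
      )
      m <- compute_metrics(as.character(y[test_idx]), pred)
      fold_metrics[[j]] <- tibble::tibble(
        fold = j, n = length(test_idx),
        accuracy = m$accuracy, precision = m$precision, f1 = m$f1
      )
      chosen[[j]] <- best
    }

    if (length(predictions) == 0) {
      abort("Every outer fold was degenerate; cannot cross-validate.")
    }
    predictions <- dplyr::bind_rows(predictions)
    fold_metrics <- dplyr::bind_rows(fold_metrics)
    pooled <- compute_metrics(predictions$true, predictions$predicted)

    structure(
      list(
        predictions = predictions,
        fold_metrics = fold_metrics,
        metrics = tibble::tibble(
          metric = c("accuracy", "precision", "f1"),
          mean = c(mean(fold_metrics$accuracy), mean(fold_metrics$precision),
                   mean(fold_metrics$f1)),
          sd = c(sd(fold_metrics$accuracy), sd(fold_metrics$precision),
                 sd(fold_metrics$f1))
        ),
        confusion = pooled$confusion,
        chosen_params = chosen,
        skipped_folds = skipped,
        features = colnames(x),
        spec = spec,
        k_outer = k_outer,
        k_inner = k_inner,
        seed = seed
      ),
      class = "bs_cv"
    )
  })
}

#' @export
print.bs_cv <- function(x, ...) {
  acc <- x$metrics[x$metrics$metric == "accuracy", ]
  cat(sprintf(
    "<bs_cv> %s, %d-fold outer / %d-fold inner nested CV on %d samples, %d features\n",
    x$spec$algorithm, x$k_outer, x$k_inner, nrow(x$predictions),
    length(x$features)
  ))
  cat(sprintf("  accuracy %.1f +/- %.1f %%\n", acc$mean, acc$sd))
  invisible(x)
}

#' Majority-vote predictions for sample groups
#'
#' Aggregates a cross-validation result's per-sample predictions to a
#' higher-level unit (e.g. a brand measured as several independent samples)
#' by majority vote. Vote ties are broken by the class with the highest mean
#' predicted-class frequency across all groups, then lexicographically; the
#' tie and its resolution are recorded.
#'
#' @param cv A [nested_cv()] result.
#' @param groups Named character vector or two-column data frame mapping
#'   `sample_id` to a group id; every predicted sample must be mapped.
#' @return A tibble: `group`, `predicted`, `n_votes`, `n_samples`, `tie`,
#'   plus `true` and `correct` when the group's samples share one true
#'   class.
#' @export
group_prediction <- function(cv, groups) {
  stopifnot(inherits(cv, "bs_cv"))
  if (is.data.frame(groups)) {
    if (!all(c("sample_id", "group") %in% names(groups))) {
      abort("`groups` data frame needs sample_id and group columns.")
    }
    map <- setNames(as.character(groups$group), groups$sample_id)
  } else {
    map <- groups
  }
  preds <- cv$predictions
  unmapped <- setdiff(preds$sample_id, names(map))
  if (length(unmapped) > 0) {
    abort(sprintf("Unmapped sample(s): %s.", paste(head(unmapped, 5), collapse = ", ")))
  }
  preds$group <- unname(map[preds$sample_id])

  # Global predicted-class frequencies, the first tie-break criterion.
  global_freq <- table(preds$predicted) / nrow(preds)

  preds |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(df, key) {
      votes <- sort(table(df$predicted), decreasing = TRUE)
      top <- names(votes)[votes == max(votes)]
      tie <- length(top) > 1
      if (tie) {
        freq <- global_freq[top]
        freq[is.na(freq)] <- 0
        top <- top[order(-freq, top)]
      }
      winner <- top[1]
      truth <- unique(df$true)
      tibble::tibble(
        predicted = winner,
        n_votes = as.integer(max(votes)),
        n_samples = nrow(df),
        tie = tie,
        true = if (length(truth) == 1) truth else NA_character_,
        correct = if (length(truth) == 1) winner == truth else NA
      )
    }) |>
    dplyr::ungroup()
}
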