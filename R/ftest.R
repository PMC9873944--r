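#' 5x2 cross-validation combined F-test between two classifiers
#'
#' Compares two classifier specifications on the same fingerprints with the
#' combined 5x2 CV F-test: five independent stratified 2-fold splits; on
#' repetition `i`, fold `j`, the error-rate difference is
#' `p_i^(j) = err_A - err_B` (train on the other fold, test on fold `j`);
#' with per-repetition mean `p_bar_i` and variance
#' `s_i^2 = (p_i^(1) - p_bar_i)^2 + (p_i^(2) - p_bar_i)^2`, the statistic
#' \deqn{f = \frac{\sum_{i,j} (p_i^{(j)})^2}{2 \sum_i s_i^2}}
#' follows approximately F(10, 5) under the null of equal performance; the
#' p-value is the upper tail. Squared differences make the test two-sided
#' (direction-agnostic): swapping A and B negates the differences and leaves
#' `f` and the p-value unchanged.
#'
#' If every repetition has zero variance — e.g. the two classifiers make
#' identical predictions everywhere — the statistic is undefined; the result
#' is flagged degenerate and reported with `p_value = 1` (identical
#' behaviour cannot be evidence of a difference).
#'
#' The 2-fold splits are stratified: with the small per-class counts typical
#' of sensor campaigns, unstratified halves can lose a class entirely.
#'
#' @param fingerprints Fingerprint tibble with `class_label`.
#' @param spec_a,spec_b [classifier_spec()] objects to compare.
#' @param seed Integer seed for the five splits (and stochastic
#'   classifiers).
#' @param features_a,features_b Optional feature subsets for each
#'   classifier, so a reduced panel can be compared against the full one.
#' @param n_repeats Number of 2-fold repetitions (default 5; the classical
#'   test).
#' @return An object of class `bs_ftest`: `f_statistic`, `df` (10, 5),
#'   `p_value`, `differences` (tibble `repetition`, `fold`, `diff`),
#'   `degenerate`.
#' @references Alpaydin, E. (1999) Combined 5x2 cv F test for comparing
#'   supervised classification learning algorithms. *Neural Computation*
#'   11, 1885-1892.
#' @export
#' @examples
#' panel <- sim_panel(n_barrels = 8, n_classes = 2, n_informative = 4,
#'                    fold_change = 6, seed = 1)
#' sim <- simulate_raw_plates(panel, sim_config(n_samples_per_class = 8,
#'                                              n_technical_reps = 2, seed = 1))
#' fps <- preprocess_plates(sim$readings)
#' ftest_5x2cv(fps, classifier_spec("linear_discriminant_analysis"),
#'             classifier_spec("dummy_uniform"), seed = 1)
ftest_5x2cv <- function(fingerprints, spec_a, spec_b, seed = NULL,
                        features_a = NULL, features_b = NULL,
                        n_repeats = 5) {
  stopifnot(inherits(spec_a, "bs_classifier_spec"),
            inherits(spec_b, "bs_classifier_spec"))
  parts <- fingerprint_parts(fingerprints)
  if (is.null(parts$class_label)) abort("`fingerprints` must have class_label.")
  y <- factor(parts$class_label)
  pick <- function(feats) {
    if (is.null(feats)) return(parts$x)
    missing <- setdiff(feats, colnames(parts$x))
    if (length(missing) > 0) {
      abort(sprintf("Unknown feature(s): %s.", paste(missing, collapse = ", ")))
    }
    parts$x[, feats, drop = FALSE]
  }
  xa <- pick(features_a)
  xb <- pick(features_b)

  error_rate <- function(spec, x, train, test) {
    model <- fit_classifier(spec$algorithm, x[train, , drop = FALSE],
                            droplevels(y[train]), grid_points(spec$grid)[[1]])
    mean(predict_classifier(model, x[test, , drop = FALSE]) !=
           as.character(y[test]))
  }

  with_seed_if(seed, {
    diffs <- purrr::map_dfr(seq_len(n_repeats), function(i) {
      halves <- stratified_folds(y, 2, seed = NULL)
      f1 <- which(halves == 1L)
      f2 <- which(halves == 2L)
      tibble::tibble(
        repetition = i,
        fold = c(1L, 2L),
        diff = c(
          error_rate(spec_a, xa, f2, f1) - error_rate(spec_b, xb, f2, f1),
          error_rate(spec_a, xa, f1, f2) - error_rate(spec_b, xb, f1, f2)
        )
      )
    })

    out <- ftest_from_differences(diffs)
    out$spec_a <- spec_a$algorithm
    out$spec_b <- spec_b$algorithm
    out
  })
}

#' Combined 5x2 CV F statistic from fold error differences
#'
#' Computes the combined F statistic, degrees of freedom and upper-tail
#' p-value from the per-repetition fold error differences directly, so a
#' comparison can be audited or reconstructed without refitting. Used
#' internally by [ftest_5x2cv()].
#'
#' @param differences A tibble with columns `repetition`, `fold`, `diff`
#'   (two folds per repetition), or a numeric matrix with one row per
#'   repetition and two columns.
#' @return A `bs_ftest` object (without classifier names).
#' @export
#' @examples
#' d <- matrix(c(0.1, -0.1), nrow = 5, ncol = 2, byrow = TRUE)
#' ftest_from_differences(d)$f_statistic # 0.5 for any +d/-d pattern
ftest_from_differences <- function(differences) {
  if (is.matrix(differences)) {
    differences <- tibble::tibble(
      repetition = rep(seq_len(nrow(differences)), each = 2L),
      fold = rep(c(1L, 2L), nrow(differences)),
      diff = as.numeric(t(differences))
    )
  }
  stopifnot(all(c("repetition", "fold", "diff") %in% names(differences)))
  n_repeats <- length(unique(differences$repetition))
  if (nrow(differences) != 2L * n_repeats) {
    abort("Each repetition must contribute exactly two fold differences.")
  }

  s2 <- differences |>
    dplyr::group_by(.data$repetition) |>
    dplyr::summarise(s2 = sum((.data$diff - mean(.data$diff))^2),
                     .groups = "drop")
  denom <- 2 * sum(s2$s2)
  degenerate <- denom == 0
  if (degenerate) {
    f <- NA_real_
    p <- 1
  } else {
    f <- sum(differences$diff^2) / denom
    p <- pf(f, df1 = 2 * n_repeats, df2 = n_repeats, lower.tail = FALSE)
  }

  structure(
    list(f_statistic = f, df = c(2L * n_repeats, n_repeats), p_value = p,
         differences = differences, degenerate = degenerate,
         spec_a = NA_character_, spec_b = NA_character_),
    class = "bs_ftest"
  )
}

#' @export
print.bs_ftest <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<bs_ftest> %s vs %s: degenerate (identical behaviour), p = 1\n",
                x$spec_a, x$spec_b))
  } else {
    cat(sprintf("<bs_ftest> %s vs %s: F(%d, %d) = %.3f, p = %.4g\n",
                x$spec_a, x$spec_b, x$df[1], x$df[2], x$f_statistic, x$p_value))
  }
  invisible(x)
}

#' Retrain on a reduced panel and compare it with the full array
#'
#' Re-estimates performance with [nested_cv()] using only the top `k`
#' features of a combined ranking, alongside the full-panel result, and
#' tests the two panels against each other with [ftest_5x2cv()]. With
#' `k = n_features` the comparison is the array against itself, which is
#' degenerate by construction (p = 1).
#'
#' @param fingerprints Fingerprint tibble with `class_label`.
#' @param ranking A [combined_rank()] result (or any tibble with `feature`
#'   ordered by importance).
#' @param k Number of top features to retain.
#' @param spec A [classifier_spec()] used for both panels.
#' @param seed Integer seed.
#' @param k_outer,k_inner Passed to [nested_cv()].
#' @return A list of class `bs_reduction`: `full_cv`, `reduced_cv`,
#'   `ftest`, `features` (the retained subset).
#' @export
reduce_and_compare <- function(fingerprints, ranking, k, spec, seed = NULL,
                               k_outer = 5, k_inner = 3) {
  parts <- fingerprint_parts(fingerprints)
  if (k < 1 || k > length(parts$features)) {
    abort(sprintf("`k` must be between 1 and %d.", length(parts$features)))
  }
  feats <- if (inherits(ranking, "bs_ranking")) {
    top_features(ranking, k)
  } else {
    head(ranking$feature, k)
  }
  with_seed_if(seed, {
    full_cv <- nested_cv(fingerprints, spec, k_outer = k_outer,
                         k_inner = k_inner, seed = NULL)
    reduced_cv <- nested_cv(fingerprints, spec, k_outer = k_outer,
                            k_inner = k_inner, seed = NULL, features = feats)
    ft <- ftest_5x2cv(fingerprints, spec, spec, seed = NULL,
                      features_a = feats, features_b = NULL)
    structure(
      list(full_cv = full_cv, reduced_cv = reduced_cv, ftest = ft,
           features = feats),
      class = "bs_reduction"
    )
  })
}

#' @export
print.bs_reduction <- function(x, ...) {
  full <- x$full_cv$metrics
  red <- x$reduced_cv$metrics
  cat(sprintf(
    "<bs_reduction> %d-feature panel: accuracy %.1f%% vs full %.1f%% (p = %.3g)\n",
    length(x$features),
    red$mean[red$metric == "accuracy"],
    full$mean[full$metric == "accuracy"],
    x$ftest$p_value
  ))
  invisible(x)
}
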