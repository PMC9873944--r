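#' Classifier specification for the cross-validation harness
#'
#' Describes one of the harness's pluggable algorithms together with its
#' hyperparameter grid. The six spot-check algorithms are Gaussian naive
#' Bayes, k-nearest neighbours, linear discriminant analysis, AdaBoost
#' (SAMME over decision stumps), and linear / RBF support vector
#' classification; two dummy baselines assign random labels (uniform over
#' classes, or drawn from the training class priors) and take no grid.
#'
#' Default grids are deliberately small — the harness spot-checks algorithms
#' rather than tuning them heavily: kNN neighbours in \{1, 3, 5\}, SVC cost
#' in \{0.1, 1, 10\}, AdaBoost rounds in \{25, 50\}.
#'
#' @param algorithm One of `"gaussian_naive_bayes"`,
#'   `"k_nearest_neighbours"`, `"linear_discriminant_analysis"`,
#'   `"adaboost"`, `"svc_linear"`, `"svc_rbf"`, `"dummy_uniform"`,
#'   `"dummy_stratified"`.
#' @param grid Optional named list of hyperparameter vectors overriding the
#'   default grid. Must be empty for the dummy baselines.
#' @return A list of class `bs_classifier_spec`.
#' @export
#' @examples
#' classifier_spec("svc_rbf")
#' classifier_spec("k_nearest_neighbours", grid = list(k = c(1, 7)))
classifier_spec <- function(algorithm = c("gaussian_naive_bayes",
                                          "k_nearest_neighbours",
                                          "linear_discriminant_analysis",
                                          "adaboost",
                                          "svc_linear",
                                          "svc_rbf",
                                          "dummy_uniform",
                                          "dummy_stratified"),
                            grid = NULL) {
  algorithm <- match.arg(algorithm)
  defaults <- list(
    gaussian_naive_bayes = list(),
    k_nearest_neighbours = list(k = c(1, 3, 5)),
    linear_discriminant_analysis = list(),
    adaboost = list(n_rounds = c(25, 50)),
    svc_linear = list(cost = c(0.1, 1, 10)),
    svc_rbf = list(cost = c(0.1, 1, 10)),
    dummy_uniform = list(),
    dummy_stratified = list()
  )
  is_dummy <- algorithm %in% c("dummy_uniform", "dummy_stratified")
  if (is_dummy && !is.null(grid) && length(grid) > 0) {
    abort("Dummy classifiers take no hyperparameter grid.")
  }
  grid <- grid %||% defaults[[algorithm]]
  structure(
    list(algorithm = algorithm, grid = grid, is_dummy = is_dummy),
    class = "bs_classifier_spec"
  )
}

#' @export
print.bs_classifier_spec <- function(x, ...) {
  cat(sprintf("<bs_classifier_spec> %s\n", x$algorithm))
  if (length(x$grid) > 0) {
    for (nm in names(x$grid)) {
      cat(sprintf("  %s: %s\n", nm, paste(x$grid[[nm]], collapse = ", ")))
    }
  }
  invisible(x)
}

# All grid combinations as a list of named parameter lists.
grid_points <- function(grid) {
  if (length(grid) == 0) return(list(list()))
  df <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

# Fit `algorithm` on (x, y) with hyperparameters `params`; returns an object
# that `predict_classifier()` understands. y is a factor.
fit_classifier <- function(algorithm, x, y, params = list()) {
  y <- droplevels(y)
  switch(
    algorithm,
    gaussian_naive_bayes = list(kind = "nb",
                                fit = e1071::naiveBayes(x, y)),
    k_nearest_neighbours = list(kind = "knn", x = x, y = y,
                                k = params$k %||% 3),
    linear_discriminant_analysis = list(kind = "lda",
                                        fit = MASS::lda(x, grouping = y)),
    adaboost = list(kind = "ada",
                    fit = fit_adaboost(x, y, n_rounds = params$n_rounds %||% 50)),
    svc_linear = list(kind = "svm",
                      fit = e1071::svm(x, y, kernel = "linear",
                                       cost = params$cost %||% 1, scale = FALSE)),
    svc_rbf = list(kind = "svm",
                   fit = e1071::svm(x, y, kernel = "radial",
                                    cost = params$cost %||% 1, scale = FALSE)),
    dummy_uniform = list(kind = "dummy_uniform", levels = levels(y)),
    dummy_stratified = list(kind = "dummy_stratified", levels = levels(y),
                            priors = as.numeric(table(y)) / length(y)),
    abort(sprintf("Unknown algorithm '%s'.", algorithm))
  )
}

predict_classifier <- function(model, x) {
  n <- nrow(x)
  out <- switch(
    model$kind,
    nb = predict(model$fit, x),
    knn = class::knn(model$x, x, model$y, k = model$k),
    lda = predict(model$fit, x)$class,
    ada = predict_adaboost(model$fit, x),
    svm = predict(model$fit, x),
    dummy_uniform = factor(sample(model$levels, n, replace = TRUE),
                           levels = model$levels),
    dummy_stratified = factor(sample(model$levels, n, replace = TRUE,
                                     prob = model$priors),
                              levels = model$levels),
    abort("Unknown model kind.")
  )
  as.character(out)
}

# SAMME multiclass AdaBoost over depth-1 rpart stumps. Weighted error below
# machine tolerance gets floored so the round weight stays finite; a round
# no better than chance for K classes ends boosting (standard SAMME rule).
fit_adaboost <- function(x, y, n_rounds = 50) {
  y <- droplevels(y)
  k <- nlevels(y)
  n <- length(y)
  w <- rep(1 / n, n)
  df <- data.frame(x, .y = y, check.names = FALSE)
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w,
                        method = "class",
                        control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                       minsplit = 2, xval = 0))
    pred <- predict(fit, df, type = "class")
    miss <- pred != y
    err <- sum(w[miss])
    if (err >= 1 - 1 / k) {
      if (m == 1L) { # even the first stump is no better than chance
        stumps <- list(fit); alphas <- 1
      }
      break
    }
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(k - 1)
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    if (err <= 1e-10) break # perfect stump: nothing left to reweight
  }
  list(stumps = stumps, alphas = alphas, levels = levels(y))
}

predict_adaboost <- function(model, x) {
  df <- as.data.frame(x)
  votes <- matrix(0, nrow(df), length(model$levels),
                  dimnames = list(NULL, model$levels))
  for (m in seq_along(model$stumps)) {
    pred <- as.character(predict(model$stumps[[m]], df, type = "class"))
    votes[cbind(seq_len(nrow(df)), match(pred, model$levels))] <-
      votes[cbind(seq_len(nrow(df)), match(pred, model$levels))] + model$alphas[m]
  }
  factor(model$levels[max.col(votes, ties.method = "first")],
         levels = model$levels)
}
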