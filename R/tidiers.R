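#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cross-validation result
#'
#' One row per outer fold with its test-set size and metrics.
#' @param x A `bs_cv` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy bs_cv
#' @export
tidy.bs_cv <- function(x, ...) {
  x$fold_metrics
}

#' One-row summary of a cross-validation result
#'
#' Mean and standard deviation across outer folds of accuracy, precision and
#' macro F1 (percent), in the `metric +/- sd` layout of a performance table.
#' @param x A `bs_cv` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance bs_cv
#' @export
glance.bs_cv <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(
    algorithm = x$spec$algorithm,
    n = nrow(x$predictions),
    n_features = length(x$features),
    k_outer = x$k_outer,
    accuracy = m$mean[m$metric == "accuracy"],
    accuracy_sd = m$sd[m$metric == "accuracy"],
    precision = m$mean[m$metric == "precision"],
    precision_sd = m$sd[m$metric == "precision"],
    f1 = m$mean[m$metric == "f1"],
    f1_sd = m$sd[m$metric == "f1"]
  )
}

#' Tidy an outlier screen: the flagged readings
#' @param x A `bs_screen` object.
#' @param ... Unused.
#' @return A tibble of flags (`sample_id`, `barrel_id`, `group`, `value`).
#' @method tidy bs_screen
#' @export
tidy.bs_screen <- function(x, ...) {
  x$flags
}

#' One-row summary of an outlier screen
#' @param x A `bs_screen` object.
#' @param ... Unused.
#' @return A one-row tibble with counts and the screening parameters.
#' @method glance bs_screen
#' @export
glance.bs_screen <- function(x, ...) {
  tibble::tibble(
    n_input = x$n_input, n_retained = x$n_retained, n_dropped = x$n_dropped,
    n_flags = nrow(x$flags),
    alpha = x$config$alpha, drop_threshold = x$config$drop_threshold,
    grouping = x$config$grouping
  )
}

#' Tidy a 5x2 CV F-test: the per-repetition fold differences
#' @param x A `bs_ftest` object.
#' @param ... Unused.
#' @return A tibble (`repetition`, `fold`, `diff`).
#' @method tidy bs_ftest
#' @export
tidy.bs_ftest <- function(x, ...) {
  x$differences
}

#' One-row summary of a 5x2 CV F-test
#' @param x A `bs_ftest` object.
#' @param ... Unused.
#' @return A one-row tibble (`f_statistic`, `df1`, `df2`, `p_value`,
#'   `degenerate`).
#' @method glance bs_ftest
#' @export
glance.bs_ftest <- function(x, ...) {
  tibble::tibble(
    comparison = paste(x$spec_a, "vs", x$spec_b),
    f_statistic = x$f_statistic, df1 = x$df[1], df2 = x$df[2],
    p_value = x$p_value, degenerate = x$degenerate
  )
}

#' Tidy a PCA projection: per-sample coordinates
#' @param x A `bs_pca` object.
#' @param ... Unused.
#' @return A tibble of scores.
#' @method tidy bs_pca
#' @export
tidy.bs_pca <- function(x, ...) {
  x$scores
}

#' One-row summary of a PCA projection
#' @param x A `bs_pca` object.
#' @param ... Unused.
#' @return A one-row tibble of explained-variance fractions.
#' @method glance bs_pca
#' @export
glance.bs_pca <- function(x, ...) {
  ev <- setNames(as.list(x$explained_variance),
                 paste0("var_PC", seq_along(x$explained_variance)))
  tibble::as_tibble(ev)
}

#' Tidy a correlation matrix into long format
#' @param x A `bs_cor` object.
#' @param ... Unused.
#' @return A tibble (`barrel_a`, `barrel_b`, `rho`).
#' @method tidy bs_cor
#' @export
tidy.bs_cor <- function(x, ...) {
  m <- unclass(x)
  tibble::as_tibble(as.table(m), .name_repair = "minimal") |>
    setNames(c("barrel_a", "barrel_b", "rho"))
}
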