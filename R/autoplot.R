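#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_tile geom_col
#'   scale_fill_gradient2 labs theme_minimal coord_equal
NULL

#' @export
ggplot2::autoplot

#' Scatter plot of a PCA projection
#'
#' @param object A [pca_project()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bs_pca
#' @export
autoplot.bs_pca <- function(object, ...) {
  df <- object$scores
  ev <- object$explained_variance
  p <- ggplot(df, aes(x = .data$PC1, y = .data$PC2))
  if ("class_label" %in% names(df)) {
    p <- p + geom_point(aes(colour = .data$class_label), size = 2)
  } else {
    p <- p + geom_point(size = 2)
  }
  p +
    labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
      y = if (length(ev) > 1) sprintf("PC2 (%.1f%%)", 100 * ev[2]) else "PC2",
      colour = "Class"
    ) +
    theme_minimal()
}

#' Heatmap of a barrel correlation matrix
#'
#' @param object A [spearman_matrix()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bs_cor
#' @export
autoplot.bs_cor <- function(object, ...) {
  df <- tidy(object)
  ord <- rownames(object)
  df$barrel_a <- factor(df$barrel_a, levels = ord)
  df$barrel_b <- factor(df$barrel_b, levels = rev(ord))
  ggplot(df, aes(x = .data$barrel_a, y = .data$barrel_b, fill = .data$rho)) +
    geom_tile() +
    scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac", mid = "white",
                         high = "#b2182b") +
    coord_equal() +
    labs(x = NULL, y = NULL, fill = "Spearman\nrho") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Confusion-matrix heatmap of a cross-validation result
#'
#' Rows are true classes, columns predicted; tiles show row-normalized
#' prediction fractions with counts printed.
#'
#' @param object A [nested_cv()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bs_cv
#' @export
autoplot.bs_cv <- function(object, ...) {
  cm <- as.data.frame(object$confusion)
  names(cm) <- c("true", "predicted", "n")
  cm <- cm |>
    dplyr::group_by(.data$true) |>
    dplyr::mutate(frac = .data$n / pmax(sum(.data$n), 1)) |>
    dplyr::ungroup()
  cm$true <- factor(cm$true, levels = rev(levels(factor(cm$true))))
  ggplot(cm, aes(x = .data$predicted, y = .data$true, fill = .data$frac)) +
    geom_tile() +
    ggplot2::geom_text(aes(label = .data$n)) +
    scale_fill_gradient2(limits = c(0, 1), low = "#2166ac", mid = "white",
                         high = "#b2182b", midpoint = 0.5) +
    coord_equal() +
    labs(x = "Predicted class", y = "True class", fill = "Fraction",
         title = object$spec$algorithm) +
    theme_minimal()
}

#' Bar chart of a combined feature ranking
#'
#' Features ordered by combined rank (most important first), bar height is
#' the summed rank (lower = better).
#'
#' @param object A [combined_rank()] result.
#' @param top Show only the `top` most important features (default all).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bs_ranking
#' @export
autoplot.bs_ranking <- function(object, top = nrow(object), ...) {
  df <- utils::head(as.data.frame(object), top)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot(df, aes(x = .data$combined_rank, y = .data$feature)) +
    geom_col(fill = "#4393c3") +
    labs(x = "Combined rank (sum of three methods; lower = more important)",
         y = NULL) +
    theme_minimal()
}
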