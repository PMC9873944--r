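#' Principal component projection of fingerprints
#'
#' Mean-centred PCA of the fingerprint matrix. The sign of each component is
#' fixed by making its largest-magnitude loading positive, so projections
#' are invariant to sample order and reproducible across platforms. If the
#' requested number of components exceeds the matrix rank it is reduced
#' with a warning.
#'
#' @param fingerprints Fingerprint tibble.
#' @param n_components Number of leading components (default 2).
#' @return An object of class `bs_pca`: `scores` (tibble with `sample_id`,
#'   optional `class_label`, `PC1`, `PC2`, ...), `loadings` (matrix),
#'   `explained_variance` (fractions).
#' @export
#' @examples
#' fps <- tibble::tibble(sample_id = as.character(1:4),
#'                       class_label = c("a", "a", "b", "b"),
#'                       b1 = c(0, 0.1, 1, 1.1), b2 = c(0.5, 0.4, 0.5, 0.6))
#' pca_project(fps)$explained_variance
pca_project <- function(fingerprints, n_components = 2) {
  parts <- fingerprint_parts(fingerprints)
  if (nrow(parts$x) < 2) abort("PCA needs at least 2 samples.")
  fit <- prcomp(parts$x, center = TRUE, scale. = FALSE)
  rank <- sum(fit$sdev > max(fit$sdev) * 1e-10)
  if (n_components > rank) {
    warn(sprintf("Requested %d components but rank is %d; reducing.",
                 n_components, rank))
    n_components <- rank
  }
  idx <- seq_len(n_components)
  rot <- fit$rotation[, idx, drop = FALSE]
  scores <- fit$x[, idx, drop = FALSE]
  # Sign convention: the largest-magnitude loading of each axis is positive.
  for (j in idx) {
    flip <- sign(rot[which.max(abs(rot[, j])), j])
    if (flip < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- fit$sdev^2 / sum(fit$sdev^2)

  score_tbl <- tibble::tibble(sample_id = parts$sample_id)
  if (!is.null(parts$class_label)) score_tbl$class_label <- parts$class_label
  score_tbl <- dplyr::bind_cols(score_tbl, tibble::as_tibble(scores))

  structure(
    list(scores = score_tbl, loadings = rot,
         explained_variance = ev[idx], all_variance = ev),
    class = "bs_pca"
  )
}

#' @export
print.bs_pca <- function(x, ...) {
  cat(sprintf("<bs_pca> %d components; explained variance: %s\n",
              length(x$explained_variance),
              paste(sprintf("%.1f%%", 100 * x$explained_variance),
                    collapse = ", ")))
  invisible(x)
}

#' Spearman rank correlation between barrels
#'
#' Rank correlation (average ranks on ties) of every pair of barrels'
#' responses across fingerprints, the standard redundancy view of a sensor
#' panel. Constant barrels have undefined correlations; their entries are
#' `NA` and a warning names them. The matrix is symmetric with unit
#' diagonal by construction, and both properties are asserted before
#' returning.
#'
#' @param fingerprints Fingerprint tibble (at least 3 rows).
#' @return A correlation matrix of class `bs_cor`.
#' @export
#' @examples
#' fps <- tibble::tibble(sample_id = as.character(1:4),
#'                       b1 = c(1, 2, 3, 4), b2 = c(1, 3, 2, 4))
#' spearman_matrix(fps)["b1", "b2"] # 0.8
spearman_matrix <- function(fingerprints) {
  parts <- fingerprint_parts(fingerprints)
  if (nrow(parts$x) < 3) abort("Spearman matrix needs at least 3 fingerprints.")
  constant <- apply(parts$x, 2, function(v) max(v) == min(v))
  if (any(constant)) {
    warn(sprintf("Constant barrel(s) have undefined correlations: %s",
                 paste(colnames(parts$x)[constant], collapse = ", ")))
  }
  rho <- suppressWarnings(cor(parts$x, method = "spearman"))
  diag(rho) <- 1
  stopifnot(isTRUE(all.equal(rho, t(rho))), all(diag(rho) == 1))
  structure(rho, class = c("bs_cor", "matrix"))
}

#' @export
print.bs_cor <- function(x, ...) {
  cat(sprintf("<bs_cor> %d x %d Spearman correlation matrix\n",
              nrow(x), ncol(x)))
  print(round(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))], 3))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
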