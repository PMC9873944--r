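# Independent brute-force oracle for the generalized ESD test: sequential
# extreme removal with freshly computed t-quantile critical values, written
# from the textbook recursion without reference to the package internals.
esd_oracle <- function(x, alpha = 0.05, k = NULL) {
  n <- length(x)
  if (is.null(k)) k <- min(max(1, floor(n / 3)), n - 2)
  idx <- seq_len(n)
  removed <- integer(0)
  exceeded <- logical(0)
  for (i in seq_len(k)) {
    cur <- x[idx]
    if (length(unique(cur)) == 1L) break
    dev <- abs(cur - mean(cur))
    j <- which(dev == max(dev))[1]
    r_i <- dev[j] / sqrt(sum((cur - mean(cur))^2) / (length(cur) - 1))
    m <- length(cur)
    p <- 1 - alpha / (2 * m)
    tq <- stats::qt(p, df = m - 2)
    lambda_i <- (m - 1) * tq / sqrt((m - 2 + tq^2) * m)
    removed <- c(removed, idx[j])
    exceeded <- c(exceeded, r_i > lambda_i)
    idx <- idx[-j]
  }
  if (any(exceeded)) removed[seq_len(max(which(exceeded)))] else integer(0)
}

# Minimal fingerprint tibble builder: class-shifted Gaussian features.
# `shifts` is a features x classes matrix of class means; noise is iid.
make_fps <- function(n_per_class = 10, shifts, noise_sd = 0.1, seed = 1) {
  withr::with_seed(seed, {
    n_feat <- nrow(shifts)
    classes <- colnames(shifts) %||% paste0("c", seq_len(ncol(shifts)))
    rows <- lapply(seq_along(classes), function(ci) {
      m <- matrix(rep(shifts[, ci], each = n_per_class), nrow = n_per_class) +
        matrix(stats::rnorm(n_per_class * n_feat, 0, noise_sd),
               nrow = n_per_class)
      colnames(m) <- paste0("F", seq_len(n_feat))
      tibble::tibble(
        sample_id = sprintf("%s_%02d", classes[ci], seq_len(n_per_class)),
        class_label = classes[ci]
      ) |>
        dplyr::bind_cols(tibble::as_tibble(m))
    })
    dplyr::bind_rows(rows)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
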