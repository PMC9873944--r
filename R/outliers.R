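#' Generalized ESD (Rosner) outlier test on a numeric vector
#'
#' Rosner's iterative extreme Studentized deviate procedure for up to
#' `max_outliers` outliers. At iteration `i` (on the `n - i + 1` remaining
#' points) the statistic is `R_i = max |x - mean| / sd`; the most extreme
#' point is set aside and `R_i` is compared with the critical value
#' \deqn{\lambda_i = \frac{(n-i)\, t_{p,\,n-i-1}}{\sqrt{(n-i-1+t^2_{p,\,n-i-1})(n-i+1)}},
#'       \quad p = 1 - \frac{\alpha}{2(n-i+1)}.}
#' The number of outliers is the *largest* `i` with `R_i > lambda_i`, and the
#' flags are the first `i` points removed — so an inner exceedance rescues
#' earlier non-exceeding iterations, which is what distinguishes the
#' generalized ESD test from repeated Grubbs tests.
#'
#' Ties in the most extreme point are broken by lowest index for
#' reproducibility. A zero-variance first iteration flags nothing.
#'
#' @param values Numeric vector, at least 4 finite values.
#' @param alpha Significance level of the test.
#' @param max_outliers Upper bound on the number of outliers tested;
#'   `"auto"` (default) uses `floor(n/3)` capped at `n - 2`.
#' @return A list of class `bs_esd`: `flags` (integer indices into `values`),
#'   and `trace`, a tibble with one row per iteration (`i`, `index`,
#'   `value`, `r`, `lambda`, `exceeds`).
#' @references Rosner, B. (1983) Percentage points for a generalized ESD
#'   many-outlier procedure. *Technometrics* 25, 165-172.
#' @export
#' @examples
#' esd_flags(c(1.0, 1.1, 0.9, 1.05, 0.95, 8.0), alpha = 0.05)$flags
esd_flags <- function(values, alpha = 0.05, max_outliers = "auto") {
  if (!is.numeric(values)) abort("`values` must be numeric.")
  if (any(!is.finite(values))) abort("`values` must be finite.")
  n <- length(values)
  if (n < 4) abort("Generalized ESD needs at least 4 values.")
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must be in (0, 1).")
  if (identical(max_outliers, "auto")) {
    max_outliers <- min(max(1L, floor(n / 3)), n - 2L)
  }
  max_outliers <- as.integer(max_outliers)
  if (max_outliers < 1 || max_outliers > n - 2L) {
    abort("`max_outliers` must be between 1 and n - 2.")
  }

  remaining <- seq_len(n)
  trace <- vector("list", max_outliers)
  for (i in seq_len(max_outliers)) {
    x <- values[remaining]
    s <- sd(x)
    if (s == 0) {
      if (i == 1L) {
        # Degenerate sample: identical values carry no outlier signal.
        return(structure(list(flags = integer(0),
                              trace = tibble::tibble(
                                i = integer(0), index = integer(0),
                                value = numeric(0), r = numeric(0),
                                lambda = numeric(0), exceeds = logical(0))),
                         class = "bs_esd"))
      }
      trace <- trace[seq_len(i - 1L)]
      break
    }
    dev <- abs(x - mean(x))
    pos <- which.max(dev) # which.max takes the first maximum: lowest index
    r <- dev[pos] / s

    n_i <- n - i + 1L              # points entering this iteration
    p <- 1 - alpha / (2 * n_i)
    nu <- n_i - 2L                 # t degrees of freedom, n - i - 1
    tq <- qt(p, df = nu)
    lambda <- (n_i - 1L) * tq / sqrt((nu + tq^2) * n_i)

    trace[[i]] <- tibble::tibble(
      i = i, index = remaining[pos], value = x[pos],
      r = r, lambda = lambda, exceeds = r > lambda
    )
    remaining <- remaining[-pos]
  }
  trace <- dplyr::bind_rows(trace)
  n_out <- if (any(trace$exceeds)) max(trace$i[trace$exceeds]) else 0L
  structure(
    list(flags = trace$index[seq_len(n_out)], trace = trace),
    class = "bs_esd"
  )
}

#' @export
print.bs_esd <- function(x, ...) {
  cat(sprintf("<bs_esd> %d outlier(s) flagged over %d iteration(s)\n",
              length(x$flags), nrow(x$trace)))
  print(x$trace)
  invisible(x)
}

#' Outlier screening parameters
#'
#' @param alpha ESD significance level (the assay's "outlier exclusion
#'   threshold"); default 0.05.
#' @param drop_threshold Minimum number of flagged readings that excludes a
#'   whole fingerprint; default 2.
#' @param max_outliers Passed to [esd_flags()]; `"auto"` or an integer.
#' @param grouping Population each reading is tested against: `"class"`
#'   (default) tests a barrel's values across same-class fingerprints;
#'   `"global"` pools all fingerprints per barrel (for unlabelled data).
#' @return A list of class `bs_outlier_config`.
#' @export
outlier_config <- function(alpha = 0.05, drop_threshold = 2,
                           max_outliers = "auto",
                           grouping = c("class", "global")) {
  grouping <- match.arg(grouping)
  stopifnot(alpha > 0, alpha < 1, drop_threshold >= 1)
  structure(
    list(alpha = alpha, drop_threshold = as.integer(drop_threshold),
         max_outliers = max_outliers, grouping = grouping),
    class = "bs_outlier_config"
  )
}

#' Screen fingerprints with the generalized ESD test and a drop rule
#'
#' Applies [esd_flags()] to each (group, barrel) population of normalized
#' values — by default the same-class fingerprints' values for one barrel —
#' and excludes any fingerprint accumulating at least `drop_threshold`
#' flagged readings. Groups with fewer than 4 members are skipped with a
#' warning and contribute no flags.
#'
#' @param fingerprints Fingerprint tibble (from [aggregate_replicates()] or
#'   compatible: `sample_id`, optional `class_label`, numeric barrel
#'   columns).
#' @param config An [outlier_config()]; individual fields may also be
#'   overridden via `...` for convenience.
#' @param ... Overrides for `alpha`, `drop_threshold`, `max_outliers`,
#'   `grouping`.
#' @return A list of class `bs_screen`: `retained` (fingerprint tibble),
#'   `dropped` (fingerprint tibble), `flags` (tibble `sample_id`,
#'   `barrel_id`, `group`, `value`), `traces` (named list of [esd_flags()]
#'   traces per group:barrel), `config`, and counts. Use [generics::tidy()]
#'   for the flag table and [generics::glance()] for the summary row.
#' @export
#' @examples
#' panel <- sim_panel(n_barrels = 6, n_classes = 2, n_informative = 2, seed = 1)
#' sim <- simulate_raw_plates(panel, sim_config(n_samples_per_class = 6,
#'                                              n_technical_reps = 2, seed = 1))
#' scr <- screen_fingerprints(preprocess_plates(sim$readings))
#' scr$n_dropped
screen_fingerprints <- function(fingerprints, config = outlier_config(), ...) {
  stopifnot(inherits(config, "bs_outlier_config"))
  dots <- list(...)
  if (length(dots) > 0) {
    config <- do.call(outlier_config, utils::modifyList(
      config[c("alpha", "drop_threshold", "max_outliers", "grouping")], dots))
  }
  parts <- fingerprint_parts(fingerprints)

  group <- if (config$grouping == "class" && !is.null(parts$class_label)) {
    parts$class_label
  } else {
    if (config$grouping == "class" && is.null(parts$class_label)) {
      warn("No class_label column; falling back to global grouping.")
    }
    rep("all", nrow(fingerprints))
  }

  flags <- list()
  traces <- list()
  small_groups <- character(0)
  for (g in unique(group)) {
    rows <- which(group == g)
    if (length(rows) < 4) {
      small_groups <- c(small_groups, g)
      next
    }
    for (b in parts$features) {
      res <- esd_flags(parts$x[rows, b], alpha = config$alpha,
                       max_outliers = config$max_outliers)
      traces[[paste(g, b, sep = ":")]] <- res$trace
      if (length(res$flags) > 0) {
        idx <- rows[res$flags]
        flags[[length(flags) + 1L]] <- tibble::tibble(
          sample_id = parts$sample_id[idx], barrel_id = b, group = g,
          value = parts$x[idx, b]
        )
      }
    }
  }
  if (length(small_groups) > 0) {
    warn(sprintf("Group(s) with fewer than 4 fingerprints skipped: %s",
                 paste(small_groups, collapse = ", ")))
  }
  flags <- if (length(flags) > 0) dplyr::bind_rows(flags) else {
    tibble::tibble(sample_id = character(0), barrel_id = character(0),
                   group = character(0), value = numeric(0))
  }

  flag_counts <- flags |>
    dplyr::count(.data$sample_id, name = "n_flags")
  dropped_ids <- flag_counts$sample_id[flag_counts$n_flags >= config$drop_threshold]

  structure(
    list(
      retained = fingerprints[!fingerprints$sample_id %in% dropped_ids, ],
      dropped = fingerprints[fingerprints$sample_id %in% dropped_ids, ],
      flags = flags,
      flag_counts = flag_counts,
      traces = traces,
      config = config,
      n_input = nrow(fingerprints),
      n_retained = sum(!fingerprints$sample_id %in% dropped_ids),
      n_dropped = length(dropped_ids)
    ),
    class = "bs_screen"
  )
}

#' @export
print.bs_screen <- function(x, ...) {
  cat(sprintf(
    "<bs_screen> %d fingerprints in, %d retained, %d dropped (alpha = %g, drop threshold = %d)\n",
    x$n_input, x$n_retained, x$n_dropped, x$config$alpha, x$config$drop_threshold
  ))
  if (nrow(x$flags) > 0) {
    cat(sprintf("%d flagged reading(s) across %d fingerprint(s)\n",
                nrow(x$flags), nrow(x$flag_counts)))
  }
  invisible(x)
}
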