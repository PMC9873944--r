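## Internal helpers shared across modules.

# Run code under a temporary RNG state when a seed is given; leave the
# caller's RNG untouched either way.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    withr::with_seed(as.integer(seed), code)
  }
}

# Ranks where 1 = best (largest score); ties get the average rank,
# matching the convention used for rank aggregation.
rank_desc <- function(scores) {
  rank(-scores, ties.method = "average")
}

assert_fingerprints <- function(fingerprints, call = rlang::caller_env()) {
  if (!is.data.frame(fingerprints)) {
    abort("`fingerprints` must be a data frame.", call = call)
  }
  if (!"sample_id" %in% names(fingerprints)) {
    abort("`fingerprints` must have a `sample_id` column.", call = call)
  }
  invisible(fingerprints)
}

# Split a fingerprint table into its numeric feature matrix and metadata.
fingerprint_parts <- function(fingerprints) {
  assert_fingerprints(fingerprints)
  meta_cols <- intersect(c("sample_id", "class_label", "n_reps_aggregated"),
                         names(fingerprints))
  feature_cols <- setdiff(names(fingerprints), meta_cols)
  x <- as.matrix(fingerprints[feature_cols])
  if (!is.numeric(x)) {
    abort("Fingerprint feature columns must all be numeric.")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    abort("Fingerprint feature values must be finite and non-missing.")
  }
  rownames(x) <- fingerprints$sample_id
  list(
    x = x,
    features = feature_cols,
    sample_id = fingerprints$sample_id,
    class_label = if ("class_label" %in% names(fingerprints)) {
      as.character(fingerprints$class_label)
    } else {
      NULL
    }
  )
}

# 384-well coordinate for a (block, position) pair. Blocks are eight
# 48-well patterns of 3 columns x 16 rows, matching the assay layout.
well_coordinate <- function(block, position) {
  stopifnot(all(block >= 1L & block <= 8L), all(position >= 1L & position <= 48L))
  row <- ((position - 1L) %% 16L) + 1L
  col <- (block - 1L) * 3L + ((position - 1L) %/% 16L) + 1L
  paste0(LETTERS[row], col)
}
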