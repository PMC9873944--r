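#' Reference-based min-max normalization of a raw reading
#'
#' Scales a raw fluorescence reading against the assay's reference wells:
#' \deqn{\mathrm{normalized} = \frac{X - \mathrm{Min}_{A+F}}{\mathrm{Max} - \mathrm{Min}_F}}
#' where `X` is the barrel + dye + analyte well, `Min_AF` the analyte + dye
#' well (correcting analyte autofluorescence), `Max` the barrel + dye well and
#' `Min_F` the dye-alone well. The result is 1 for an untouched loaded barrel
#' and 0 for fully displaced dye; values are *not* clipped, so strong
#' displacement combined with autofluorescence can go negative and noisy
#' wells can exceed 1.
#'
#' All arguments are vectorized and recycled.
#'
#' @param x Sample well intensity.
#' @param min_af Analyte + dye reference intensity.
#' @param max_ref Barrel + dye reference intensity.
#' @param min_f Dye-alone reference intensity.
#' @return Normalized signal (dimensionless).
#' @export
#' @examples
#' normalize_reading(50, 10, 90, 10) # 0.5
normalize_reading <- function(x, min_af, max_ref, min_f) {
  denom <- max_ref - min_f
  if (any(denom == 0)) {
    abort("Degenerate reference: Max - Min_F is zero.")
  }
  (x - min_af) / denom
}

#' Normalize a long-format plate table against its reference wells
#'
#' Computes per-reading normalized signals from a raw readings table (the
#' schema written by [simulate_raw_plates()] / read by
#' [read_raw_readings()]). Reference wells are aggregated by median within
#' their scope before use: `max_ref` per (plate, barrel), `dye_ref` per
#' plate, `analyte_ref` per (plate, analyte) where the analyte key column is
#' `analyte_key` (default `class_label`, i.e. one autofluorescence reference
#' per analyte class per plate). With `ref_scope = "global"` the references
#' are pooled across plates instead.
#'
#' A barrel whose reference range `Max - Min_F` on some plate is not
#' positive, or falls below `min_dynamic_range` times that plate's median
#' range, has no usable dynamic range there (this is how non-binding control
#' channels, and receptors with too little loaded fluorescence, announce
#' themselves). Such barrels are excluded from the whole panel — a partial
#' barrel would leave most fingerprints incomplete — and reported with the
#' plates that condemned them. Sample readings lacking a matching reference
#' are likewise excluded and reported.
#'
#' @param readings Raw readings tibble.
#' @param ref_scope `"plate"` (default) or `"global"`.
#' @param analyte_key Column identifying the analyte of `analyte_ref` wells
#'   and sample wells (`"class_label"` or `"sample_id"`).
#' @param min_dynamic_range Minimum usable reference range, as a fraction of
#'   the per-plate median range.
#' @return A tibble with `plate_id`, `barrel_id`, `sample_id`, `class_label`,
#'   `replicate`, `value`, carrying a `report` attribute (a list with
#'   `degenerate_references` and `missing_references` tibbles); retrieve it
#'   with [preprocess_report()].
#' @export
normalize_plates <- function(readings,
                             ref_scope = c("plate", "global"),
                             analyte_key = "class_label",
                             min_dynamic_range = 0.05) {
  ref_scope <- match.arg(ref_scope)
  if (!analyte_key %in% names(readings)) {
    abort(sprintf("`analyte_key` column '%s' not present in readings.", analyte_key))
  }
  needed <- c("plate_id", "role", "barrel_id", "sample_id", "replicate", "intensity")
  missing <- setdiff(needed, names(readings))
  if (length(missing) > 0) {
    abort(sprintf("Readings are missing column(s): %s.", paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(readings$intensity))) {
    abort("All intensities must be finite.")
  }

  if (ref_scope == "global") {
    # Pool references by erasing the plate key before aggregation.
    ref_plate <- function(df) dplyr::mutate(df, plate_id = "__global__")
  } else {
    ref_plate <- identity
  }

  max_ref <- readings |>
    dplyr::filter(.data$role == "max_ref") |>
    ref_plate() |>
    dplyr::group_by(.data$plate_id, .data$barrel_id) |>
    dplyr::summarise(max_i = median(.data$intensity), .groups = "drop")
  min_f <- readings |>
    dplyr::filter(.data$role == "dye_ref") |>
    ref_plate() |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::summarise(min_f = median(.data$intensity), .groups = "drop")
  min_af <- readings |>
    dplyr::filter(.data$role == "analyte_ref") |>
    ref_plate() |>
    dplyr::group_by(.data$plate_id, analyte = .data[[analyte_key]]) |>
    dplyr::summarise(min_af = median(.data$intensity), .groups = "drop")

  if (nrow(max_ref) == 0 || nrow(min_f) == 0 || nrow(min_af) == 0) {
    abort("Readings must contain max_ref, dye_ref and analyte_ref wells.")
  }

  ranges <- max_ref |>
    dplyr::left_join(min_f, by = "plate_id") |>
    dplyr::mutate(range = .data$max_i - .data$min_f) |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::mutate(usable = .data$range > 0 &
                    .data$range >= min_dynamic_range * median(pmax(.data$range, 0))) |>
    dplyr::ungroup()
  degenerate <- ranges |>
    dplyr::filter(!.data$usable) |>
    dplyr::select("plate_id", "barrel_id", "range")
  # degenerate anywhere -> excluded everywhere (panel-wide barrel drop)
  bad_barrels <- unique(degenerate$barrel_id)
  ranges$usable <- ranges$usable & !ranges$barrel_id %in% bad_barrels

  samples <- readings |>
    dplyr::filter(.data$role == "sample") |>
    dplyr::mutate(.ref_plate = if (ref_scope == "global") "__global__" else .data$plate_id,
                  analyte = .data[[analyte_key]])

  joined <- samples |>
    dplyr::left_join(dplyr::select(ranges, "plate_id", "barrel_id", "max_i",
                                   "min_f", "usable"),
                     by = c(".ref_plate" = "plate_id", "barrel_id")) |>
    dplyr::left_join(min_af, by = c(".ref_plate" = "plate_id", "analyte"))

  missing_refs <- joined |>
    dplyr::filter(is.na(.data$max_i) | is.na(.data$min_f) | is.na(.data$min_af)) |>
    dplyr::select(dplyr::any_of(c("plate_id", "well", "barrel_id", "sample_id",
                                  "replicate")))
  if (nrow(missing_refs) > 0) {
    warn(sprintf("%d sample reading(s) had no matching reference and were dropped.",
                 nrow(missing_refs)))
  }

  out <- joined |>
    dplyr::filter(!is.na(.data$max_i), !is.na(.data$min_f), !is.na(.data$min_af),
                  .data$usable) |>
    dplyr::mutate(value = (.data$intensity - .data$min_af) / (.data$max_i - .data$min_f))

  keep <- intersect(c("plate_id", "barrel_id", "sample_id", "class_label",
                      "replicate", "value"),
                    c(names(out), "value"))
  out <- dplyr::select(out, dplyr::all_of(keep))
  attr(out, "report") <- list(
    degenerate_references = degenerate,
    missing_references = missing_refs
  )
  out
}

#' Retrieve the preprocessing report attached to a result
#'
#' @param x A result of [normalize_plates()] or [preprocess_plates()].
#' @return A list of report tibbles (degenerate references, missing
#'   references, dropped samples).
#' @export
preprocess_report <- function(x) {
  attr(x, "report")
}

#' Aggregate technical replicates into per-sample fingerprints
#'
#' Collapses normalized readings to one fingerprint per sample by taking the
#' per-barrel median across technical replicates (and plates, when a sample
#' was read on several). Samples missing one or more barrels are dropped and
#' reported by default (`on_missing = "drop"`); with `on_missing = "keep"`
#' they are retained with `NA` in the missing positions.
#'
#' @param normalized Output of [normalize_plates()].
#' @param on_missing `"drop"` (default) or `"keep"`.
#' @return A wide tibble: `sample_id`, `class_label` (if available),
#'   `n_reps_aggregated`, then one numeric column per barrel. The `report`
#'   attribute lists dropped samples.
#' @export
aggregate_replicates <- function(normalized, on_missing = c("drop", "keep")) {
  on_missing <- match.arg(on_missing)
  needed <- c("barrel_id", "sample_id", "value")
  if (!all(needed %in% names(normalized))) {
    abort("`normalized` must have barrel_id, sample_id and value columns.")
  }
  has_class <- "class_label" %in% names(normalized)

  per_barrel <- normalized |>
    dplyr::group_by(.data$sample_id, .data$barrel_id) |>
    dplyr::summarise(
      value = median(.data$value),
      n_reps = dplyr::n(),
      class_label = if (has_class) dplyr::first(.data$class_label) else NA_character_,
      .groups = "drop"
    )

  all_barrels <- sort(unique(per_barrel$barrel_id))
  wide <- per_barrel |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(n_reps_aggregated = max(.data$n_reps)) |>
    dplyr::ungroup() |>
    dplyr::select(-"n_reps") |>
    tidyr::pivot_wider(names_from = "barrel_id", values_from = "value")

  incomplete <- wide$sample_id[!stats::complete.cases(wide[all_barrels])]
  if (on_missing == "drop" && length(incomplete) > 0) {
    warn(sprintf("Dropped %d sample(s) with incomplete fingerprints: %s",
                 length(incomplete), paste(head(incomplete, 5), collapse = ", ")))
    wide <- wide[!wide$sample_id %in% incomplete, ]
  }

  meta <- c("sample_id", if (has_class) "class_label", "n_reps_aggregated")
  out <- dplyr::select(wide, dplyr::all_of(meta), dplyr::all_of(all_barrels))
  attr(out, "report") <- c(
    attr(normalized, "report"),
    list(dropped_samples = incomplete)
  )
  out
}

#' Raw plate readings to screened-ready fingerprints
#'
#' Convenience wrapper chaining [normalize_plates()] and
#' [aggregate_replicates()].
#'
#' @inheritParams normalize_plates
#' @inheritParams aggregate_replicates
#' @return Fingerprint tibble with a combined `report` attribute.
#' @export
#' @examples
#' panel <- sim_panel(n_barrels = 6, n_classes = 2, n_informative = 2, seed = 1)
#' sim <- simulate_raw_plates(panel, sim_config(n_samples_per_class = 4,
#'                                              n_technical_reps = 2, seed = 1))
#' fps <- preprocess_plates(sim$readings)
#' dim(fps)
preprocess_plates <- function(readings,
                              ref_scope = c("plate", "global"),
                              analyte_key = "class_label",
                              min_dynamic_range = 0.05,
                              on_missing = c("drop", "keep")) {
  normalized <- normalize_plates(readings, ref_scope = ref_scope,
                                 analyte_key = analyte_key,
                                 min_dynamic_range = min_dynamic_range)
  aggregate_replicates(normalized, on_missing = on_missing)
}
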