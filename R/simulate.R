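#' Construct a synthetic receptor panel with known ground truth
#'
#' Builds a panel of dye-binding receptor "barrels" plus two control channels
#' (a no-receptor blank and a collapsed, non-binding bundle), together with a
#' barrel-by-class analyte affinity matrix. A subset of barrels is planted as
#' *informative*: their analyte affinities differ between classes by up to
#' `fold_change`, while all other barrels respond identically to every class.
#'
#' Affinities are dissociation-constant-like quantities in the same
#' concentration units as the analyte concentrations handed to
#' [simulate_raw_plates()]: a lower `K` means stronger binding and therefore
#' more dye displacement. For each informative barrel the class-specific
#' affinities are `K0 / m_c` with multipliers `m_c` log-spaced over
#' `[1, fold_change]` and assigned to classes in a random order per barrel
#' (`class_spread = "shuffled"`), so different informative barrels order the
#' classes differently and no single barrel is sufficient by construction.
#' With `class_spread = "ordered"` every informative barrel ranks the classes
#' the same way, which makes low-dimensional panels separable — useful for
#' constructing minimal arrays.
#'
#' The `informative` flag stored on the barrel table is *derived from the
#' affinity matrix* by the stated rule (max/min class affinity ratio at least
#' `fold_threshold`), not copied from the planting, so it stays honest if the
#' affinities are edited afterwards.
#'
#' @param n_barrels Number of receptor barrels (controls are added on top).
#' @param n_classes Number of analyte classes.
#' @param n_informative Number of barrels planted with class-dependent
#'   affinities; the default `NULL` uses 10 or `n_barrels`, whichever is
#'   smaller.
#' @param fold_change Maximum between-class affinity ratio for planted
#'   barrels.
#' @param fold_threshold Ratio at or above which a barrel is labelled
#'   informative in the ground truth (default 2).
#' @param class_spread `"shuffled"` (default) or `"ordered"`; see Details.
#' @param dye_affinity_meanlog,dye_affinity_sdlog Log-normal parameters for
#'   per-barrel dye dissociation constants (same units as
#'   `dye_concentration`).
#' @param base_affinity_meanlog,base_affinity_sdlog Log-normal parameters for
#'   the class-independent component of analyte affinities.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters for the
#'   loaded-barrel fluorescence intensity (arbitrary units).
#' @param seed Integer seed; the caller's RNG state is untouched.
#'
#' @return An object of class `bs_panel`: a list with `barrels` (a tibble with
#'   `barrel_id`, `group`, `is_control`, `dye_affinity`, `baseline_max`,
#'   `informative`), `affinity` (barrel x class matrix), `classes` (class
#'   names) and `fold_threshold`.
#' @seealso [dye_occupancy()], [sim_config()], [simulate_raw_plates()]
#' @export
#' @examples
#' panel <- sim_panel(n_barrels = 12, n_classes = 3, n_informative = 4, seed = 1)
#' panel$barrels
sim_panel <- function(n_barrels = 46,
                      n_classes = 5,
                      n_informative = NULL,
                      fold_change = 4,
                      fold_threshold = 2,
                      class_spread = c("shuffled", "ordered"),
                      dye_affinity_meanlog = 0,
                      dye_affinity_sdlog = 0.4,
                      base_affinity_meanlog = log(10),
                      base_affinity_sdlog = 0.5,
                      baseline_meanlog = log(1000),
                      baseline_sdlog = 0.3,
                      seed = NULL) {
  class_spread <- match.arg(class_spread)
  n_informative <- n_informative %||% min(10L, n_barrels)
  if (n_barrels < 1) abort("`n_barrels` must be at least 1.")
  if (n_classes < 1) abort("`n_classes` must be at least 1.")
  if (n_informative > n_barrels) {
    abort("`n_informative` cannot exceed `n_barrels`.")
  }
  if (fold_change < 1 || fold_threshold < 1) {
    abort("`fold_change` and `fold_threshold` must be >= 1.")
  }

  with_seed_if(seed, {
    barrel_id <- sprintf("B%02d", seq_len(n_barrels))
    # Chemistry groups in roughly the proportions of a mixed hydrophobic /
    # polar / charged / aromatic panel (16:11:12:7 for the default 46).
    group_sizes <- c(I = 16, II = 11, III = 12, IV = 7)
    groups <- rep(rep(names(group_sizes), group_sizes), length.out = n_barrels)

    dye_affinity <- stats::rlnorm(n_barrels, dye_affinity_meanlog, dye_affinity_sdlog)
    baseline_max <- stats::rlnorm(n_barrels, baseline_meanlog, baseline_sdlog)
    base_affinity <- stats::rlnorm(n_barrels, base_affinity_meanlog, base_affinity_sdlog)

    classes <- sprintf("class%d", seq_len(n_classes))
    affinity <- matrix(rep(base_affinity, times = n_classes),
                       nrow = n_barrels, ncol = n_classes,
                       dimnames = list(barrel_id, classes))

    informative_idx <- if (n_informative > 0) {
      sort(sample.int(n_barrels, n_informative))
    } else {
      integer(0)
    }
    if (n_classes > 1) {
      multipliers <- fold_change^(seq(0, 1, length.out = n_classes))
      for (b in informative_idx) {
        ord <- if (class_spread == "shuffled") sample.int(n_classes) else seq_len(n_classes)
        affinity[b, ] <- base_affinity[b] / multipliers[ord]
      }
    }

    barrels <- tibble::tibble(
      barrel_id = c(barrel_id, "BLANK", "CTRL"),
      group = c(groups, "control", "control"),
      is_control = c(rep(FALSE, n_barrels), TRUE, TRUE),
      dye_affinity = c(dye_affinity, Inf, Inf),
      baseline_max = c(baseline_max, 0, 0)
    )

    affinity <- rbind(
      affinity,
      matrix(Inf, nrow = 2, ncol = n_classes,
             dimnames = list(c("BLANK", "CTRL"), classes))
    )

    ratio <- apply(affinity[seq_len(n_barrels), , drop = FALSE], 1,
                   function(k) max(k) / min(k))
    barrels$informative <- c(unname(ratio >= fold_threshold), FALSE, FALSE)

    structure(
      list(barrels = barrels, affinity = affinity, classes = classes,
           fold_threshold = fold_threshold),
      class = "bs_panel"
    )
  })
}

#' @export
print.bs_panel <- function(x, ...) {
  cat(sprintf(
    "<bs_panel> %d barrels + %d controls, %d classes, %d informative barrels\n",
    sum(!x$barrels$is_control), sum(x$barrels$is_control),
    length(x$classes), sum(x$barrels$informative)
  ))
  print(x$barrels, n = 6)
  invisible(x)
}

#' Equilibrium dye occupancy of a barrel under competing analytes
#'
#' Single-site competitive binding: the reporter dye at concentration `D` and
#' the analytes compete for one channel site, giving an occupied fraction
#' \deqn{\theta = \frac{D/K_D}{1 + D/K_D + \sum_a (c_a/K_{b,a})^h}.}
#' With no analyte this reduces to `(D/K_D) / (1 + D/K_D)`, and theta is
#' strictly decreasing in every analyte concentration. `hill` is an optional
#' cooperativity exponent applied to the analyte terms (default 1, i.e. no
#' cooperativity). Control channels bind no dye and return 0.
#'
#' @param panel A [sim_panel()] object.
#' @param barrel A barrel identifier present in the panel.
#' @param concentrations Named numeric vector of analyte concentrations; names
#'   must be panel class names. Missing analytes are treated as absent.
#' @param dye_concentration Reporter dye concentration (same units as the
#'   affinities).
#' @param hill Cooperativity exponent for the analyte terms.
#' @return Occupied fraction in `[0, 1]`.
#' @export
#' @examples
#' panel <- sim_panel(n_barrels = 4, n_classes = 2, seed = 1)
#' dye_occupancy(panel, "B01", c(class1 = 0), dye_concentration = 1)
dye_occupancy <- function(panel, barrel, concentrations,
                          dye_concentration = 1, hill = 1) {
  stopifnot(inherits(panel, "bs_panel"))
  if (length(barrel) != 1L || !barrel %in% panel$barrels$barrel_id) {
    abort(sprintf("Unknown barrel '%s'.", as.character(barrel)[1]))
  }
  if (length(concentrations) > 0) {
    if (is.null(names(concentrations)) || any(!nzchar(names(concentrations)))) {
      abort("`concentrations` must be a named vector of analyte concentrations.")
    }
    unknown <- setdiff(names(concentrations), colnames(panel$affinity))
    if (length(unknown) > 0) {
      abort(sprintf("Unknown analyte(s): %s.", paste(unknown, collapse = ", ")))
    }
    if (any(concentrations < 0)) {
      abort("Analyte concentrations must be non-negative.")
    }
  }
  if (dye_concentration < 0) abort("`dye_concentration` must be non-negative.")

  row <- match(barrel, panel$barrels$barrel_id)
  kd <- panel$barrels$dye_affinity[row]
  if (!is.finite(kd) || panel$barrels$is_control[row]) return(0)
  d_term <- dye_concentration / kd
  comp <- 0
  if (length(concentrations) > 0) {
    k <- panel$affinity[barrel, names(concentrations)]
    comp <- sum((concentrations / k)^hill)
  }
  d_term / (1 + d_term + comp)
}

#' Simulation settings for synthetic plate data
#'
#' Bundles the assay-level parameters of the fingerprint simulator. The
#' defaults mirror a small-molecule sensing campaign: five analyte classes
#' measured as ten independently prepared samples each, four technical
#' replicates per sample dispensed as 48-well array blocks on 384-well
#' plates, with modest replicate noise, per-plate gain variation, and rare
#' gross liquid-handling failures.
#'
#' @param dye_concentration Reporter dye concentration (affinity units).
#' @param concentration Analyte concentration; a scalar applied to every
#'   class, or a named vector per class.
#' @param n_samples_per_class Independent samples per analyte class.
#' @param n_technical_reps Technical replicate blocks per sample.
#' @param replicate_noise_sd Gaussian well noise, expressed on the normalized
#'   signal scale (it is converted to intensity units per well).
#' @param plate_gain_sd Standard deviation of the per-plate log-normal gain.
#' @param autofluorescence Additive analyte autofluorescence in intensity
#'   units; scalar or named per class.
#' @param dye_background Free-dye fluorescence intensity (the dye-alone
#'   reference level, before gain).
#' @param outlier_rate Per-well probability of a liquid-handling failure.
#' @param outlier_magnitude Multiplicative distortion applied to failed wells
#'   (the intensity is multiplied by this factor or its reciprocal, with equal
#'   probability).
#' @param hill Cooperativity exponent passed to the binding model.
#' @param seed Integer seed controlling every random draw of the simulation.
#' @return A validated list of class `bs_sim_config`.
#' @export
sim_config <- function(dye_concentration = 1,
                       concentration = 10,
                       n_samples_per_class = 10,
                       n_technical_reps = 4,
                       replicate_noise_sd = 0.05,
                       plate_gain_sd = 0.05,
                       autofluorescence = 30,
                       dye_background = 50,
                       outlier_rate = 0.01,
                       outlier_magnitude = 5,
                       hill = 1,
                       seed = 1L) {
  stopifnot(
    dye_concentration > 0,
    all(concentration >= 0),
    n_samples_per_class >= 1, n_technical_reps >= 1,
    replicate_noise_sd >= 0, plate_gain_sd >= 0,
    all(autofluorescence >= 0), dye_background > 0,
    outlier_rate >= 0, outlier_rate <= 1,
    outlier_magnitude > 0, hill > 0
  )
  structure(
    list(
      dye_concentration = dye_concentration,
      concentration = concentration,
      n_samples_per_class = as.integer(n_samples_per_class),
      n_technical_reps = as.integer(n_technical_reps),
      replicate_noise_sd = replicate_noise_sd,
      plate_gain_sd = plate_gain_sd,
      autofluorescence = autofluorescence,
      dye_background = dye_background,
      outlier_rate = outlier_rate,
      outlier_magnitude = outlier_magnitude,
      hill = hill,
      seed = as.integer(seed)
    ),
    class = "bs_sim_config"
  )
}

# Expand a scalar-or-named parameter to one value per class.
per_class <- function(value, classes, what) {
  if (length(value) == 1L && is.null(names(value))) {
    return(setNames(rep(value, length(classes)), classes))
  }
  if (is.null(names(value)) || !all(classes %in% names(value))) {
    abort(sprintf("`%s` must be a scalar or named for every class.", what))
  }
  value[classes]
}

#' Simulate raw 384-well plate readings with ground truth
#'
#' Emits a long-format table of raw fluorescence readings laid out as eight
#' 48-well array blocks per 384-well plate. Each plate carries three blocks
#' of loaded-barrel references (`max_ref`, barrel + dye, no analyte), a
#' reference block with four dye-alone wells (`dye_ref`) and replicated
#' analyte + dye wells per class (`analyte_ref`; four replicates when the
#' block has room), and up to four sample blocks (barrel + dye + analyte),
#' one block per technical replicate of a sample. Taking per-plate medians
#' over three reference wells makes every reference robust to a single
#' gross liquid-handling failure and shrinks the shared plate-level
#' reference error that would otherwise correlate all fingerprints read on
#' one plate.
#'
#' A well's noiseless intensity is
#' `gain * (baseline_max * theta + dye_background + autofluorescence)`,
#' with `theta` from [dye_occupancy()]; the per-plate gain is log-normal with
#' log-sd `plate_gain_sd`, and Gaussian noise scaled to the well's reference
#' range is added so that `replicate_noise_sd` is expressed on the normalized
#' scale. A Bernoulli(`outlier_rate`) subset of wells is distorted
#' multiplicatively by `outlier_magnitude` to emulate liquid-handling
#' failures. With all noise terms zero, pushing the output through
#' [preprocess_plates()] recovers the analytic occupancy ratio
#' `theta_with / theta_without` exactly.
#'
#' @param panel A [sim_panel()] object.
#' @param config A [sim_config()] object.
#' @return An object of class `bs_sim`: a list with `readings` (tibble:
#'   `plate_id`, `well`, `role`, `barrel_id`, `sample_id`, `class_label`,
#'   `replicate`, `intensity`), `truth_samples` (`sample_id`, `class_label`),
#'   `truth_barrels` (`barrel_id`, `informative`) and `outlier_wells` (the
#'   wells that were distorted).
#' @export
#' @examples
#' panel <- sim_panel(n_barrels = 8, n_classes = 2, n_informative = 3, seed = 1)
#' sim <- simulate_raw_plates(panel, sim_config(n_samples_per_class = 3,
#'                                              n_technical_reps = 2, seed = 1))
#' dplyr::count(sim$readings, role)
simulate_raw_plates <- function(panel, config) {
  stopifnot(inherits(panel, "bs_panel"), inherits(config, "bs_sim_config"))
  classes <- panel$classes
  if (length(classes) == 0) abort("Panel has no analyte classes.")
  if (nrow(panel$barrels) == 0) abort("Panel has no barrels.")
  n_panel <- nrow(panel$barrels)
  if (n_panel > 48) abort("Panel (including controls) cannot exceed 48 channels per block.")

  conc <- per_class(config$concentration, classes, "concentration")
  auto <- per_class(config$autofluorescence, classes, "autofluorescence")

  barrels <- panel$barrels
  d_term <- config$dye_concentration / barrels$dye_affinity
  d_term[barrels$is_control] <- 0
  theta0 <- ifelse(d_term > 0, d_term / (1 + d_term), 0)
  # theta for each barrel x class at the configured challenge concentration
  theta_with <- matrix(0, n_panel, length(classes),
                       dimnames = list(barrels$barrel_id, classes))
  for (ci in seq_along(classes)) {
    comp <- (conc[ci] / panel$affinity[, classes[ci]])^config$hill
    theta_with[, ci] <- ifelse(d_term > 0, d_term / (1 + d_term + comp), 0)
  }

  samples <- tibble::tibble(
    class_label = rep(classes, each = config$n_samples_per_class),
    sample_id = sprintf("%s_s%02d", .data$class_label,
                        rep(seq_len(config$n_samples_per_class), length(classes)))
  )

  blocks <- tidyr::expand_grid(
    sample_id = samples$sample_id,
    replicate = seq_len(config$n_technical_reps)
  ) |>
    dplyr::left_join(samples, by = "sample_id") |>
    dplyr::arrange(.data$sample_id, .data$replicate)
  blocks$plate <- (seq_len(nrow(blocks)) - 1L) %/% 4L + 1L
  blocks$block <- (seq_len(nrow(blocks)) - 1L) %% 4L + 5L
  n_plates <- max(blocks$plate)
  n_dye_ref <- 4L
  # analyte references are replicated as far as the reference block allows
  n_analyte_ref <- max(1L, min(4L, (48L - n_dye_ref) %/% length(classes)))

  with_seed_if(config$seed, {
    gains <- exp(stats::rnorm(n_plates, 0, config$plate_gain_sd))

    plate_rows <- function(p) {
      g <- gains[p]
      pid <- sprintf("plate%02d", p)
      # Blocks 1-3: loaded-barrel references, one well per panel channel,
      # dispensed three times per plate.
      max_ref <- purrr::map_dfr(1:3, function(rep_block) tibble::tibble(
        plate_id = pid,
        well = well_coordinate(rep_block, seq_len(n_panel)),
        role = "max_ref",
        barrel_id = barrels$barrel_id,
        sample_id = NA_character_,
        class_label = NA_character_,
        replicate = rep_block,
        mean_intensity = as.numeric(g * (barrels$baseline_max * theta0 + config$dye_background)),
        noise_scale = as.numeric(g * pmax(barrels$baseline_max * theta0, config$dye_background))
      ))
      # Block 4: dye-alone wells then the autofluorescence wells per class.
      dye_ref <- tibble::tibble(
        plate_id = pid,
        well = well_coordinate(4L, seq_len(n_dye_ref)),
        role = "dye_ref",
        barrel_id = NA_character_,
        sample_id = NA_character_,
        class_label = NA_character_,
        replicate = seq_len(n_dye_ref),
        mean_intensity = g * config$dye_background,
        noise_scale = g * config$dye_background
      )
      analyte_ref <- tibble::tibble(
        plate_id = pid,
        well = well_coordinate(4L, n_dye_ref +
                                 seq_len(length(classes) * n_analyte_ref)),
        role = "analyte_ref",
        barrel_id = NA_character_,
        sample_id = NA_character_,
        class_label = rep(classes, each = n_analyte_ref),
        replicate = rep(seq_len(n_analyte_ref), length(classes)),
        mean_intensity = as.numeric(g * (config$dye_background +
                                           rep(auto, each = n_analyte_ref))),
        noise_scale = g * config$dye_background
      )
      # Blocks 5-8: one 48-well array block per sample replicate.
      pb <- blocks[blocks$plate == p, ]
      sample_rows <- purrr::pmap_dfr(pb, function(sample_id, replicate, class_label, plate, block) {
        # computed up front: tibble() evaluates sequentially, so the scalar
        # class_label argument must be used before the column shadows it
        mu <- as.numeric(g * (barrels$baseline_max * theta_with[, class_label] +
                                config$dye_background + auto[class_label]))
        ns <- as.numeric(g * pmax(barrels$baseline_max * theta0, config$dye_background))
        tibble::tibble(
          plate_id = pid,
          well = well_coordinate(block, seq_len(n_panel)),
          role = "sample",
          barrel_id = barrels$barrel_id,
          sample_id = sample_id,
          class_label = class_label,
          replicate = as.integer(replicate),
          mean_intensity = mu,
          noise_scale = ns
        )
      })
      dplyr::bind_rows(max_ref, dye_ref, analyte_ref, sample_rows)
    }

    readings <- purrr::map_dfr(seq_len(n_plates), plate_rows)
    n <- nrow(readings)
    noise <- stats::rnorm(n, 0, 1) * config$replicate_noise_sd * readings$noise_scale
    intensity <- readings$mean_intensity + noise

    fail <- stats::runif(n) < config$outlier_rate
    if (any(fail)) {
      up <- stats::runif(sum(fail)) < 0.5
      factor <- ifelse(up, config$outlier_magnitude, 1 / config$outlier_magnitude)
      intensity[fail] <- intensity[fail] * factor
    }
    readings$intensity <- as.numeric(intensity)
    outlier_wells <- readings[fail, c("plate_id", "well", "role", "barrel_id",
                                      "sample_id", "replicate")]
    readings$mean_intensity <- NULL
    readings$noise_scale <- NULL

    structure(
      list(
        readings = readings,
        truth_samples = samples[, c("sample_id", "class_label")],
        truth_barrels = barrels[, c("barrel_id", "informative")],
        outlier_wells = outlier_wells
      ),
      class = "bs_sim"
    )
  })
}

#' @export
print.bs_sim <- function(x, ...) {
  cat(sprintf(
    "<bs_sim> %d readings on %d plates; %d samples, %d distorted wells\n",
    nrow(x$readings), dplyr::n_distinct(x$readings$plate_id),
    nrow(x$truth_samples), nrow(x$outlier_wells)
  ))
  invisible(x)
}

#' Write a simulated dataset to CSV files
#'
#' Writes `readings.csv` (long-format raw wells), `truth_samples.csv` and
#' `truth_barrels.csv` into `dir`.
#'
#' @param sim A [simulate_raw_plates()] result.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "bs_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sim$readings, file.path(dir, "readings.csv"))
  readr::write_csv(sim$truth_samples, file.path(dir, "truth_samples.csv"))
  readr::write_csv(sim$truth_barrels, file.path(dir, "truth_barrels.csv"))
  invisible(dir)
}

#' Read a long-format raw readings table
#'
#' Reads a CSV of raw well readings, optionally renaming user columns to the
#' canonical schema (`plate_id`, `well`, `role`, `barrel_id`, `sample_id`,
#' `class_label`, `replicate`, `intensity`).
#'
#' @param path CSV file path.
#' @param col_map Optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(intensity = "RFU")`.
#' @return A tibble of raw readings.
#' @export
read_raw_readings <- function(path, col_map = NULL) {
  readings <- readr::read_csv(path, show_col_types = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(readings)) {
        abort(sprintf("Column '%s' not found in %s.", col_map[[canon]], path))
      }
      names(readings)[names(readings) == col_map[[canon]]] <- canon
    }
  }
  required <- c("plate_id", "well", "role", "barrel_id", "sample_id",
                "replicate", "intensity")
  missing <- setdiff(required, names(readings))
  if (length(missing) > 0) {
    abort(sprintf("Raw readings are missing column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  readings
}
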