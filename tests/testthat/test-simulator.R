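test_that("dye occupancy follows single-site competitive equilibrium", {
  panel <- sim_panel(n_barrels = 4, n_classes = 2, n_informative = 0, seed = 1)
  # force known affinities
  panel$barrels$dye_affinity[1] <- 1
  panel$affinity["B01", ] <- c(1, 1)

  # D/K_D = 1, no analyte: theta = 0.5
  expect_equal(dye_occupancy(panel, "B01", c(class1 = 0), dye_concentration = 1),
               0.5)
  # one analyte at c/K = 2 quarters the occupancy relative to the formula
  expect_equal(dye_occupancy(panel, "B01", c(class1 = 2), dye_concentration = 1),
               0.25)
  # saturating analyte displaces everything
  expect_lt(dye_occupancy(panel, "B01", c(class1 = 1e12), dye_concentration = 1),
            1e-10)
  # controls never bind dye
  expect_identical(dye_occupancy(panel, "BLANK", c(class1 = 0)), 0)
  expect_identical(dye_occupancy(panel, "CTRL", c(class1 = 100)), 0)
})

test_that("occupancy is within [0,1] and strictly decreasing in concentration", {
  panel <- sim_panel(n_barrels = 6, n_classes = 3, n_informative = 3, seed = 7)
  concs <- c(0, 0.1, 1, 5, 20, 100)
  for (b in c("B01", "B04", "B06")) {
    theta <- vapply(concs, function(cc)
      dye_occupancy(panel, b, c(class2 = cc)), numeric(1))
    expect_true(all(theta >= 0 & theta <= 1))
    expect_true(all(diff(theta) < 0))
  }
})

test_that("occupancy rejects unknown identifiers and negative concentrations", {
  panel <- sim_panel(n_barrels = 4, n_classes = 2, seed = 1)
  expect_error(dye_occupancy(panel, "nope", c(class1 = 1)), "Unknown barrel")
  expect_error(dye_occupancy(panel, "B01", c(gold = 1)), "Unknown analyte")
  expect_error(dye_occupancy(panel, "B01", c(class1 = -1)), "non-negative")
})

test_that("simulation is byte-identical under the same seed", {
  panel <- sim_panel(n_barrels = 8, n_classes = 2, n_informative = 3, seed = 3)
  cfg <- sim_config(n_samples_per_class = 4, n_technical_reps = 2, seed = 11)
  s1 <- simulate_raw_plates(panel, cfg)
  s2 <- simulate_raw_plates(panel, cfg)
  expect_identical(s1, s2)
  s3 <- simulate_raw_plates(panel, sim_config(n_samples_per_class = 4,
                                              n_technical_reps = 2, seed = 12))
  expect_false(identical(s1$readings$intensity, s3$readings$intensity))
})

test_that("noiseless simulation round-trips to the analytic occupancy ratio", {
  panel <- sim_panel(n_barrels = 10, n_classes = 3, n_informative = 5,
                     fold_change = 4, seed = 5)
  cfg <- sim_config(n_samples_per_class = 3, n_technical_reps = 2,
                    replicate_noise_sd = 0, plate_gain_sd = 0,
                    outlier_rate = 0, seed = 9)
  sim <- simulate_raw_plates(panel, cfg)
  fps <- suppressWarnings(preprocess_plates(sim$readings))

  d <- cfg$dye_concentration / panel$barrels$dye_affinity
  theta0 <- d / (1 + d)
  for (ci in seq_along(panel$classes)) {
    cl <- panel$classes[ci]
    expected <- vapply(seq_len(10), function(b) {
      th <- dye_occupancy(panel, panel$barrels$barrel_id[b],
                          setNames(cfg$concentration, cl),
                          dye_concentration = cfg$dye_concentration)
      th / theta0[b]
    }, numeric(1))
    got <- as.numeric(fps[fps$class_label == cl, panel$barrels$barrel_id[1:10]][1, ])
    expect_equal(got, expected, tolerance = 1e-9)
  }
  # control channels are degenerate references and are excluded, not emitted
  expect_false(any(c("BLANK", "CTRL") %in% names(fps)))
})

test_that("informative ground truth applies the fold-ratio rule to the affinities", {
  panel <- sim_panel(n_barrels = 12, n_classes = 4, n_informative = 5,
                     fold_change = 4, fold_threshold = 2, seed = 2)
  aff <- panel$affinity[!rownames(panel$affinity) %in% c("BLANK", "CTRL"), ]
  ratio <- apply(aff, 1, function(k) max(k) / min(k))
  expect_identical(unname(ratio >= 2),
                   panel$barrels$informative[!panel$barrels$is_control])
  expect_identical(sum(panel$barrels$informative), 5L)
  # planted barrels hit the fold change exactly; the rest are flat
  expect_equal(unname(sort(unique(round(ratio, 8)))), c(1, 4))
})

test_that("identical affinity vectors across classes give chance-level CV accuracy", {
  # Monte-Carlo over seeds: with no class signal, a real classifier cannot
  # beat guessing between two classes.
  accs <- vapply(1:20, function(s) {
    panel <- sim_panel(n_barrels = 6, n_classes = 2, n_informative = 0, seed = s)
    sim <- simulate_raw_plates(panel, sim_config(n_samples_per_class = 8,
                                                 n_technical_reps = 2, seed = s))
    fps <- suppressWarnings(preprocess_plates(sim$readings))
    cv <- nested_cv(fps, classifier_spec("linear_discriminant_analysis"),
                    k_outer = 3, seed = s)
    glance(cv)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 50), 12)
})

test_that("simulated plates carry the documented layout and roles", {
  panel <- sim_panel(n_barrels = 46, n_classes = 5, seed = 1)
  sim <- simulate_raw_plates(panel, sim_config(n_samples_per_class = 2,
                                               n_technical_reps = 1, seed = 1))
  r <- sim$readings
  expect_setequal(unique(r$role), c("sample", "max_ref", "dye_ref", "analyte_ref"))
  expect_true(all(grepl("^[A-P](1?[0-9]|2[0-4])$", r$well)))
  # three max_ref wells per channel per plate, refs on every plate
  per_plate <- dplyr::count(dplyr::filter(r, role == "max_ref"),
                            plate_id, barrel_id)
  expect_true(all(per_plate$n == 3))
  # analyte autofluorescence references replicated 4x per class per plate
  expect_true(all(table(r$plate_id[r$role == "analyte_ref"]) == 20))
  expect_true(all(table(r$plate_id[r$role == "dye_ref"]) == 4))
  # no well is used twice on a plate
  expect_false(any(duplicated(r[c("plate_id", "well")])))
})

test_that("write_sim and read_raw_readings round-trip the readings table", {
  panel <- sim_panel(n_barrels = 5, n_classes = 2, seed = 1)
  sim <- simulate_raw_plates(panel, sim_config(n_samples_per_class = 2,
                                               n_technical_reps = 1, seed = 1))
  dir <- withr::local_tempdir()
  write_sim(sim, dir)
  back <- read_raw_readings(file.path(dir, "readings.csv"))
  expect_equal(nrow(back), nrow(sim$readings))
  expect_equal(back$intensity, sim$readings$intensity, tolerance = 1e-12)
})
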