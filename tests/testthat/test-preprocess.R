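test_that("normalize_reading matches the reference formula and its anchors", {
  # direct substitution
  expect_equal(normalize_reading(50, 10, 90, 10), 0.5)
  # loaded barrel with no displacement anchors at 1
  expect_equal(normalize_reading(90, 10, 90, 10), 1)
  # dye-alone level anchors at 0
  expect_equal(normalize_reading(10, 10, 90, 10), 0)
  # autofluorescence above residual signal goes negative, no clipping
  expect_lt(normalize_reading(20, 40, 100, 10), 0)
  expect_gt(normalize_reading(120, 10, 90, 10), 1)
  expect_error(normalize_reading(5, 1, 7, 7), "Degenerate")
})

test_that("normalization is invariant to a common gain and covariant to offsets", {
  withr::with_seed(42, {
    for (i in 1:25) {
      x <- runif(1, 0, 200); min_af <- runif(1, 0, 50)
      max_ref <- runif(1, 60, 300); min_f <- runif(1, 0, 50)
      g <- runif(1, 0.1, 10)
      base <- normalize_reading(x, min_af, max_ref, min_f)
      expect_equal(normalize_reading(g * x, g * min_af, g * max_ref, g * min_f),
                   base, tolerance = 1e-12)
      # offset added to X and Min_AF only shifts by 0 (exact identity);
      # offset added to X only shifts by off/(Max - Min_F)
      off <- runif(1, -20, 20)
      expect_equal(normalize_reading(x + off, min_af + off, max_ref, min_f),
                   base, tolerance = 1e-12)
      expect_equal(normalize_reading(x + off, min_af, max_ref, min_f),
                   base + off / (max_ref - min_f), tolerance = 1e-12)
    }
  })
})

make_mini_readings <- function() {
  # one plate, two barrels, two samples of one analyte, two replicates
  tibble::tibble(
    plate_id = "p1",
    well = sprintf("A%d", 1:14),
    role = c("max_ref", "max_ref", "dye_ref", "analyte_ref",
             rep("sample", 10)),
    barrel_id = c("b1", "b2", NA, NA,
                  rep("b1", 4), rep("b2", 4), "b1", "b2"),
    sample_id = c(NA, NA, NA, NA, rep("s1", 8), "s2", "s2"),
    class_label = c(NA, NA, NA, "tea", rep("tea", 10)),
    replicate = c(1L, 1L, 1L, 1L, 1L, 2L, 3L, 4L, 1L, 2L, 3L, 4L, 1L, 1L),
    intensity = c(90, 190, 10, 15,
                  50, 60, 55, 1000, 105, 115, 110, 1000, 45, 100)
  )
}

test_that("plate normalization applies per-plate references by role", {
  rd <- make_mini_readings()
  norm <- normalize_plates(rd)
  # b1: (X - 15) / (90 - 10); b2: (X - 15) / (190 - 10)
  s1b1 <- sort(norm$value[norm$sample_id == "s1" & norm$barrel_id == "b1"])
  expect_equal(s1b1, sort((c(50, 60, 55, 1000) - 15) / 80))
  s2b2 <- norm$value[norm$sample_id == "s2" & norm$barrel_id == "b2"]
  expect_equal(s2b2, (100 - 15) / 180)
})

test_that("replicate aggregation takes the per-barrel median and is order-invariant", {
  rd <- make_mini_readings()
  norm <- normalize_plates(rd)
  fps <- aggregate_replicates(norm)
  # s1 b1 reps: (50,60,55,1000 - 15)/80 -> median of (35,45,40,985)/80
  expect_equal(fps$b1[fps$sample_id == "s1"], median(c(35, 45, 40, 985) / 80))
  expect_equal(fps$n_reps_aggregated[fps$sample_id == "s1"], 4L)
  # single replicate passes through
  expect_equal(fps$b2[fps$sample_id == "s2"], 85 / 180)

  shuffled <- withr::with_seed(1, norm[sample.int(nrow(norm)), ])
  fps2 <- aggregate_replicates(shuffled)
  expect_equal(fps2[order(fps2$sample_id), ], fps[order(fps$sample_id), ],
               ignore_attr = TRUE)
})

test_that("median absorbs a gross replicate error", {
  expect_equal(median(c(0.2, 0.4, 0.6, 100.0)), 0.5)
  rd <- make_mini_readings()
  fps <- aggregate_replicates(normalize_plates(rd))
  # the 1000-intensity replicate does not drag the median far
  expect_lt(fps$b1[fps$sample_id == "s1"], 1)
})

test_that("aggregation is idempotent on an already-aggregated fingerprint", {
  rd <- make_mini_readings()
  fps <- aggregate_replicates(normalize_plates(rd))
  long <- tidyr::pivot_longer(fps, cols = c("b1", "b2"),
                              names_to = "barrel_id", values_to = "value")
  again <- aggregate_replicates(long)
  expect_equal(again$b1, fps$b1)
  expect_equal(again$b2, fps$b2)
})

test_that("degenerate and missing references are reported, incomplete samples dropped", {
  rd <- make_mini_readings()
  # collapse b2's reference range on the plate
  rd$intensity[rd$role == "max_ref" & rd$barrel_id == "b2"] <- 10
  norm <- normalize_plates(rd)
  rep <- preprocess_report(norm)
  expect_true("b2" %in% rep$degenerate_references$barrel_id)
  expect_false("b2" %in% norm$barrel_id)
  # s1/s2 now lack barrel b2 entirely -> fingerprints complete on b1 only
  fps <- aggregate_replicates(norm)
  expect_identical(names(fps)[4], "b1")

  # a sample reading whose analyte has no reference is dropped and reported
  rd2 <- make_mini_readings()
  rd2$class_label[rd2$role == "analyte_ref"] <- "coffee"
  expect_warning(norm2 <- normalize_plates(rd2), "no matching reference")
  expect_equal(nrow(norm2), 0)
})

test_that("global reference scope pools references across plates", {
  rd <- make_mini_readings()
  rd2 <- make_mini_readings()
  rd2$plate_id <- "p2"
  rd2$intensity[rd2$role == "max_ref"] <- c(110, 210) # different plate gain
  both <- dplyr::bind_rows(rd, rd2)
  per_plate <- normalize_plates(both, ref_scope = "plate")
  pooled <- normalize_plates(both, ref_scope = "global")
  # per-plate scope uses each plate's own Max; pooling uses the median of both
  v_plate <- per_plate$value[per_plate$plate_id == "p2" &
                               per_plate$sample_id == "s2" &
                               per_plate$barrel_id == "b1"]
  v_pool <- pooled$value[pooled$plate_id == "p2" &
                           pooled$sample_id == "s2" &
                           pooled$barrel_id == "b1"]
  expect_equal(v_plate, (45 - 15) / 100)
  expect_equal(v_pool, (45 - 15) / 90)
})
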