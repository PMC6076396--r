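test_that("default panel has four accessions with a dynamics-only pair", {
  panel <- default_accession_panel()
  expect_length(panel, 4)
  a <- panel[[1]]; b <- panel[[2]]
  # identical static appearance
  expect_identical(a$leaf_aspect, b$leaf_aspect)
  expect_identical(a$hue_center, b$hue_center)
  expect_identical(a$hue_jitter, b$hue_jitter)
  expect_identical(a$rotation_phyllotaxy, b$rotation_phyllotaxy)
  # different temporal parameters
  expect_false(a$expansion_rate == b$expansion_rate)
  expect_false(identical(a$leaf_add_schedule(0:30), b$leaf_add_schedule(0:30)))
  # a static parameter differs elsewhere in the panel
  expect_false(panel[[1]]$hue_center == panel[[3]]$hue_center)
})

test_that("accession_spec validates its invariants", {
  bad_schedule <- function(day) 5 - day
  expect_error(accession_spec("x", bad_schedule, 2, 2, 90), "non-decreasing")
  expect_error(accession_spec("x", leaf_schedule(2, 8), -1, 2, 90), "expansion_rate")
  expect_error(accession_spec("x", leaf_schedule(2, 8), 2, 0.5, 90), "leaf_aspect")
})

test_that("render_frame is deterministic and grows monotonically", {
  spec <- default_accession_panel()[[1]]
  r1 <- render_frame(spec, day = 12, canvas_size = 128, seed = 5)
  r2 <- render_frame(spec, day = 12, canvas_size = 128, seed = 5)
  expect_identical(r1, r2)
  expect_equal(dim(r1$frame), c(128, 128, 3))
  expect_true(all(r1$frame >= 0 & r1$frame <= 1))
  # empty plant before the first leaf
  r0 <- render_frame(spec, day = 0, canvas_size = 128, seed = 5)
  expect_false(any(r0$mask))
  # growth: later mask strictly larger for a monotone schedule
  r5 <- render_frame(spec, day = 5, canvas_size = 128, seed = 5)
  r20 <- render_frame(spec, day = 20, canvas_size = 128, seed = 5)
  expect_gt(sum(r20$mask), sum(r5$mask))
  # mask marks exactly the rendered foreground
  expect_true(all(dim(r1$mask) == c(128, 128)))
})

test_that("render_frame rejects canvases that cannot hold the plant", {
  expect_error(render_frame(default_accession_panel()[[1]], 5, canvas_size = 32),
               ">= 64")
  big <- accession_spec("big", leaf_schedule(1, 10), expansion_rate = 8,
                        leaf_aspect = 2, hue_center = 95, leaf_max_length = 200)
  expect_error(render_frame(big, day = 21, canvas_size = 64, seed = 1),
               "canvas too small")
})

test_that("generate_sequences produces labelled fixed-length sequences", {
  ds <- small_dataset()
  expect_length(ds$sequences, 8)
  expect_true(all(vapply(ds$sequences, function(s) length(s$frames), integer(1)) == 12))
  expect_equal(sort(unique(ds$manifest$genotype_index)), 0:3)
  # default sequence length is 22 frames
  one <- generate_sequences(dynamics_panel(), 1, canvas_size = 128, seed = 2)
  expect_true(all(vapply(one$sequences, function(s) length(s$frames), integer(1)) == 22))
  # germination offsets differ across replicates
  expect_gt(length(unique(small_dataset()$manifest$germination_offset)), 1)
})

test_that("truth-mask area is non-decreasing in day for monotone schedules", {
  for (sq in small_dataset()$sequences) {
    areas <- vapply(sq$truth_masks, sum, numeric(1))
    expect_true(all(diff(areas) >= 0))
  }
})

test_that("datasets round-trip through disk byte-for-byte reproducibly", {
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  m1 <- generate_dataset(dynamics_panel(), 2, d1, n_days = 5, canvas_size = 64, seed = 9)
  m2 <- generate_dataset(dynamics_panel(), 2, d2, n_days = 5, canvas_size = 64, seed = 9)
  expect_equal(m1, m2)
  expect_equal(nrow(m1), 2 * 2 * 5)
  f1 <- file.path(d1, m1$frame_path); f2 <- file.path(d2, m2$frame_path)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  back <- read_dataset(d1)
  expect_length(back$sequences, 4)
  sq <- back$sequences[[1]]
  expect_s3_class(sq, "plant_sequence")
  expect_length(sq$truth_masks, 5)
})

test_that("plant_sequence enforces its invariants", {
  f <- list(array(0, c(8, 8, 3)), array(0, c(8, 8, 3)))
  expect_error(plant_sequence("p", 0, f, day_index = c(1)), "")
  expect_error(plant_sequence("p", 0, f, day_index = c(2, 2)), "strictly increasing")
  expect_error(plant_sequence("p", 0, f, day_index = 1:2,
                              truth_masks = list(matrix(FALSE, 4, 4),
                                                 matrix(FALSE, 8, 8))),
               "spatial size")
  ok <- plant_sequence("p", 0, f, day_index = 1:2)
  expect_s3_class(ok, "plant_sequence")
})
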