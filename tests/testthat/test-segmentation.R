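test_that("otsu_threshold separates a two-delta histogram and handles degeneracy", {
  counts <- numeric(256)
  counts[10 + 1] <- 500; counts[200 + 1] <- 500
  t <- otsu_threshold(counts)
  expect_gte(t, 10); expect_lt(t, 200)
  # single occupied bin returns that level
  single <- numeric(256); single[77 + 1] <- 42
  expect_equal(otsu_threshold(single), 77)
  expect_error(otsu_threshold(numeric(256)), "empty histogram")
  expect_error(otsu_threshold(numeric(10)), "256")
})

test_that("otsu_threshold matches the exhaustive search oracle", {
  for (s in 1:25) {
    counts <- random_histogram(s)
    expect_equal(otsu_threshold(counts), otsu_bruteforce(counts), info = s)
  }
})

test_that("channel_trinary_mask builds core and dilation ring", {
  ch <- matrix(100, 64, 64)
  ch[30, 30] <- 0                     # single dark pixel, strong contrast
  tm <- channel_trinary_mask(ch, "low")
  expect_equal(tm[30, 30], 2L)
  ring <- tm[28:32, 28:32]
  expect_equal(sum(tm == 2L), 1)
  # radius-1 disc at 64 px: the 8-neighbourhood is the ring
  expect_equal(sum(tm == 1L), 8)
  expect_true(all(tm[29:31, 29:31][-5] == 1L))
  expect_equal(sum(tm == 0L), 64 * 64 - 9)
  # high polarity flips the foreground side
  th <- channel_trinary_mask(-ch, "high")
  expect_equal(th[30, 30], 2L)
  # constant channel carries no evidence
  expect_true(all(channel_trinary_mask(matrix(5, 16, 16), "low") == 0L))
  # weak-contrast split is gated to all-background
  weak <- matrix(rep(c(0, 4), each = 128), 16, 16)
  expect_true(all(channel_trinary_mask(weak, "low", min_contrast = 8) == 0L))
})

test_that("combine_masks reproduces the printed mapping exactly", {
  expected <- matrix(c(DEF_BG,  PROB_BG, PROB_FG,
                       PROB_BG, PROB_BG, PROB_FG,
                       PROB_FG, PROB_FG, DEF_FG), 3, 3, byrow = TRUE)
  for (a in 0:2) for (b in 0:2) {
    got <- combine_masks(matrix(a, 1, 1), matrix(b, 1, 1))
    expect_equal(got[1, 1], expected[a + 1, b + 1], info = paste(a, b))
  }
  # symmetric in its arguments, as the printed table is
  set.seed(4)
  ma <- matrix(sample(0:2, 100, TRUE), 10)
  mb <- matrix(sample(0:2, 100, TRUE), 10)
  expect_identical(combine_masks(ma, mb), combine_masks(mb, ma))
  expect_error(combine_masks(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
  expect_error(combine_masks(matrix(5, 1, 1), matrix(0, 1, 1)), "values")
})

test_that("grabcut_refine recovers a high-contrast disc and honours hard seeds", {
  set.seed(8)
  s <- 96
  img <- array(0, c(s, s, 3))
  img[, , 1] <- 0.45 + 0.05 * matrix(runif(s * s), s)
  img[, , 2] <- 0.33 + 0.04 * matrix(runif(s * s), s)
  img[, , 3] <- 0.22 + 0.03 * matrix(runif(s * s), s)
  truth <- matrix(FALSE, s, s)
  for (r in 1:s) for (c in 1:s) if ((r - 48)^2 + (c - 48)^2 <= 22^2) truth[r, c] <- TRUE
  img[, , 1][truth] <- 0.15; img[, , 2][truth] <- 0.55; img[, , 3][truth] <- 0.12
  seed_mask <- matrix(PROB_BG, s, s)
  inner <- matrix(FALSE, s, s)
  for (r in 1:s) for (c in 1:s) if ((r - 48)^2 + (c - 48)^2 <= 12^2) inner[r, c] <- TRUE
  seed_mask[inner] <- DEF_FG
  outer_ring <- matrix(FALSE, s, s)
  for (r in 1:s) for (c in 1:s) if ((r - 48)^2 + (c - 48)^2 >= 40^2) outer_ring[r, c] <- TRUE
  seed_mask[outer_ring] <- DEF_BG
  seed_mask[truth & !inner] <- PROB_FG
  m <- grabcut_refine(img, seed_mask)
  expect_type(m, "logical")
  expect_equal(dim(m), c(s, s))
  expect_gte(mask_iou(m, truth), 0.9)
  # hard constraints never flip
  expect_true(all(m[seed_mask == DEF_FG]))
  expect_false(any(m[seed_mask == DEF_BG]))
  expect_error(grabcut_refine(img, matrix(DEF_BG, s, s)), "no foreground")
})

test_that("segment_plant recovers synthetic rosettes and returns empty masks pre-germination", {
  r <- easy_frame(day = 15)
  m <- segment_plant(r$frame)
  expect_gte(mask_iou(m, r$mask), 0.8)
  r0 <- render_frame(easy_accession_panel()[[1]], day = 0, canvas_size = 128, seed = 11)
  expect_false(any(segment_plant(r0$frame)))
  expect_error(segment_plant(matrix(0, 8, 8)), "RGB")
})

test_that("segmented area is non-decreasing along a growth sequence (10% tolerance)", {
  sq <- small_dataset()$sequences[[1]]
  areas <- vapply(sq$frames[seq(2, 12, 2)], function(f) sum(segment_plant(f)), numeric(1))
  ok <- areas[-1] >= 0.9 * areas[-length(areas)]
  expect_true(all(ok))
})

test_that("color_correct fits and inverts an affine distortion", {
  set.seed(3)
  img <- array(runif(16 * 16 * 3, 0, 0.5), c(16, 16, 3))
  ref <- matrix(runif(18, 0.1, 0.9), 6, 3)
  expect_equal(color_correct(img, ref, ref), img, tolerance = 1e-12)
  # observed channels halved: transform must recover the doubling
  obs <- ref / 2
  corrected <- color_correct(img / 2, obs, ref)
  expect_equal(corrected, img, tolerance = 1e-8)
  expect_error(color_correct(img, ref[1:3, ], ref[1:3, ]), ">= 4")
  rank_def <- matrix(rep(c(0.2, 0.3, 0.4), each = 5), 5, 3)
  expect_error(color_correct(img, rank_def, ref[1:5, ]), "rank")
})
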