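test_that("color_stats summarises foreground pixels only", {
  img <- array(0, c(8, 8, 3))
  img[, , 1] <- 100 / 255; img[, , 2] <- 150 / 255; img[, , 3] <- 50 / 255
  full <- matrix(TRUE, 8, 8)
  cs <- color_stats(img, full)
  expect_length(cs, 12)
  expect_equal(unname(cs[1:9]), rep(c(100, 150, 50) / 255, 3))
  # two-pixel mean
  img2 <- array(0, c(1, 2, 3))
  img2[1, 2, ] <- c(200, 100, 50) / 255
  cs2 <- color_stats(img2, matrix(TRUE, 1, 2))
  expect_equal(unname(cs2[1:3]), c(100, 50, 25) / 255)
  # HSV of a pure red region matches the reference conversion
  red <- array(0, c(4, 4, 3)); red[, , 1] <- 1
  csr <- color_stats(red, matrix(TRUE, 4, 4))
  expect_equal(unname(csr[10:12]), unname(drop(rgb2hsv(255, 0, 0))))
  expect_error(color_stats(img, matrix(FALSE, 8, 8)), "empty mask")
})

test_that("shape_stats matches analytic geometry of simple regions", {
  sq <- matrix(FALSE, 64, 64); sq[21:40, 21:40] <- TRUE
  s <- shape_stats(sq)
  expect_length(s, 8)
  expect_equal(unname(s["area"]), 400)
  expect_equal(unname(s["perimeter"]), 76)  # traced boundary of pixel centres
  expect_equal(unname(s["roundness"]), 400 / 76)
  expect_equal(unname(s["compactness"]), 1, tolerance = 1e-12)
  expect_equal(unname(s["extent"]), 1)
  expect_equal(unname(s["eccentricity"]), 1, tolerance = 1e-10)
  rect <- matrix(FALSE, 64, 96); rect[21:40, 21:60] <- TRUE
  expect_equal(unname(shape_stats(rect)["eccentricity"]), 2, tolerance = 1e-10)
  # conventional roundness flag
  expect_equal(unname(shape_stats(sq, conventional_roundness = TRUE)["roundness"]),
               4 * pi * 400 / 76^2)
  line <- matrix(FALSE, 32, 32); line[5, 3:20] <- TRUE
  expect_error(shape_stats(line), "degenerate")
  expect_error(shape_stats(matrix(FALSE, 8, 8)), ">= 3")
})

test_that("compactness and extent are bounded for arbitrary regions", {
  for (s in 1:10) {
    m <- random_blob(s)
    st <- shape_stats(m)
    expect_lte(st[["compactness"]], 1.05)
    expect_lte(st[["extent"]], 1)
    expect_gte(st[["eccentricity"]], 1)
    expect_true(all(is.finite(st)))
  }
})

test_that("fourier descriptors have the printed layout and invariances", {
  disc <- matrix(FALSE, 101, 101)
  for (r in 1:101) for (c in 1:101)
    if ((r - 51)^2 + (c - 51)^2 <= 900) disc[r, c] <- TRUE
  fd <- fourier_descriptors(disc)
  expect_length(fd, 1024)
  # translation invariance: DC removal kills integer shifts
  m1 <- matrix(FALSE, 120, 120); m1[6:106, 6:106] <- disc
  m2 <- matrix(FALSE, 120, 120); m2[11:111, 13:113] <- disc
  expect_lt(max(abs(fourier_descriptors(m1) - fourier_descriptors(m2))), 1e-6)
  # a circle concentrates its spectrum at the +-1 harmonics
  f <- complex(real = fd[1:512], imaginary = fd[513:1024])
  energy <- Mod(f)^2
  expect_gt((energy[2] + energy[512]) / sum(energy), 0.95)
  expect_error(fourier_descriptors(matrix(FALSE, 8, 8)), "empty mask")
})

test_that("glcm features match hand-enumerated co-occurrence counts", {
  # constant region: single-cell GLCM
  g0 <- glcm_features(matrix(0.5, 10, 10), matrix(TRUE, 10, 10))
  expect_length(g0, 12)
  expect_equal(unname(g0[c("Energy_0", "Energy_45", "Energy_90", "Energy_135")]),
               rep(1, 4))
  expect_equal(unname(g0[c("Contrast_0", "Contrast_45", "Contrast_90", "Contrast_135")]),
               rep(0, 4))
  expect_equal(unname(g0[c("Homogeneity_0", "Homogeneity_45", "Homogeneity_90",
                           "Homogeneity_135")]), rep(1, 4))
  # checkerboard at 0 degrees: p(0,1) = p(1,0) = 0.5
  cb <- outer(1:64, 1:64, function(r, c) (r + c) %% 2)
  g <- glcm_features(cb, matrix(TRUE, 64, 64), n_levels = 2)
  expect_equal(unname(g["Energy_0"]), 0.5)
  expect_equal(unname(g["Contrast_0"]), 1)
  expect_equal(unname(g["Homogeneity_0"]), 0.5)
  # diagonal neighbours share parity
  expect_equal(unname(g["Contrast_45"]), 0)
  expect_error(glcm_features(cb, matrix(FALSE, 64, 64)), ">= 2")
})

test_that("glcm is invariant to grey shifts and permutes under rotation", {
  set.seed(12)
  gr <- matrix(runif(48 * 48), 48, 48)
  mk <- random_blob(3)
  g1 <- glcm_features(gr, mk)
  # adding a constant shifts the quantisation range identically
  expect_equal(glcm_features(gr + 0.3, mk), g1)
  # rotating by 90 degrees swaps the 0/90 and 45/135 direction blocks
  g2 <- glcm_features(rotate90(gr), rotate90(mk))
  expect_equal(unname(g2[7:9]), unname(g1[1:3]))
  expect_equal(unname(g2[1:3]), unname(g1[7:9]))
  expect_equal(unname(g2[10:12]), unname(g1[4:6]))
})

test_that("extract_features concatenates the documented 1056-element layout", {
  r <- easy_frame(day = 12)
  v <- extract_features(r$frame, r$mask)
  expect_length(v, 1056)
  expect_true(all(is.finite(v)))
  expect_identical(v, extract_features(r$frame, r$mask))
  expect_named(v)
  expect_equal(sum(startsWith(names(v), "color_")), 12)
  expect_equal(sum(startsWith(names(v), "shape_")), 8)
  expect_equal(sum(startsWith(names(v), "fourier_")), 1024)
  expect_equal(sum(startsWith(names(v), "glcm_")), 12)
  expect_error(extract_features(r$frame, matrix(FALSE, 128, 128)), "empty mask")
})

test_that("feature tables encode absent plants as zero rows", {
  ds <- small_dataset()
  tbl <- extract_features_table(ds$sequences[1:2])
  expect_equal(nrow(tbl), 24)
  expect_equal(ncol(tbl), 3 + 1056)
  empty_rows <- vapply(ds$sequences[[1]]$truth_masks, sum, numeric(1)) < 16
  if (any(empty_rows)) {
    sub <- tbl[tbl$plant_id == ds$sequences[[1]]$plant_id, ]
    featcols <- as.matrix(sub[empty_rows, -(1:3)])
    expect_true(all(featcols == 0))
  }
  expect_true(all(is.finite(as.matrix(tbl[, -(1:3)]))))
})

test_that("every feature is finite across a synthetic fixture set", {
  ds <- small_dataset()
  tbl <- extract_features_table(ds$sequences)
  expect_true(all(is.finite(as.matrix(tbl[, -(1:3)]))))
})
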