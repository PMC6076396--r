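test_that("rotation augmentation quadruples the set and preserves content", {
  set.seed(2)
  frames <- lapply(1:10, function(i) array(runif(16 * 16 * 3), c(16, 16, 3)))
  labels <- sample(0:3, 10, replace = TRUE)
  aug <- augment_rotations(frames, labels)
  expect_length(aug$frames, 40)
  expect_equal(aug$labels, rep(labels, each = 4))
  # four quarter turns compose to the identity
  expect_equal(rotate90(frames[[1]], 4L), frames[[1]])
  expect_equal(rotate90(rotate90(frames[[1]], 3L)), frames[[1]])
  # rotation is a pixel permutation: area preserved
  m <- random_blob(5, side = 32)
  for (k in 1:3) expect_equal(sum(rotate90(m, k)), sum(m))
  ns <- list(array(0, c(8, 10, 3)))
  expect_error(augment_rotations(ns, 0), "square")
})

test_that("area sub-classes split each genotype into balanced quantile bins", {
  set.seed(7)
  areas <- runif(100, 10, 1000)
  sub <- assign_area_subclasses(areas, rep(0L, 100))
  expect_equal(as.integer(table(sub$area_bin)), rep(20L, 5))
  expect_equal(sub$flat_label, sub$area_bin)
  # per-genotype partition: bin sizes sum to the genotype count
  areas2 <- runif(37); gts <- rep(c(0L, 1L), c(20, 17))
  sub2 <- assign_area_subclasses(areas2, gts)
  expect_equal(nrow(sub2), 37)
  expect_equal(as.integer(tapply(sub2$area_bin, sub2$genotype, length)), c(20L, 17L))
  expect_true(all(sub2$flat_label == sub2$genotype * 5L + sub2$area_bin))
  # ties fall into the lowest bin
  sub3 <- assign_area_subclasses(rep(42, 12), rep(0L, 12))
  expect_true(all(sub3$area_bin == 0L))
  # too few samples: reduced bins with a warning
  expect_warning(sub4 <- assign_area_subclasses(c(1, 2, 3), rep(0L, 3)), "bins")
  expect_lte(max(sub4$area_bin), 2)
})

test_that("cnn backprop matches finite differences", {
  cfg <- cnn_config(n_outputs = 3, input_size = 8, feature_dim = 5,
                    conv_widths = c(2, 3, 4), epochs = 1, seed = 3)
  params <- local({ set.seed(9); phenoseq:::init_cnn_params(cfg) })
  B <- 3
  set.seed(31)
  x <- array(rnorm(8 * 8 * B * 3), c(8, 8, B, 3))
  y <- c(1, 2, 3)
  lossfun <- function(p) {
    fw <- phenoseq:::cnn_forward(p, x)
    pr <- phenoseq:::softmax_rows(fw$logits)
    mean(-log(pr[cbind(seq_len(B), y)]))
  }
  fw <- phenoseq:::cnn_forward(params, x)
  pr <- phenoseq:::softmax_rows(fw$logits)
  dlog <- pr; dlog[cbind(seq_len(B), y)] <- dlog[cbind(seq_len(B), y)] - 1
  dlog <- dlog / B
  g <- phenoseq:::cnn_backward(params, fw$cache, dlog)
  eps <- 1e-5
  for (nm in names(params)) {
    ii <- sample(length(params[[nm]]), min(4, length(params[[nm]])))
    for (i in ii) {
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
      num <- (lossfun(p1) - lossfun(p2)) / (2 * eps)
      expect_lt(abs(num - g[[nm]][i]) / max(abs(num) + abs(g[[nm]][i]), 1e-6),
                1e-4)
    }
  }
})

test_that("train_cnn reduces the loss, is reproducible, and sizes its head as L x bins", {
  ds <- small_dataset()
  frames <- unlist(lapply(ds$sequences, `[[`, "frames"), recursive = FALSE)
  areas <- unlist(lapply(ds$sequences, function(s) vapply(s$truth_masks, sum, numeric(1))))
  gts <- unlist(lapply(ds$sequences, function(s) rep(s$genotype, 12)))
  sub <- assign_area_subclasses(areas, gts)
  cfg <- cnn_config(n_outputs = 20, input_size = 16, epochs = 3, seed = 4,
                    conv_widths = c(4, 8, 16), feature_dim = 16)
  m <- train_cnn(frames, sub$flat_label, cfg)
  expect_lt(tail(m$loss_history, 1), m$loss_history[1])
  expect_equal(ncol(m$params$W5), 20)  # 4 genotypes x 5 bins
  m2 <- train_cnn(frames, sub$flat_label, cfg)
  expect_identical(tail(m$loss_history, 1), tail(m2$loss_history, 1))
  expect_error(train_cnn(frames, rep(99L, length(frames)), cfg), "0..n_outputs")
  # deterministic features of the right width; distinct genotypes differ
  f1 <- extract_deep_features(m, frames[1:2])
  expect_equal(dim(f1), c(2, 16))
  expect_identical(f1, extract_deep_features(m, frames[1:2]))
  late_a <- ds$sequences[[1]]$frames[[12]]   # genotype 0, fully grown
  late_b <- ds$sequences[[7]]$frames[[12]]   # genotype 3
  fd <- extract_deep_features(m, list(late_a, late_b))
  expect_gt(sum((fd[1, ] - fd[2, ])^2), 0)
})

test_that("collapse_subclass_probs sums each genotype's bins", {
  p <- matrix(1 / 10, 3, 10)
  g <- collapse_subclass_probs(p, n_bins = 5)
  expect_equal(dim(g), c(3, 2))
  expect_true(all(abs(g - 0.5) < 1e-12))
  p2 <- matrix(0, 1, 10); p2[1, 7] <- 1
  expect_equal(collapse_subclass_probs(p2, 5)[1, ], c(0, 1))
})

test_that("compiled im2col and pooling match their plain-R counterparts", {
  set.seed(6)
  S <- 8L; B <- 3L; C <- 2L
  x <- array(rnorm(S * S * B * C), c(S, S, B, C))
  idx <- phenoseq:::make_conv_idx(S, C, B)
  colR <- phenoseq:::pad1(x)[idx]
  dim(colR) <- c(S * S * B, 9L * C)
  expect_equal(phenoseq:::im2col3(x, S, B, C), colR, ignore_attr = TRUE)
  mp <- phenoseq:::maxpool2(x, S, B, C)
  # every pooled value is the max of its 2x2 block
  for (k in 1:20) {
    r <- sample(S / 2, 1); cc <- sample(S / 2, 1)
    b <- sample(B, 1); f <- sample(C, 1)
    expect_equal(mp$out[r, cc, b, f],
                 max(x[(2 * r - 1):(2 * r), (2 * cc - 1):(2 * cc), b, f]))
  }
})
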