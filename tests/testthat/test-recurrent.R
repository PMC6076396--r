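test_that("rnn_step follows the printed recurrence in closed form", {
  # zero parameters: h = tanh(0) = 0, y = sigmoid(0) = 0.5
  p <- structure(list(W_xh = matrix(0, 3, 2), W_hh = matrix(0, 3, 3),
                      W_hy = matrix(0, 2, 3), b = numeric(3)),
                 class = "rnn_params")
  st <- rnn_step(p, c(1, -2), c(0.3, 0.1, -0.5))
  expect_equal(st$h, rep(0, 3))
  expect_equal(st$y, rep(0.5, 2))
  # scalar case: h = tanh(W_xh x + W_hh h_prev) = tanh(1.1)
  ps <- structure(list(W_xh = matrix(1, 1, 1), W_hh = matrix(0.5, 1, 1),
                       W_hy = matrix(2, 1, 1), b = 0), class = "rnn_params")
  st2 <- rnn_step(ps, 1, 0.2)
  expect_equal(st2$h, tanh(1.1))
  expect_equal(st2$y, 1 / (1 + exp(-2 * tanh(1.1))))
  expect_error(rnn_step(ps, c(1, 2), 0.2), "dimension")
})

test_that("lstm_step follows the printed gate equations in closed form", {
  zero <- function(H, D) structure(
    list(W_xi = matrix(0, H, D), W_hi = matrix(0, H, H), b_i = numeric(H),
         W_xf = matrix(0, H, D), W_hf = matrix(0, H, H), b_f = numeric(H),
         W_xo = matrix(0, H, D), W_ho = matrix(0, H, H), b_o = numeric(H),
         W_xc = matrix(0, H, D), W_hc = matrix(0, H, H), b_c = numeric(H)),
    class = "lstm_params")
  p <- zero(2, 3)
  st <- lstm_step(p, c(1, 2, 3), c(0, 0), c(0, 0))
  expect_equal(st$h, c(0, 0))
  expect_equal(st$c, c(0, 0))
  # zero parameters with memory: every gate is 0.5, candidate 0
  st2 <- lstm_step(p, c(1, 2, 3), c(0, 0), c(2, 2))
  expect_equal(st2$c, c(1, 1))                 # 0.5 * 2
  expect_equal(st2$h, rep(0.5 * tanh(1), 2))
  expect_true(all(st2$i > 0 & st2$i < 1))
  expect_true(all(abs(st2$h) < 1))
  expect_error(lstm_step(p, c(1, 2), c(0, 0), c(0, 0)), "dimension")
})

test_that("step implementations match the scalar brute-force oracles", {
  set.seed(77)
  for (rep in 1:30) {
    D <- sample(1:4, 1); H <- sample(1:4, 1); O <- sample(1:3, 1)
    rp <- rnn_params(D, H, O, init = 1)
    x <- rnorm(D); h0 <- rnorm(H)
    got <- rnn_step(rp, x, h0)
    want <- rnn_step_oracle(rp, x, h0)
    expect_lt(max(abs(got$h - want$h)), 1e-10)
    expect_lt(max(abs(got$y - want$y)), 1e-10)
    lp <- lstm_params(D, H, init = 1)
    c0 <- rnorm(H)
    gotl <- lstm_step(lp, x, h0, c0)
    wantl <- lstm_step_oracle(lp, x, h0, c0)
    expect_lt(max(abs(gotl$h - wantl$h)), 1e-10)
    expect_lt(max(abs(gotl$c - wantl$c)), 1e-10)
  }
})

test_that("a saturated-off forget gate erases the memory dependence", {
  set.seed(5)
  lp <- lstm_params(2, 3, init = 0.5)
  lp$b_f <- rep(-50, 3)                       # forget gate -> 0
  x <- rnorm(2); h0 <- rnorm(3)
  a <- lstm_step(lp, x, h0, c_prev = rnorm(3))
  b <- lstm_step(lp, x, h0, c_prev = rnorm(3) * 100)
  expect_lt(max(abs(a$c - b$c)), 1e-10)
  expect_lt(max(abs(a$h - b$h)), 1e-10)
})

test_that("the batched classifier layer agrees with iterated lstm_step", {
  set.seed(13)
  D <- 3; H <- 4; TT <- 6
  lay <- local({ set.seed(2); phenoseq:::init_lstm_layer(D, H) })
  idx <- function(k) ((k - 1) * H + 1):(k * H)
  lp <- structure(list(
    W_xi = t(lay$Wx[, idx(1)]), W_hi = t(lay$Wh[, idx(1)]), b_i = lay$b[idx(1)],
    W_xf = t(lay$Wx[, idx(2)]), W_hf = t(lay$Wh[, idx(2)]), b_f = lay$b[idx(2)],
    W_xo = t(lay$Wx[, idx(3)]), W_ho = t(lay$Wh[, idx(3)]), b_o = lay$b[idx(3)],
    W_xc = t(lay$Wx[, idx(4)]), W_hc = t(lay$Wh[, idx(4)]), b_c = lay$b[idx(4)]),
    class = "lstm_params")
  xs <- matrix(rnorm(TT * D), TT, D)
  fwd <- phenoseq:::lstm_layer_forward(lay, phenoseq:::stack_sequences(list(xs)))
  h <- numeric(H); cc <- numeric(H)
  for (t in seq_len(TT)) {
    st <- lstm_step(lp, xs[t, ], h, cc)
    h <- st$h; cc <- st$c
    expect_lt(max(abs(h - fwd$hs[t, 1, ])), 1e-12)
  }
})

test_that("lstm classifier backprop matches finite differences", {
  set.seed(7)
  H <- 3; D <- 2; TT <- 4; B <- 3; L <- 2
  net <- local({
    set.seed(11)
    list(layers = list(phenoseq:::init_lstm_layer(D, H),
                       phenoseq:::init_lstm_layer(H, H)),
         Why = matrix(runif(H * L, -0.5, 0.5), H), by = numeric(L),
         readout = "final")
  })
  x <- array(rnorm(TT * B * D), c(TT, B, D)); y <- c(1, 2, 1)
  lossfun <- function(net) {
    fw <- phenoseq:::lstm_net_forward(net, x)
    p <- phenoseq:::softmax_rows(fw$logits)
    mean(-log(p[cbind(seq_len(B), y)]))
  }
  fw <- phenoseq:::lstm_net_forward(net, x)
  p <- phenoseq:::softmax_rows(fw$logits)
  dlog <- p; dlog[cbind(seq_len(B), y)] <- dlog[cbind(seq_len(B), y)] - 1
  dlog <- dlog / B
  g <- phenoseq:::lstm_net_backward(net, fw, dlog)
  eps <- 1e-5
  for (li in 1:2) for (nm in c("Wx", "Wh", "b")) {
    for (i in sample(length(net$layers[[li]][[nm]]), 4)) {
      n1 <- net; n1$layers[[li]][[nm]][i] <- n1$layers[[li]][[nm]][i] + eps
      n2 <- net; n2$layers[[li]][[nm]][i] <- n2$layers[[li]][[nm]][i] - eps
      num <- (lossfun(n1) - lossfun(n2)) / (2 * eps)
      expect_lt(abs(num - g$layers[[li]][[nm]][i]) /
                  max(abs(num) + abs(g$layers[[li]][[nm]][i]), 1e-6), 1e-3)
    }
  }
})

test_that("train_lstm separates slope-distinct classes and controls are at chance", {
  set.seed(42)
  mkseq <- function(cl) {
    t <- 1:22; slope <- if (cl == 0) 0.05 else 0.08
    matrix(rep(slope * t, 8), 22, 8) + matrix(rnorm(22 * 8, 0, 0.25), 22, 8) +
      rep(runif(8, -0.5, 0.5), each = 22)
  }
  tr_y <- rep(0:1, each = 20); te_y <- rep(0:1, each = 10)
  tr <- lapply(tr_y, mkseq); te <- lapply(te_y, mkseq)
  cfg <- lstm_config(n_classes = 2, hidden = 64, epochs = 40, seed = 5)
  m <- train_lstm(tr, tr_y, cfg)
  acc <- mean((max.col(predict(m, te), ties.method = "first") - 1L) == te_y)
  expect_gte(acc, 0.9)
  # determinism: identical loss curve under the same seed
  m2 <- train_lstm(tr, tr_y, cfg)
  expect_identical(m$loss_history, m2$loss_history)
  # label-shuffled control: held-out accuracy within binomial noise of 1/L
  set.seed(99)
  yshuf <- sample(tr_y)
  mshuf <- train_lstm(tr, yshuf, lstm_config(n_classes = 2, hidden = 64,
                                             epochs = 15, seed = 5))
  acc_shuf <- mean((max.col(predict(mshuf, te), ties.method = "first") - 1L) == te_y)
  bounds <- qbinom(c(0.025, 0.975), 20, 0.5) / 20
  expect_gte(acc_shuf, bounds[1]); expect_lte(acc_shuf, bounds[2])
})

test_that("classify_sequence returns a normalised score over classes", {
  set.seed(1)
  tr <- lapply(rep(0:1, each = 6), function(cl)
    matrix(rnorm(10 * 4, mean = cl), 10, 4))
  m <- train_lstm(tr, rep(0:1, each = 6),
                  lstm_config(n_classes = 2, hidden = 16, epochs = 5, seed = 2))
  sc <- classify_sequence(m, matrix(rnorm(10 * 4), 10, 4))
  expect_length(sc, 2)
  expect_equal(sum(sc), 1, tolerance = 1e-6)
  # truncated sequences still yield a valid distribution
  sc3 <- classify_sequence(m, matrix(rnorm(3 * 4), 3, 4))
  expect_equal(sum(sc3), 1, tolerance = 1e-6)
  expect_true(all(sc3 >= 0))
  expect_error(classify_sequence(m, matrix(0, 5, 7)), "dimension")
})
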