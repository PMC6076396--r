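# Independent brute-force oracles used by unit and acceptance tests.
# Kept deliberately naive (loops, scalar arithmetic) so they share no code
# with the implementations they check.

# exhaustive between-class-variance search over all 256 candidate levels
otsu_bruteforce <- function(counts) {
  n <- sum(counts)
  best <- -1; best_t <- NA
  for (t in 0:255) {
    w0 <- sum(counts[1:(t + 1)]) / n
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum((0:t) * counts[1:(t + 1)]) / sum(counts[1:(t + 1)])
    mu1 <- sum((if (t < 255) (t + 1):255 else integer(0)) *
                 counts[(t + 2):256]) / sum(counts[(t + 2):256])
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best + 1e-12) { best <- v; best_t <- t }
  }
  if (is.na(best_t)) which(counts > 0)[1] - 1 else best_t
}

# scalar-arithmetic evaluation of the printed recurrences
rnn_step_oracle <- function(p, x, h_prev) {
  H <- length(h_prev)
  h <- numeric(H)
  for (i in seq_len(H)) {
    acc <- p$b[i]
    for (j in seq_along(x)) acc <- acc + p$W_xh[i, j] * x[j]
    for (j in seq_len(H)) acc <- acc + p$W_hh[i, j] * h_prev[j]
    h[i] <- tanh(acc)
  }
  y <- numeric(nrow(p$W_hy))
  for (i in seq_len(nrow(p$W_hy))) {
    acc <- 0
    for (j in seq_len(H)) acc <- acc + p$W_hy[i, j] * h[j]
    y[i] <- 1 / (1 + exp(-acc))
  }
  list(h = h, y = y)
}

lstm_step_oracle <- function(p, x, h_prev, c_prev) {
  H <- length(h_prev)
  gate <- function(Wx, Wh, b, squash) {
    out <- numeric(H)
    for (i in seq_len(H)) {
      acc <- b[i]
      for (j in seq_along(x)) acc <- acc + Wx[i, j] * x[j]
      for (j in seq_len(H)) acc <- acc + Wh[i, j] * h_prev[j]
      out[i] <- squash(acc)
    }
    out
  }
  sig <- function(a) 1 / (1 + exp(-a))
  i_t <- gate(p$W_xi, p$W_hi, p$b_i, sig)
  f_t <- gate(p$W_xf, p$W_hf, p$b_f, sig)
  o_t <- gate(p$W_xo, p$W_ho, p$b_o, sig)
  g_t <- gate(p$W_xc, p$W_hc, p$b_c, tanh)
  c_t <- numeric(H); h_t <- numeric(H)
  for (i in seq_len(H)) {
    c_t[i] <- f_t[i] * c_prev[i] + i_t[i] * g_t[i]
    h_t[i] <- o_t[i] * tanh(c_t[i])
  }
  list(h = h_t, c = c_t)
}

random_histogram <- function(seed) {
  set.seed(seed)
  counts <- numeric(256)
  k <- sample(1:30, 1)
  counts[sample(256, k)] <- rpois(k, lambda = sample(c(3, 50, 500), 1))
  if (sum(counts) == 0) counts[sample(256, 1)] <- 5
  counts
}
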