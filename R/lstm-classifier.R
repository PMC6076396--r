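#' LSTM sequence classifier configuration
#'
#' A stacked (default two-layer) LSTM over per-frame feature vectors with a
#' softmax readout of the genotype class at the final time step (optionally
#' the per-step average of class scores). Trained with mini-batch stochastic
#' gradient descent with momentum by backpropagation through time.
#'
#' @param n_classes number of genotype classes L.
#' @param hidden hidden units per layer (default 256).
#' @param n_layers stacked LSTM layers (default 2; layer 2 consumes layer 1's
#'   hidden states).
#' @param learning_rate,momentum,weight_decay,batch_size SGD hyperparameters
#'   (defaults 0.01, 0.9, 0.005, 32).
#' @param epochs training epochs.
#' @param seed RNG seed for initialisation and batch order.
#' @param readout `"final"` (class scores at the last step) or `"mean"`
#'   (per-step scores averaged).
#' @param standardize z-score the features with training-set statistics.
#' @return an `lstm_config` list.
#' @export
lstm_config <- function(n_classes, hidden = 256L, n_layers = 2L,
                        learning_rate = 0.01, momentum = 0.9,
                        weight_decay = 0.005, batch_size = 32L, epochs = 40L,
                        seed = 1L, readout = c("final", "mean"),
                        standardize = TRUE) {
  readout <- match.arg(readout)
  stopifnot(n_classes >= 2, hidden >= 1, n_layers >= 1, learning_rate > 0,
            momentum >= 0, weight_decay >= 0, batch_size >= 1, epochs >= 1)
  structure(list(n_classes = as.integer(n_classes), hidden = as.integer(hidden),
                 n_layers = as.integer(n_layers), learning_rate = learning_rate,
                 momentum = momentum, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 seed = as.integer(seed), readout = readout,
                 standardize = isTRUE(standardize)),
            class = "lstm_config")
}

# ---- internal batched LSTM ------------------------------------------------
# Layer parameters use gate-concatenated matrices: Wx (D x 4H), Wh (H x 4H),
# b (4H), gate column order i, f, o, g(candidate).

init_lstm_layer <- function(input_dim, hidden, forget_bias = 1) {
  k <- 1 / sqrt(hidden)
  b <- numeric(4L * hidden)
  b[(hidden + 1L):(2L * hidden)] <- forget_bias
  list(Wx = matrix(runif(input_dim * 4L * hidden, -k, k), input_dim),
       Wh = matrix(runif(hidden * 4L * hidden, -k, k), hidden),
       b = b)
}

# Forward one layer over a (T x B x D) input array; returns hidden states
# (T x B x H) and the per-step caches for BPTT.
lstm_layer_forward <- function(layer, x) {
  dims <- dim(x); TT <- dims[1]; B <- dims[2]; D <- dims[3]
  H <- nrow(layer$Wh)
  xall <- matrix(aperm(x, c(2, 1, 3)), nrow = B * TT)      # rows (b, t)
  ax <- xall %*% layer$Wx + rep(layer$b, each = B * TT)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  hs <- array(0, c(TT, B, H))
  cache <- vector("list", TT)
  gi <- seq_len(H); gf <- H + gi; go <- 2L * H + gi; gg <- 3L * H + gi
  for (t in seq_len(TT)) {
    rows <- ((t - 1L) * B + 1L):(t * B)
    a <- ax[rows, , drop = FALSE] + h %*% layer$Wh
    i <- sigmoid(a[, gi, drop = FALSE])
    f <- sigmoid(a[, gf, drop = FALSE])
    o <- sigmoid(a[, go, drop = FALSE])
    g <- tanh(a[, gg, drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h_prev <- h
    h <- o * tc
    hs[t, , ] <- h
    cache[[t]] <- list(i = i, f = f, o = o, g = g, c = cc, tc = tc,
                       c_prev = c_prev, h_prev = h_prev)
  }
  list(hs = hs, cache = cache, xall = xall)
}

# Backward through one layer; dh is (T x B x H) upstream gradient w.r.t. the
# hidden states. Returns parameter grads and (T x B x D) input gradient.
lstm_layer_backward <- function(layer, fwd, dh, need_dx = TRUE) {
  H <- nrow(layer$Wh)
  dims <- dim(dh); TT <- dims[1]; B <- dims[2]
  D <- nrow(layer$Wx)
  gi <- seq_len(H); gf <- H + gi; go <- 2L * H + gi; gg <- 3L * H + gi
  dA <- matrix(0, B * TT, 4L * H)
  dh_next <- matrix(0, B, H)
  dc_next <- matrix(0, B, H)
  for (t in rev(seq_len(TT))) {
    cc <- fwd$cache[[t]]
    dht <- matrix(dh[t, , ], B, H) + dh_next
    dct <- dht * cc$o * (1 - cc$tc^2) + dc_next
    da <- matrix(0, B, 4L * H)
    da[, go] <- dht * cc$tc * cc$o * (1 - cc$o)
    da[, gi] <- dct * cc$g * cc$i * (1 - cc$i)
    da[, gf] <- dct * cc$c_prev * cc$f * (1 - cc$f)
    da[, gg] <- dct * cc$i * (1 - cc$g^2)
    rows <- ((t - 1L) * B + 1L):(t * B)
    dA[rows, ] <- da
    dh_next <- da %*% t(layer$Wh)
    dc_next <- dct * cc$f
  }
  # recompute h_prev stack for the Wh gradient
  hprev <- matrix(0, B * TT, H)
  for (t in seq_len(TT)) hprev[((t - 1L) * B + 1L):(t * B), ] <- fwd$cache[[t]]$h_prev
  g <- list(Wx = crossprod(fwd$xall, dA), Wh = crossprod(hprev, dA), b = colSums(dA))
  dx <- NULL
  if (need_dx) {
    dxall <- dA %*% t(layer$Wx)
    dx <- aperm(array(dxall, c(B, TT, D)), c(2, 1, 3))
  }
  list(grads = g, dx = dx)
}

lstm_net_forward <- function(net, x) {
  acts <- vector("list", length(net$layers))
  inp <- x
  for (li in seq_along(net$layers)) {
    acts[[li]] <- lstm_layer_forward(net$layers[[li]], inp)
    inp <- acts[[li]]$hs
  }
  hs_top <- acts[[length(acts)]]$hs
  dims <- dim(hs_top); TT <- dims[1]; B <- dims[2]
  if (net$readout == "final") {
    logits <- matrix(hs_top[TT, , ], B) %*% net$Why + rep(net$by, each = B)
  } else {
    logits <- matrix(0, B, ncol(net$Why))
    for (t in seq_len(TT))
      logits <- logits + matrix(hs_top[t, , ], B) %*% net$Why + rep(net$by, each = B)
    logits <- logits / TT
  }
  list(logits = logits, acts = acts)
}

lstm_net_backward <- function(net, fwd, dlogits) {
  n_layers <- length(net$layers)
  hs_top <- fwd$acts[[n_layers]]$hs
  dims <- dim(hs_top); TT <- dims[1]; B <- dims[2]; H <- dims[3]
  dh_top <- array(0, c(TT, B, H))
  if (net$readout == "final") {
    gWhy <- crossprod(matrix(hs_top[TT, , ], B), dlogits)
    gby <- colSums(dlogits)
    dh_top[TT, , ] <- dlogits %*% t(net$Why)
  } else {
    gWhy <- matrix(0, nrow(net$Why), ncol(net$Why))
    for (t in seq_len(TT))
      gWhy <- gWhy + crossprod(matrix(hs_top[t, , ], B), dlogits) / TT
    gby <- colSums(dlogits)
    dupper <- (dlogits %*% t(net$Why)) / TT
    for (t in seq_len(TT)) dh_top[t, , ] <- dupper
  }
  grads <- vector("list", n_layers)
  dh <- dh_top
  for (li in rev(seq_len(n_layers))) {
    bk <- lstm_layer_backward(net$layers[[li]], fwd$acts[[li]], dh, need_dx = li > 1L)
    grads[[li]] <- bk$grads
    if (li > 1L) dh <- bk$dx
  }
  list(layers = grads, Why = gWhy, by = gby)
}

# stack a list of equal-length T x D feature matrices into (T, B, D)
stack_sequences <- function(seqs) {
  TT <- nrow(seqs[[1]]); D <- ncol(seqs[[1]]); B <- length(seqs)
  x <- array(0, c(TT, B, D))
  for (i in seq_len(B)) x[, i, ] <- seqs[[i]]
  x
}

#' Train the stacked LSTM sequence classifier
#'
#' Feature sequences (one matrix per plant, rows = frames in day order) are
#' classified into genotype classes from the information of the entire
#' sequence: the stacked LSTM is unrolled over the frames and the class scores
#' are read out at the final step. Cross-entropy is minimised by SGD with
#' momentum and weight decay; training is seed-reproducible. Sequences may
#' have different lengths (mini-batches group equal lengths).
#'
#' @param sequences list of T_i x D feature matrices.
#' @param labels 0-based genotype labels.
#' @param config an [lstm_config()].
#' @return a `phenoseq_lstm` classifier with `$loss_history`.
#' @export
train_lstm <- function(sequences, labels, config) {
  stopifnot(inherits(config, "lstm_config"), length(sequences) == length(labels))
  if (any(vapply(sequences, nrow, integer(1)) < 1L)) stop("empty sequence", call. = FALSE)
  labels <- as.integer(labels)
  if (any(labels < 0L | labels >= config$n_classes))
    stop("labels must lie in 0..n_classes-1", call. = FALSE)
  D <- ncol(sequences[[1]])
  if (any(vapply(sequences, ncol, integer(1)) != D))
    stop("all sequences must share one feature dimension", call. = FALSE)

  if (config$standardize) {
    allx <- do.call(rbind, sequences)
    ctr <- colMeans(allx)
    scl <- pmax(apply(allx, 2, sd), 1e-8)
  } else {
    ctr <- numeric(D); scl <- rep(1, D)
  }
  seqs <- lapply(sequences, function(s) sweep(sweep(s, 2, ctr), 2, scl, `/`))

  set.seed(config$seed)
  H <- config$hidden
  layers <- vector("list", config$n_layers)
  for (li in seq_len(config$n_layers))
    layers[[li]] <- init_lstm_layer(if (li == 1L) D else H, H)
  k <- 1 / sqrt(H)
  net <- list(layers = layers,
              Why = matrix(runif(H * config$n_classes, -k, k), H),
              by = numeric(config$n_classes), readout = config$readout)

  flat <- function(n) c(lapply(n$layers, function(l) l[c("Wx", "Wh", "b")]),
                        list(out = list(Wx = n$Why, Wh = NULL, b = n$by)))
  vel <- rapply(flat(net), function(p) p * 0, how = "replace")
  lr <- config$learning_rate; mom <- config$momentum; wd <- config$weight_decay
  n <- length(seqs)
  y <- labels + 1L
  lens <- vapply(seqs, nrow, integer(1))
  loss_hist <- numeric(config$epochs)

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    # group the shuffled order into equal-length mini-batches
    batches <- list()
    for (len in unique(lens[ord])) {
      pool <- ord[lens[ord] == len]
      for (s in seq(1L, length(pool), config$batch_size))
        batches[[length(batches) + 1L]] <- pool[s:min(s + config$batch_size - 1L, length(pool))]
    }
    losses <- numeric(0)
    for (take in batches) {
      x <- stack_sequences(seqs[take])
      B <- length(take)
      fw <- lstm_net_forward(net, x)
      p <- softmax_rows(fw$logits)
      losses <- c(losses, mean(-log(pmax(p[cbind(seq_len(B), y[take])], 1e-12))))
      dlog <- p
      dlog[cbind(seq_len(B), y[take])] <- dlog[cbind(seq_len(B), y[take])] - 1
      dlog <- dlog / B
      g <- lstm_net_backward(net, fw, dlog)
      for (li in seq_along(net$layers)) {
        for (nm in c("Wx", "Wh", "b")) {
          grad <- g$layers[[li]][[nm]] + (if (nm == "b") 0 else wd) * net$layers[[li]][[nm]]
          vel[[li]][[nm]] <- mom * vel[[li]][[nm]] - lr * grad
          net$layers[[li]][[nm]] <- net$layers[[li]][[nm]] + vel[[li]][[nm]]
        }
      }
      gw <- g$Why + wd * net$Why
      vel$out$Wx <- mom * vel$out$Wx - lr * gw
      net$Why <- net$Why + vel$out$Wx
      vel$out$b <- mom * vel$out$b - lr * g$by
      net$by <- net$by + vel$out$b
    }
    loss_hist[ep] <- mean(losses)
  }
  structure(list(net = net, config = config, center = ctr, scale = scl,
                 loss_history = loss_hist),
            class = "phenoseq_lstm")
}

#' @export
print.phenoseq_lstm <- function(x, ...) {
  cat(sprintf("<phenoseq_lstm> %d classes, %d layer(s) x %d hidden, %s readout; final loss %.4f\n",
              x$config$n_classes, x$config$n_layers, x$config$hidden,
              x$config$readout, tail(x$loss_history, 1)))
  invisible(x)
}

#' Class scores of a feature sequence
#'
#' Runs a trained sequence classifier over one plant's feature sequence and
#' returns normalised class scores (softmax, summing to 1). The predicted
#' genotype is the arg-max; ties resolve to the lowest class index.
#'
#' @param classifier a trained `phenoseq_lstm`.
#' @param sequence T x D feature matrix (any T >= 1).
#' @return named numeric vector of L class scores.
#' @export
classify_sequence <- function(classifier, sequence) {
  stopifnot(inherits(classifier, "phenoseq_lstm"))
  if (ncol(sequence) != length(classifier$center))
    stop("feature dimension mismatch", call. = FALSE)
  s <- sweep(sweep(sequence, 2, classifier$center), 2, classifier$scale, `/`)
  fw <- lstm_net_forward(classifier$net, stack_sequences(list(s)))
  drop(softmax_rows(fw$logits))
}

#' @rdname classify_sequence
#' @param object a trained `phenoseq_lstm`.
#' @param sequences list of feature matrices.
#' @param ... unused.
#' @return for `predict()`: a matrix of class scores, one row per sequence.
#' @export
predict.phenoseq_lstm <- function(object, sequences, ...) {
  t(vapply(sequences, function(s) classify_sequence(object, s),
           numeric(object$config$n_classes)))
}
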