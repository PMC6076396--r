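#' Rotation augmentation
#'
#' Expands a set of square images by the three quarter-turn rotations (90, 180,
#' 270 degrees) about the image centre; every output keeps the label of its
#' source. Output order is deterministic: each original is followed by its
#' three rotations.
#'
#' @param frames list of square matrices or H x W x C arrays.
#' @param labels vector of labels, one per frame.
#' @return list with `frames` (length `4 * length(input)`) and `labels`.
#' @export
augment_rotations <- function(frames, labels) {
  stopifnot(length(frames) == length(labels))
  for (f in frames) {
    d <- dim(f)
    if (d[1] != d[2]) stop("rotation augmentation requires square images", call. = FALSE)
  }
  out_frames <- vector("list", 4L * length(frames))
  out_labels <- rep(labels, each = 4L)
  for (i in seq_along(frames)) {
    base <- 4L * (i - 1L)
    out_frames[[base + 1L]] <- frames[[i]]
    out_frames[[base + 2L]] <- rotate90(frames[[i]], 1L)
    out_frames[[base + 3L]] <- rotate90(frames[[i]], 2L)
    out_frames[[base + 4L]] <- rotate90(frames[[i]], 3L)
  }
  list(frames = out_frames, labels = out_labels)
}

#' Split genotype classes into area sub-classes
#'
#' Within each genotype, bin edges are the 20/40/60/80% area quantiles
#' (inverse-ECDF definition) and each sample is assigned the number of edges
#' its area strictly exceeds, so ties fall into the lower bin. The flat
#' sub-class label is `genotype * n_bins + area_bin`, giving the L x 5 class
#' set the per-frame classifier trains on. A genotype with fewer samples than
#' bins gets a reduced bin count, with a warning.
#'
#' @param areas non-negative plant areas in pixels, one per sample.
#' @param genotypes 0-based genotype indices, parallel to `areas`.
#' @param n_bins sub-classes per genotype (default 5).
#' @return tibble with columns `genotype`, `area_bin`, `flat_label`.
#' @export
assign_area_subclasses <- function(areas, genotypes, n_bins = 5L) {
  stopifnot(length(areas) == length(genotypes), all(areas >= 0))
  bin <- integer(length(areas))
  for (gt in unique(genotypes)) {
    sel <- genotypes == gt
    ng <- sum(sel)
    nb <- n_bins
    if (ng < n_bins) {
      warning(sprintf("genotype %s has %d samples < %d bins; using %d bins",
                      gt, ng, n_bins, max(1L, ng)))
      nb <- max(1L, ng)
    }
    if (nb == 1L) { bin[sel] <- 0L; next }
    edges <- stats::quantile(areas[sel], probs = seq_len(nb - 1L) / nb, type = 1)
    bin[sel] <- vapply(areas[sel], function(a) sum(a > edges), integer(1))
  }
  tibble::tibble(genotype = as.integer(genotypes), area_bin = bin,
                 flat_label = as.integer(genotypes) * as.integer(n_bins) + bin)
}

#' CNN configuration
#'
#' A small convolutional network for per-frame sub-class classification:
#' three blocks of 3x3 convolution + ReLU + 2x2 max-pooling with widths
#' `conv_widths`, a dense layer of `feature_dim` units (the deep-feature
#' layer) and a softmax classification head over `n_outputs` classes. Trained
#' by stochastic gradient descent with momentum in mini-batches.
#'
#' @param n_outputs number of output classes (genotypes x area bins).
#' @param input_size frames are resized to this square side (default 32).
#' @param feature_dim width of the last dense layer before classification.
#' @param conv_widths widths of the three convolution blocks.
#' @param learning_rate,momentum,weight_decay,batch_size SGD hyperparameters
#'   (defaults 0.001, 0.9, 1e-6, 32).
#' @param epochs training epochs.
#' @param seed RNG seed controlling initialisation and batch order.
#' @param augment apply rotation augmentation to the training set.
#' @return a `cnn_config` list.
#' @export
cnn_config <- function(n_outputs, input_size = 32L, feature_dim = 128L,
                       conv_widths = c(16L, 32L, 64L), learning_rate = 0.001,
                       momentum = 0.9, weight_decay = 1e-6, batch_size = 32L,
                       epochs = 16L, seed = 1L, augment = TRUE) {
  stopifnot(n_outputs >= 2, input_size %% 8 == 0, length(conv_widths) == 3,
            learning_rate > 0, momentum >= 0, weight_decay >= 0,
            batch_size >= 1, epochs >= 1, feature_dim >= 1)
  structure(list(n_outputs = as.integer(n_outputs), input_size = as.integer(input_size),
                 feature_dim = as.integer(feature_dim),
                 conv_widths = as.integer(conv_widths),
                 learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 augment = isTRUE(augment)),
            class = "cnn_config")
}

# ---- internal network machinery -------------------------------------------

# im2col index matrix for 3x3 pad-1 convolution over an (S,S,B,C) batch;
# rows ordered (row, col, batch), columns (offset-row, offset-col, channel).
make_conv_idx <- function(S, C, B, cache = NULL) {
  key <- paste(S, C, B, sep = "x")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  P <- S + 2L
  r <- rep(seq_len(S), S)
  cc <- rep(seq_len(S), each = S)
  base <- cc * P + (r + 1L)                       # padded linear index of (r+1, c+1)
  if (B > 1L) base <- rep(base, B) + rep((0:(B - 1L)) * P * P, each = S * S)
  d9 <- as.vector(outer(-1:1, (-1:1) * P, `+`))
  idx1 <- outer(base, d9, `+`)                    # (S^2 B) x 9
  if (C > 1L) {
    idx1 <- do.call(cbind, lapply(0:(C - 1L), function(ch) idx1 + ch * P * P * B))
  }
  storage.mode(idx1) <- "integer"
  if (!is.null(cache)) cache[[key]] <- idx1
  idx1
}

# pad the spatial dims of an (S,S,B,C) array by one zero ring
pad1 <- function(x) {
  d <- dim(x); P <- d[1] + 2L
  xp <- array(0, c(P, P, d[3], d[4]))
  xp[2:(P - 1L), 2:(P - 1L), , ] <- x
  xp
}

conv_forward <- function(x, W, b) {
  d <- dim(x); S <- d[1]; B <- d[3]
  col <- im2col3(x, S, B, d[4])
  out <- col %*% W
  out <- out + rep(b, each = nrow(out))
  dim(out) <- c(S, S, B, ncol(W))
  list(out = out, col = col)
}

# weights rearranged for the transposed convolution that computes dx:
# W is (9C x F) with rows (offset, channel); returns (9F x C) with flipped
# offsets, so dx = im2col(dout) %*% W_t.
flip_weights <- function(W, C) {
  f <- ncol(W)
  arr <- array(W, c(9L, C, f))
  matrix(aperm(arr[9:1, , , drop = FALSE], c(1, 3, 2)), nrow = 9L * f)
}

conv_backward <- function(dout, col, W, C, need_dx = TRUE) {
  f <- ncol(W)
  d <- dim(dout); S <- d[1]; B <- d[3]
  doutm <- dout
  dim(doutm) <- c(length(dout) / f, f)
  dW <- crossprod(col, doutm)
  db <- colSums(doutm)
  dx <- NULL
  if (need_dx) {
    dcol <- im2col3(dout, S, B, f)
    dx <- dcol %*% flip_weights(W, C)
    dim(dx) <- c(S, S, B, C)
  }
  list(dW = dW, db = db, dx = dx)
}

relu <- function(x) x * (x > 0)

maxpool_forward <- function(x) {
  d <- dim(x)
  mp <- maxpool2(x, d[1], d[3], d[4])
  list(out = mp$out, which = mp$which, dims = d)
}

maxpool_backward <- function(dout, pool) {
  d <- pool$dims
  maxpool2_backward(dout, pool$which, d[1], d[3], d[4])
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

init_cnn_params <- function(config) {
  cw <- config$conv_widths
  S <- config$input_size
  flat <- (S / 8)^2 * cw[3]
  he <- function(nin, nout) matrix(rnorm(nin * nout) * sqrt(2 / nin), nin, nout)
  list(
    W1 = he(9 * 3, cw[1]), b1 = numeric(cw[1]),
    W2 = he(9 * cw[1], cw[2]), b2 = numeric(cw[2]),
    W3 = he(9 * cw[2], cw[3]), b3 = numeric(cw[3]),
    W4 = he(flat, config$feature_dim), b4 = numeric(config$feature_dim),
    W5 = he(config$feature_dim, config$n_outputs), b5 = numeric(config$n_outputs)
  )
}

# Forward pass over a batch array (S,S,B,3); returns logits, features and the
# caches needed for backprop.
cnn_forward <- function(params, x) {
  d <- dim(x); B <- d[3]
  c1 <- conv_forward(x, params$W1, params$b1)
  r1 <- relu(c1$out)
  p1 <- maxpool_forward(r1)
  c2 <- conv_forward(p1$out, params$W2, params$b2)
  r2 <- relu(c2$out)
  p2 <- maxpool_forward(r2)
  c3 <- conv_forward(p2$out, params$W3, params$b3)
  r3 <- relu(c3$out)
  p3 <- maxpool_forward(r3)
  # flatten to B x (S/8)^2*cw3 with (row, col, feature) column order
  flat <- t(matrix(aperm(p3$out, c(1, 2, 4, 3)), ncol = B))
  z4 <- flat %*% params$W4 + rep(params$b4, each = B)
  h4 <- relu(z4)                                # deep features
  logits <- h4 %*% params$W5 + rep(params$b5, each = B)
  list(logits = logits, features = h4,
       cache = list(x = x, c1 = c1, p1 = p1, c2 = c2, p2 = p2,
                    c3 = c3, p3 = p3, flat = flat, z4 = z4, h4 = h4))
}

cnn_backward <- function(params, cache, dlogits) {
  B <- nrow(dlogits)
  g <- list()
  g$W5 <- crossprod(cache$h4, dlogits)
  g$b5 <- colSums(dlogits)
  dh4 <- tcrossprod(dlogits, params$W5)
  dz4 <- dh4 * (cache$z4 > 0)
  g$W4 <- crossprod(cache$flat, dz4)
  g$b4 <- colSums(dz4)
  dflat <- tcrossprod(dz4, params$W4)
  d3 <- dim(cache$p3$out)
  dp3 <- aperm(array(t(dflat), c(d3[1], d3[2], d3[4], d3[3])), c(1, 2, 4, 3))
  dr3 <- maxpool_backward(dp3, cache$p3)
  dc3 <- dr3 * (cache$c3$out > 0)
  cw <- vapply(list(params$b1, params$b2, params$b3), length, integer(1))
  bk3 <- conv_backward(dc3, cache$c3$col, params$W3, cw[2], need_dx = TRUE)
  g$W3 <- bk3$dW; g$b3 <- bk3$db
  dr2 <- maxpool_backward(bk3$dx, cache$p2)
  dc2 <- dr2 * (cache$c2$out > 0)
  bk2 <- conv_backward(dc2, cache$c2$col, params$W2, cw[1], need_dx = TRUE)
  g$W2 <- bk2$dW; g$b2 <- bk2$db
  dr1 <- maxpool_backward(bk2$dx, cache$p1)
  dc1 <- dr1 * (cache$c1$out > 0)
  bk1 <- conv_backward(dc1, cache$c1$col, params$W1, 3L, need_dx = FALSE)
  g$W1 <- bk1$dW; g$b1 <- bk1$db
  g
}

# Stack a list of frames into an (S,S,B,3) batch, resizing when needed.
stack_frames <- function(frames, S) {
  B <- length(frames)
  x <- array(0, c(S, S, B, 3L))
  for (i in seq_len(B)) {
    f <- frames[[i]]
    if (!all(dim(f)[1:2] == c(S, S))) f <- resize_image(f, S)
    x[, , i, ] <- f
  }
  x
}

#' Train the per-frame CNN
#'
#' Minimises softmax cross-entropy over the flat sub-class labels by
#' mini-batch stochastic gradient descent with momentum and weight decay.
#' Training frames are optionally expanded with rotation augmentation, resized
#' to `config$input_size` and normalised per channel with statistics of the
#' training set. Fully seed-reproducible.
#'
#' @param frames list of RGB arrays (square).
#' @param labels integer flat sub-class labels in `0..n_outputs-1`.
#' @param config a [cnn_config()].
#' @return a `phenoseq_cnn` model object with the learned parameters,
#'   normalisation statistics and per-epoch mean loss in `$loss_history`.
#' @export
train_cnn <- function(frames, labels, config) {
  stopifnot(inherits(config, "cnn_config"), length(frames) == length(labels))
  labels <- as.integer(labels)
  if (any(labels < 0L | labels >= config$n_outputs))
    stop("labels must lie in 0..n_outputs-1", call. = FALSE)
  if (length(unique(labels)) < 2L) stop("need >= 2 distinct labels", call. = FALSE)
  S <- config$input_size
  frames <- lapply(frames, function(f) if (all(dim(f)[1:2] == c(S, S))) f else resize_image(f, S))
  if (config$augment) {
    aug <- augment_rotations(frames, labels)
    frames <- aug$frames; labels <- aug$labels
  }
  x_all <- stack_frames(frames, S)
  norm <- list(mean = apply(x_all, 4, mean), sd = pmax(apply(x_all, 4, sd), 1e-6))
  for (ch in 1:3) x_all[, , , ch] <- (x_all[, , , ch] - norm$mean[ch]) / norm$sd[ch]
  n <- dim(x_all)[3]
  y <- labels + 1L

  set.seed(config$seed)
  params <- init_cnn_params(config)
  vel <- lapply(params, function(p) p * 0)
  lr <- config$learning_rate; mom <- config$momentum; wd <- config$weight_decay
  bs <- config$batch_size
  loss_hist <- numeric(config$epochs)

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, bs)) {
      take <- ord[start:min(start + bs - 1L, n)]
      xb <- x_all[, , take, , drop = FALSE]
      yb <- y[take]
      fw <- cnn_forward(params, xb)
      p <- softmax_rows(fw$logits)
      B <- length(take)
      losses <- c(losses, mean(-log(pmax(p[cbind(seq_len(B), yb)], 1e-12))))
      dlog <- p
      dlog[cbind(seq_len(B), yb)] <- dlog[cbind(seq_len(B), yb)] - 1
      dlog <- dlog / B
      g <- cnn_backward(params, fw$cache, dlog)
      for (nm in names(params)) {
        grad <- g[[nm]] + wd * params[[nm]]
        vel[[nm]] <- mom * vel[[nm]] - lr * grad
        params[[nm]] <- params[[nm]] + vel[[nm]]
      }
    }
    loss_hist[ep] <- mean(losses)
  }
  structure(list(params = params, config = config, norm = norm,
                 loss_history = loss_hist),
            class = "phenoseq_cnn")
}

#' @export
print.phenoseq_cnn <- function(x, ...) {
  cat(sprintf("<phenoseq_cnn> %d outputs, %d-d features, input %dx%d; final loss %.4f\n",
              x$config$n_outputs, x$config$feature_dim, x$config$input_size,
              x$config$input_size, tail(x$loss_history, 1)))
  invisible(x)
}

# Batched deterministic forward pass; type "prob" returns the softmax over
# sub-classes, "feature" the penultimate-layer activations.
cnn_apply <- function(model, frames, type = c("prob", "feature")) {
  type <- match.arg(type)
  S <- model$config$input_size
  x <- stack_frames(frames, S)
  for (ch in 1:3) x[, , , ch] <- (x[, , , ch] - model$norm$mean[ch]) / model$norm$sd[ch]
  n <- dim(x)[3]
  bs <- model$config$batch_size
  out <- NULL
  for (start in seq(1L, n, bs)) {
    take <- start:min(start + bs - 1L, n)
    fw <- cnn_forward(model$params, x[, , take, , drop = FALSE])
    piece <- if (type == "prob") softmax_rows(fw$logits) else fw$features
    out <- rbind(out, piece)
  }
  out
}

#' @rdname train_cnn
#' @param object a trained `phenoseq_cnn`.
#' @param type `"prob"` for sub-class probabilities, `"feature"` for deep
#'   features, `"class"` for the arg-max flat label.
#' @param ... unused.
#' @export
predict.phenoseq_cnn <- function(object, frames, type = c("prob", "feature", "class"), ...) {
  type <- match.arg(type)
  if (type == "class") {
    p <- cnn_apply(object, frames, "prob")
    return(max.col(p, ties.method = "first") - 1L)
  }
  cnn_apply(object, frames, type)
}

#' Deep features of frames under a trained CNN
#'
#' Deterministic activations of the last dense layer before the classification
#' head, the fixed-length per-frame representation fed to the sequence models.
#'
#' @param model a trained `phenoseq_cnn`.
#' @param frames list of RGB arrays.
#' @return numeric matrix, one row per frame, `feature_dim` columns.
#' @export
extract_deep_features <- function(model, frames) {
  cnn_apply(model, frames, "feature")
}

#' Collapse sub-class probabilities to genotype probabilities
#'
#' Sums the softmax mass of each genotype's area bins.
#'
#' @param probs matrix of sub-class probabilities (columns in flat-label order).
#' @param n_bins area bins per genotype.
#' @return matrix with one column per genotype.
#' @export
collapse_subclass_probs <- function(probs, n_bins = 5L) {
  L <- ncol(probs) / n_bins
  stopifnot(L == round(L))
  out <- sapply(seq_len(L), function(g)
    rowSums(probs[, ((g - 1L) * n_bins + 1L):(g * n_bins), drop = FALSE]))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L)
  out
}
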