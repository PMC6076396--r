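#' Otsu threshold of an 8-bit intensity histogram
#'
#' Returns the level `t` in `0..255` that maximises the between-class variance
#' of the split into `{<= t}` and `{> t}`. Ties are broken towards the smallest
#' level; a histogram with a single occupied bin returns that bin's level (the
#' degenerate split leaves everything in one class).
#'
#' @param counts numeric vector of 256 non-negative bin counts for levels
#'   0..255.
#' @return integer threshold level in 0..255.
#' @export
otsu_threshold <- function(counts) {
  if (length(counts) != 256L) stop("`counts` must have 256 bins", call. = FALSE)
  if (any(counts < 0)) stop("negative bin counts", call. = FALSE)
  n <- sum(counts)
  if (n == 0) stop("empty histogram", call. = FALSE)
  lev <- 0:255
  p <- counts / n
  w0 <- cumsum(p)
  mu <- cumsum(p * lev)
  mu_t <- mu[256]
  w1 <- 1 - w0
  # between-class variance for threshold t = level index - 1
  num <- (mu_t * w0 - mu)^2
  den <- w0 * w1
  sigma_b <- ifelse(den > 0, num / den, -Inf)
  if (all(!is.finite(sigma_b))) {
    # single occupied bin: return its level
    return(lev[which(counts > 0)[1]])
  }
  lev[which.max(sigma_b)]
}

# 256-bin histogram of a real-valued channel rescaled linearly to 0..255 over
# its own range. Returns counts plus the rescaling so class means can be mapped
# back to native units. A constant channel occupies a single bin.
channel_histogram <- function(channel) {
  rng <- range(channel)
  if (diff(rng) == 0) {
    q <- matrix(0L, nrow(channel), ncol(channel))
  } else {
    q <- matrix(as.integer(pmin(255, floor((channel - rng[1]) / diff(rng) * 256))),
                nrow(channel), ncol(channel))
  }
  counts <- tabulate(as.vector(q) + 1L, nbins = 256L)
  list(counts = counts, quantised = q, range = rng)
}

#' Trinary mask of one colour channel
#'
#' Binarises a channel with Otsu's method, keeps the side named by
#' `foreground_polarity` as candidate foreground `B`, dilates it with a disc
#' structuring element to a superset `D`, and returns `B + D`: 0 outside the
#' dilation, 1 on the dilation ring (probable background/foreground), 2 on the
#' foreground core. The ring protects leaf borders that fade into the soil.
#'
#' To suppress spurious foreground on plant-free frames, the Otsu split must
#' separate the two class means by at least `min_contrast` in the channel's
#' native units; otherwise the whole mask is 0 (no foreground evidence).
#'
#' @param channel numeric matrix (e.g. the a* or b* plane of an L*a*b* image).
#' @param foreground_polarity `"low"` if the foreground lies below the Otsu
#'   threshold (a* for green plants), `"high"` if above (b*).
#' @param dilate_radius disc radius in pixels at a 256 px image; scaled
#'   proportionally to the actual image size.
#' @param min_contrast minimum Otsu class-mean separation (native units) for
#'   the channel to carry foreground evidence.
#' @return integer matrix with values in `{0, 1, 2}`.
#' @export
channel_trinary_mask <- function(channel, foreground_polarity = c("low", "high"),
                                 dilate_radius = 5, min_contrast = 8) {
  foreground_polarity <- match.arg(foreground_polarity)
  if (!is.matrix(channel)) stop("`channel` must be a single-channel matrix", call. = FALSE)
  h <- channel_histogram(channel)
  t <- otsu_threshold(h$counts)
  lowside <- h$quantised <= t
  if (all(lowside) || !any(lowside)) return(matrix(0L, nrow(channel), ncol(channel)))
  gap <- abs(mean(channel[lowside]) - mean(channel[!lowside]))
  if (gap < min_contrast) return(matrix(0L, nrow(channel), ncol(channel)))
  B <- if (foreground_polarity == "low") lowside else !lowside
  r <- max(1L, round(dilate_radius * min(dim(channel)) / 256))
  D <- EBImage::dilate(matrix(as.numeric(B), nrow(B)), EBImage::makeBrush(2L * r + 1L, "disc")) > 0
  matrix(as.integer(B) + as.integer(D), nrow(B))
}

#' Combine two trinary channel masks into a GrabCut seed mask
#'
#' Element-wise combination of the a*- and b*-channel trinary masks into the
#' four-level seed mask: both foreground cores agree -> definite foreground;
#' both zero -> definite background; any foreground core on one side ->
#' probable foreground; remaining mixtures of 0/1 -> probable background.
#'
#' Encoding follows the GrabCut convention: 0 definite background, 1 definite
#' foreground, 2 probable background, 3 probable foreground (constants
#' `DEF_BG`, `DEF_FG`, `PROB_BG`, `PROB_FG`).
#'
#' @param mask_a,mask_b integer matrices with values in `{0, 1, 2}`, same size.
#' @return integer matrix with values in `{0, 1, 2, 3}`.
#' @export
combine_masks <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b))) stop("mask shapes differ", call. = FALSE)
  if (!all(mask_a %in% 0:2) || !all(mask_b %in% 0:2))
    stop("trinary masks must take values in {0, 1, 2}", call. = FALSE)
  # lookup indexed by 3*a + b
  map <- c(DEF_BG,  PROB_BG, PROB_FG,   # a=0, b=0/1/2
           PROB_BG, PROB_BG, PROB_FG,   # a=1
           PROB_FG, PROB_FG, DEF_FG)    # a=2
  out <- map[3L * as.integer(mask_a) + as.integer(mask_b) + 1L]
  matrix(out, nrow(mask_a))
}

#' @rdname combine_masks
#' @export
DEF_BG <- 0L
#' @rdname combine_masks
#' @export
DEF_FG <- 1L
#' @rdname combine_masks
#' @export
PROB_BG <- 2L
#' @rdname combine_masks
#' @export
PROB_FG <- 3L

# Fit a K-component full-covariance Gaussian mixture to n x 3 colours by
# k-means assignment; returns per-pixel log-density evaluator.
fit_gmm <- function(z, k = 5L) {
  n <- nrow(z)
  k <- max(1L, min(k, n, nrow(unique(z))))
  if (k == 1L || n < 2L * k) {
    comp <- list(list(w = 1, mu = colMeans(z), cov = stats::cov(z) + diag(1e-4, 3)))
  } else {
    km <- suppressWarnings(stats::kmeans(z, centers = k, iter.max = 30, nstart = 1))
    comp <- lapply(seq_len(k), function(j) {
      zj <- z[km$cluster == j, , drop = FALSE]
      cv <- if (nrow(zj) > 3) stats::cov(zj) else diag(1e-3, 3)
      list(w = nrow(zj) / n, mu = colMeans(zj), cov = cv + diag(1e-5, 3))
    })
  }
  comp
}

gmm_logdens <- function(comp, z) {
  lp <- vapply(comp, function(cp) {
    ch <- tryCatch(chol(cp$cov), error = function(e) chol(cp$cov + diag(1e-3, 3)))
    d <- sweep(z, 2, cp$mu)
    y <- backsolve(ch, t(d), transpose = TRUE)
    -0.5 * colSums(y^2) - sum(log(diag(ch))) - 1.5 * log(2 * pi) + log(cp$w)
  }, numeric(nrow(z)))
  if (is.null(dim(lp))) lp <- matrix(lp, nrow = nrow(z))
  m <- apply(lp, 1, max)
  m + log(rowSums(exp(lp - m)))
}

#' GrabCut refinement of a quaternary seed mask
#'
#' Mask-initialised GrabCut with the bounding box fixed to the whole image:
#' Gaussian-mixture colour models for foreground and background are fitted to
#' the current labelling, a grid graph with contrast-weighted 8-neighbour
#' links and likelihood terminal links is cut by max-flow, and the two steps
#' alternate for `iterations` rounds. Definite seed cells are hard
#' constraints and can never flip. Morphological opening then closing with a
#' small disc removes speckle and holes.
#'
#' @param img RGB array.
#' @param seed quaternary seed matrix (see [combine_masks()]).
#' @param iterations GrabCut alternations (default 5).
#' @param gamma contrast term weight (default 50, the usual GrabCut setting).
#' @param k number of mixture components per colour model.
#' @param clean_radius disc radius of the opening/closing element at a 256 px
#'   image, scaled proportionally.
#' @return logical plant mask.
#' @export
grabcut_refine <- function(img, seed, iterations = 5, gamma = 50, k = 5L,
                           clean_radius = 2) {
  assert_rgb(img)
  assert_mask(seed, img, "seed")
  if (!any(seed == DEF_FG | seed == PROB_FG))
    stop("seed contains no foreground evidence", call. = FALSE)
  h <- nrow(seed); w <- ncol(seed); n <- h * w
  z <- matrix(img, ncol = 3L)
  hard_fg <- as.vector(seed == DEF_FG)
  hard_bg <- as.vector(seed == DEF_BG)
  fg <- as.vector(seed == DEF_FG | seed == PROB_FG)

  # 8-neighbour contrast links (right, down, down-right, down-left)
  idx <- matrix(seq_len(n), h, w)
  pairs <- rbind(
    cbind(as.vector(idx[, -w]), as.vector(idx[, -1])),
    cbind(as.vector(idx[-h, ]), as.vector(idx[-1, ])),
    cbind(as.vector(idx[-h, -w]), as.vector(idx[-1, -1])),
    cbind(as.vector(idx[-h, -1]), as.vector(idx[-1, -w]))
  )
  dist <- c(rep(1, (w - 1) * h), rep(1, (h - 1) * w), rep(sqrt(2), 2 * (h - 1) * (w - 1)))
  dz2 <- rowSums((z[pairs[, 1], ] - z[pairs[, 2], ])^2)
  beta <- 1 / (2 * mean(dz2) + 1e-12)
  nlink <- gamma * exp(-beta * dz2) / dist

  src <- n + 1L; snk <- n + 2L
  KMAX <- 1e8
  edges <- rbind(pairs, cbind(rep(src, n), seq_len(n)), cbind(seq_len(n), rep(snk, n)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)

  # colour models are estimated on a bounded pixel subsample; estimating a
  # 5-component mixture does not need every pixel
  gmm_cap <- 4000L
  for (it in seq_len(iterations)) {
    if (sum(fg) < 4 || sum(!fg) < 4) break
    comp_fg <- with_local_seed(760731L + it, {
      zi <- z[fg, , drop = FALSE]
      if (nrow(zi) > gmm_cap) zi <- zi[sample.int(nrow(zi), gmm_cap), , drop = FALSE]
      fit_gmm(zi, k)
    })
    comp_bg <- with_local_seed(880123L + it, {
      zi <- z[!fg, , drop = FALSE]
      if (nrow(zi) > gmm_cap) zi <- zi[sample.int(nrow(zi), gmm_cap), , drop = FALSE]
      fit_gmm(zi, k)
    })
    d_fg <- -gmm_logdens(comp_fg, z)   # cost of labelling foreground
    d_bg <- -gmm_logdens(comp_bg, z)
    cap_src <- pmin(d_bg, KMAX)        # paid when pixel falls on background side
    cap_snk <- pmin(d_fg, KMAX)        # paid when pixel falls on foreground side
    cap_src[hard_fg] <- KMAX; cap_snk[hard_fg] <- 0
    cap_snk[hard_bg] <- KMAX; cap_src[hard_bg] <- 0
    cut <- igraph::min_cut(g, source = src, target = snk,
                           capacity = c(nlink, cap_src, cap_snk), value.only = FALSE)
    p1 <- cut$partition1
    fg_side <- if (src %in% p1) p1 else cut$partition2
    new_fg <- rep(FALSE, n)
    new_fg[fg_side[fg_side <= n]] <- TRUE
    new_fg[hard_fg] <- TRUE
    new_fg[hard_bg] <- FALSE
    if (identical(new_fg, fg) && it > 1) { fg <- new_fg; break }
    fg <- new_fg
  }

  m <- matrix(as.numeric(fg), h, w)
  r <- max(1L, round(clean_radius * min(h, w) / 256))
  br <- EBImage::makeBrush(2L * r + 1L, "disc")
  m <- EBImage::closing(EBImage::opening(m, br), br) > 0
  m[matrix(hard_fg, h, w)] <- TRUE
  m[matrix(hard_bg, h, w)] <- FALSE
  m
}

#' Segment a plant from a top-view RGB frame
#'
#' Full segmentation pipeline: convert to L*a*b*, build trinary masks from the
#' a* channel (plants on the low side) and the b* channel (plants on the high
#' side), combine them into the quaternary GrabCut seed, refine with
#' [grabcut_refine()]. A frame with no foreground evidence (e.g. before
#' germination) yields an empty mask rather than an error.
#'
#' @param img RGB array (H x W x 3).
#' @param iterations,gamma,k,dilate_radius,clean_radius,min_contrast tuning
#'   parameters passed to the component steps.
#' @return logical plant mask.
#' @export
segment_plant <- function(img, iterations = 5, gamma = 50, k = 5L,
                          dilate_radius = 5, clean_radius = 2, min_contrast = 8) {
  assert_rgb(img)
  lab <- rgb_to_lab(img)
  ta <- channel_trinary_mask(lab$a, "low", dilate_radius, min_contrast)
  tb <- channel_trinary_mask(lab$b, "high", dilate_radius, min_contrast)
  q <- combine_masks(ta, tb)
  if (!any(q == DEF_FG | q == PROB_FG))
    return(matrix(FALSE, nrow(q), ncol(q)))
  grabcut_refine(img, q, iterations = iterations, gamma = gamma, k = k,
                 clean_radius = clean_radius)
}

#' Affine colour-card correction
#'
#' Fits an affine colour transform (3x3 matrix plus offset) mapping observed
#' colour-card patch colours to their reference values by least squares, and
#' applies it to the image with clipping to `[0, 1]`.
#'
#' @param img RGB array.
#' @param observed,reference n x 3 matrices of patch colours in `[0, 1]`,
#'   n >= 4 and full rank.
#' @return colour-corrected RGB array.
#' @export
color_correct <- function(img, observed, reference) {
  assert_rgb(img)
  observed <- as.matrix(observed); reference <- as.matrix(reference)
  if (nrow(observed) < 4 || nrow(reference) != nrow(observed) ||
      ncol(observed) != 3 || ncol(reference) != 3)
    stop("need >= 4 patch pairs of RGB triples", call. = FALSE)
  X <- cbind(1, observed)
  qr_x <- qr(X)
  if (qr_x$rank < 4) stop("rank-deficient patch set", call. = FALSE)
  B <- qr.coef(qr_x, reference)           # 4 x 3: offset row then 3x3 matrix
  m <- matrix(img, ncol = 3L)
  out <- sweep(m %*% B[-1, , drop = FALSE], 2, B[1, ], `+`)
  array(clamp01(out), dim(img))
}
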