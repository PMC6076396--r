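#' Hand-crafted descriptors of a segmented plant
#'
#' The fixed 1056-element descriptor battery: 12 colour statistics, 8 shape
#' statistics, 1024 Fourier contour components (512 real + 512 imaginary) and
#' 12 GLCM texture statistics. See [extract_features()] for the layout.
#'
#' @name handcrafted-features
NULL

#' Colour statistics over the plant foreground
#'
#' Mean, max and min of each RGB channel plus the mean of each HSV channel,
#' all computed over foreground pixels only.
#'
#' @param img RGB array.
#' @param mask logical plant mask with at least one foreground pixel.
#' @return named numeric vector of length 12 (mean/max/min RGB, mean HSV).
#' @export
color_stats <- function(img, mask) {
  assert_rgb(img); assert_mask(mask, img)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  px <- cbind(img[, , 1][mask], img[, , 2][mask], img[, , 3][mask])
  hsv <- t(grDevices::rgb2hsv(t(px), maxColorValue = 1))
  out <- c(colMeans(px), apply(px, 2, max), apply(px, 2, min), colMeans(hsv))
  names(out) <- c(paste0("mean_", c("R", "G", "B")), paste0("max_", c("R", "G", "B")),
                  paste0("min_", c("R", "G", "B")), paste0("mean_", c("H", "S", "V")))
  out
}

# Outer boundary polylines (pixel centres, ordered) of every connected
# component of a mask; rows are (row, col), 1-based.
mask_contours <- function(mask) {
  lbl <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask)))
  k <- max(lbl)
  if (k == 0) return(list())
  oc <- EBImage::ocontour(lbl)
  lapply(oc, function(m) cbind(row = m[, 1] + 1, col = m[, 2] + 1))
}

# Closed-polyline length (unit steps and sqrt(2) diagonals along the trace).
contour_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  d <- rbind(diff(pts), pts[1, ] - pts[nrow(pts), ])
  sum(sqrt(rowSums(d^2)))
}

# Second central moments (covariance) of a uniform polygon region, by the
# standard shoelace extension; pts are the vertices in order.
polygon_covariance <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  ixx <- sum((y^2 + y * yn + yn^2) * cr) / 12
  iyy <- sum((x^2 + x * xn + xn^2) * cr) / 12
  ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  # central, normalised by signed area -> covariance of the uniform density
  # (signs cancel for either vertex orientation)
  m <- matrix(c(iyy / a - cx^2, ixy / a - cx * cy,
                ixy / a - cx * cy, ixx / a - cy^2), 2, 2)
  list(area = abs(a), cov = m)
}

#' Shape statistics of a plant mask
#'
#' Area (pixel count), perimeter (traced boundary length), roundness
#' (area/perimeter, following the convention used throughout this pipeline;
#' set `conventional_roundness = TRUE` for 4*pi*A/P^2), compactness
#' (area / convex-hull area), eccentricity (convex-hull major/minor axis-length
#' ratio, >= 1), the major and minor axis lengths of the ellipse with the same
#' second moments as the region, and extent (area / bounding-box area).
#'
#' The convex hull is taken over pixel corners so that a filled rectangle has
#' compactness exactly 1.
#'
#' @param mask logical plant mask with >= 3 foreground pixels spanning a
#'   non-degenerate (non-collinear) region.
#' @param conventional_roundness use 4*pi*A/P^2 instead of A/P.
#' @return named numeric vector of length 8.
#' @export
shape_stats <- function(mask, conventional_roundness = FALSE) {
  assert_mask(mask)
  area <- sum(mask)
  if (area < 3) stop("mask needs >= 3 foreground pixels", call. = FALSE)
  pix <- which(mask, arr.ind = TRUE)
  # pixel-corner cloud for the hull
  corners <- rbind(pix + matrix(c(-0.5, -0.5), area, 2, byrow = TRUE),
                   pix + matrix(c(-0.5,  0.5), area, 2, byrow = TRUE),
                   pix + matrix(c( 0.5, -0.5), area, 2, byrow = TRUE),
                   pix + matrix(c( 0.5,  0.5), area, 2, byrow = TRUE))
  hull <- corners[grDevices::chull(corners), , drop = FALSE]
  pc <- polygon_covariance(hull)
  hull_area <- pc$area
  ev <- eigen(pc$cov, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 1e-9) stop("degenerate (collinear) region", call. = FALSE)
  eccentricity <- sqrt(ev[1] / ev[2])
  # region second moments -> equivalent-ellipse axis lengths
  cv <- stats::cov(pix) * (area - 1) / area
  evr <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (evr[2] <= 1e-9) stop("degenerate (collinear) region", call. = FALSE)
  major_len <- 4 * sqrt(max(evr[1], 0))
  minor_len <- 4 * sqrt(max(evr[2], 0))
  perim <- sum(vapply(mask_contours(mask), contour_length, numeric(1)))
  if (perim <= 0) stop("degenerate contour", call. = FALSE)
  roundness <- if (conventional_roundness) 4 * pi * area / perim^2 else area / perim
  bbox <- (diff(range(pix[, 1])) + 1) * (diff(range(pix[, 2])) + 1)
  out <- c(area = area, perimeter = perim, roundness = roundness,
           compactness = area / hull_area, eccentricity = eccentricity,
           ellipse_major_len = major_len, ellipse_minor_len = minor_len,
           extent = area / bbox)
  out
}

#' Fourier descriptors of the plant contour
#'
#' The outer contour of the largest connected component is resampled to 512
#' points equally spaced in arc length, read as complex coordinates
#' `col + i*row`, and Fourier transformed. The zero-frequency (DC) coefficient
#' -- the translation carrier -- is set to zero, which makes the descriptor
#' translation invariant. The output is the 512 real parts followed by the 512
#' imaginary parts.
#'
#' @param mask logical plant mask with a closed outer contour.
#' @param n_points contour resampling count (default 512, giving the printed
#'   1024 output elements).
#' @return numeric vector of length `2 * n_points`.
#' @export
fourier_descriptors <- function(mask, n_points = 512L) {
  assert_mask(mask)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  lbl <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask)))
  sizes <- tabulate(lbl[lbl > 0])
  big <- which.max(sizes)
  cont <- mask_contours(lbl == big)[[1]]
  if (nrow(cont) < 2) stop("degenerate contour", call. = FALSE)
  closed <- rbind(cont, cont[1, , drop = FALSE])
  steps <- sqrt(rowSums(diff(closed)^2))
  cum <- c(0, cumsum(steps))
  total <- cum[length(cum)]
  if (total <= 0) stop("degenerate contour", call. = FALSE)
  s <- seq(0, total, length.out = n_points + 1L)[seq_len(n_points)]
  rr <- stats::approx(cum, closed[, 1], xout = s)$y
  cc <- stats::approx(cum, closed[, 2], xout = s)$y
  z <- complex(real = cc, imaginary = rr)
  f <- stats::fft(z)
  f[1] <- 0
  c(Re(f), Im(f))
}

#' GLCM texture statistics over the plant foreground
#'
#' Grey levels of foreground pixels are quantised to `n_levels` bins over the
#' foreground intensity range. One co-occurrence matrix is accumulated per
#' direction (0, 45, 90, 135 degrees; offset distance 1), counting only pairs
#' where both pixels are foreground; each matrix is symmetrised and normalised
#' to sum 1, and Energy (sum p^2), Contrast (sum (i-j)^2 p) and Homogeneity
#' (sum p / (1 + |i-j|)) are extracted.
#'
#' @param gray numeric matrix of grey values.
#' @param mask logical plant mask; must contain at least one valid
#'   co-occurring pair in some direction.
#' @param n_levels quantisation levels (default 32).
#' @return named numeric vector of length 12, direction-major:
#'   Energy/Contrast/Homogeneity at 0, 45, 90, 135 degrees.
#' @export
glcm_features <- function(gray, mask, n_levels = 32L) {
  if (!is.matrix(gray)) stop("`gray` must be a matrix", call. = FALSE)
  assert_mask(mask)
  if (sum(mask) < 2) stop("mask needs >= 2 foreground pixels", call. = FALSE)
  g <- gray[mask]
  rng <- range(g)
  q <- matrix(NA_integer_, nrow(gray), ncol(gray))
  if (diff(rng) == 0) {
    q[mask] <- 0L
  } else {
    q[mask] <- pmin(n_levels - 1L, as.integer(floor((gray[mask] - rng[1]) / diff(rng) * n_levels)))
  }
  h <- nrow(gray); w <- ncol(gray)
  # (drow, dcol) offsets for 0, 45, 90, 135 degrees in image coordinates
  offs <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  dir_names <- c("0", "45", "90", "135")
  out <- numeric(0)
  any_pairs <- FALSE
  for (d in seq_along(offs)) {
    dr <- offs[[d]][1]; dc <- offs[[d]][2]
    r1 <- max(1L, 1L - dr):min(h, h - dr)
    c1 <- max(1L, 1L - dc):min(w, w - dc)
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) {
      stats <- c(Energy = NA_real_, Contrast = NA_real_, Homogeneity = NA_real_)
    } else {
      any_pairs <- TRUE
      tab <- table(factor(a[ok], levels = 0:(n_levels - 1L)),
                   factor(b[ok], levels = 0:(n_levels - 1L)))
      p <- unclass(tab) + t(unclass(tab))
      p <- p / sum(p)
      ij <- outer(0:(n_levels - 1L), 0:(n_levels - 1L), `-`)
      stats <- c(Energy = sum(p^2), Contrast = sum(ij^2 * p),
                 Homogeneity = sum(p / (1 + abs(ij))))
    }
    names(stats) <- paste0(names(stats), "_", dir_names[d])
    out <- c(out, stats)
  }
  if (!any_pairs) stop("no valid foreground pairs in any direction", call. = FALSE)
  # a direction with no pairs on a sparse mask contributes the degenerate
  # single-cell values rather than NA, keeping the vector finite
  out[is.na(out)] <- rep(c(1, 0, 1), 4)[is.na(out)]
  out
}

#' Extract the full hand-crafted feature vector of one frame
#'
#' Fixed-layout concatenation: `color[12]`, `shape[8]`, `fourier[1024]`,
#' `glcm[12]` -- 1056 elements in total.
#'
#' @param img RGB array.
#' @param mask logical plant mask.
#' @param n_levels GLCM quantisation levels.
#' @return named numeric vector of length 1056.
#' @export
extract_features <- function(img, mask, n_levels = 32L) {
  col <- color_stats(img, mask)
  shp <- shape_stats(mask)
  fo <- fourier_descriptors(mask)
  names(fo) <- c(sprintf("fourier_re_%03d", 1:512), sprintf("fourier_im_%03d", 1:512))
  gl <- glcm_features(rgb_to_gray(img), mask, n_levels)
  c(setNames(col, paste0("color_", names(col))),
    setNames(shp, paste0("shape_", names(shp))),
    fo,
    setNames(gl, paste0("glcm_", names(gl))))
}

#' Per-frame feature table of a set of plant sequences
#'
#' Applies [extract_features()] to every frame of every sequence and returns a
#' tidy table (one row per frame). Frames whose mask has fewer than `min_area`
#' foreground pixels -- e.g. before germination or after a failed segmentation
#' -- are encoded as all-zero rows, a documented "plant absent" code that keeps
#' sequences rectangular.
#'
#' @param sequences list of [plant_sequence()] objects.
#' @param masks optional list (parallel to `sequences`) of lists of masks; by
#'   default the sequences' own `truth_masks` are used.
#' @param min_area minimum foreground pixel count for a frame to be featurised.
#' @return tibble with columns `plant_id`, `genotype`, `day` and 1056 feature
#'   columns.
#' @export
extract_features_table <- function(sequences, masks = NULL, min_area = 16L) {
  feat_names <- NULL
  rows <- vector("list", sum(vapply(sequences, function(s) length(s$frames), integer(1))))
  i <- 0L
  for (si in seq_along(sequences)) {
    sq <- sequences[[si]]
    mk <- if (is.null(masks)) sq$truth_masks else masks[[si]]
    if (is.null(mk)) stop("no masks available for plant ", sq$plant_id, call. = FALSE)
    for (j in seq_along(sq$frames)) {
      i <- i + 1L
      if (sum(mk[[j]]) >= min_area) {
        v <- extract_features(sq$frames[[j]], mk[[j]])
        if (is.null(feat_names)) feat_names <- names(v)
      } else {
        v <- NULL
      }
      rows[[i]] <- list(plant_id = sq$plant_id, genotype = sq$genotype,
                        day = sq$day_index[j], v = v)
    }
  }
  if (is.null(feat_names))
    stop("no frame had a mask with >= min_area pixels", call. = FALSE)
  mat <- t(vapply(rows, function(r) if (is.null(r$v)) numeric(1056) else r$v,
                  numeric(1056)))
  colnames(mat) <- feat_names
  dplyr::bind_cols(
    tibble::tibble(
      plant_id = vapply(rows, `[[`, character(1), "plant_id"),
      genotype = vapply(rows, `[[`, integer(1), "genotype"),
      day = vapply(rows, `[[`, integer(1), "day")),
    tibble::as_tibble(mat))
}
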