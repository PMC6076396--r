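#' Image and mask utilities
#'
#' Images are plain numeric arrays of dimension height x width x 3 with values
#' in `[0, 1]`; masks are logical (or 0/1) matrices of the same spatial size.
#' These helpers keep the rest of the package free of ad-hoc shape checks.
#'
#' @name image-utils
#' @keywords internal
NULL

assert_rgb <- function(img, arg = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(sprintf("`%s` must be a height x width x 3 RGB array", arg), call. = FALSE)
  invisible(img)
}

assert_mask <- function(mask, img = NULL, arg = "mask") {
  if (!is.matrix(mask))
    stop(sprintf("`%s` must be a matrix", arg), call. = FALSE)
  if (!is.null(img) && !all(dim(mask) == dim(img)[1:2]))
    stop(sprintf("`%s` must match the image spatial size", arg), call. = FALSE)
  invisible(mask)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Rotate a square image or mask by a multiple of 90 degrees
#'
#' Exact pixel permutation (no interpolation), counter-clockwise.
#'
#' @param x a matrix or an H x W x C array; H must equal W.
#' @param k number of quarter turns (0-3).
#' @return the rotated object, same type and dimensions.
#' @export
rotate90 <- function(x, k = 1L) {
  k <- as.integer(k) %% 4L
  d <- dim(x)
  if (d[1] != d[2]) stop("rotate90() requires a square image", call. = FALSE)
  if (k == 0L) return(x)
  rot_mat <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  if (is.matrix(x)) {
    for (i in seq_len(k)) x <- rot_mat(x)
    return(x)
  }
  out <- x
  for (i in seq_len(k)) {
    nxt <- array(0, dim(out))
    for (ch in seq_len(dim(out)[3])) nxt[, , ch] <- rot_mat(out[, , ch])
    out <- nxt
  }
  out
}

# Bilinear resize to side x side via EBImage (channel layout preserved).
resize_image <- function(img, side) {
  assert_rgb(img)
  out <- EBImage::resize(img, w = side, h = side)
  array(as.numeric(out), c(side, side, 3L))
}

# RGB [0,1] H x W x 3 -> list of L, a, b channel matrices (CIE Lab, D65).
rgb_to_lab <- function(img) {
  assert_rgb(img)
  d <- dim(img)
  m <- matrix(img, ncol = 3L)  # columns R, G, B
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  list(L = matrix(lab[, 1], d[1], d[2]),
       a = matrix(lab[, 2], d[1], d[2]),
       b = matrix(lab[, 3], d[1], d[2]))
}

# Standard luminance grey conversion (Rec. 601 weights).
rgb_to_gray <- function(img) {
  assert_rgb(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Read / write frames and masks as PNG
#'
#' Masks are written as 8-bit greyscale PNGs with values 0/255 and read back as
#' logical matrices; quaternary seed masks use levels 0-3.
#'
#' @param path file path.
#' @param img,mask objects to write.
#' @return `read_frame()` an RGB array; `read_mask()` a logical matrix.
#' @name png-io
NULL

#' @rdname png-io
#' @export
read_frame <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' @rdname png-io
#' @export
write_frame <- function(img, path) {
  assert_rgb(img)
  png::writePNG(clamp01(img), path)
  invisible(path)
}

#' @rdname png-io
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}

#' @rdname png-io
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname png-io
#' @export
write_quaternary <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask) / 255, nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b logical matrices of equal size.
#' @return IoU in `[0, 1]`; defined as 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
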