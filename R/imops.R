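# Low-level image operations shared by the phantom generator, augmentation
# and radiomics filters. Images are plain numeric matrices, rows = image
# height (top row first), columns = width. 8-bit images hold values 0..255.

#' Min-max rescale a matrix to 8-bit gray levels
#'
#' A constant input maps to 0 everywhere (the degenerate-range convention
#' used throughout the package).
#'
#' @param img Numeric matrix.
#' @return Matrix of integers 0..255 (stored as numeric).
#' @export
rescale_8bit <- function(img) {
  rng <- range(img)
  if (!all(is.finite(rng))) abort("image contains non-finite values")
  if (rng[2] == rng[1]) return(matrix(0, nrow(img), ncol(img)))
  round((img - rng[1]) / (rng[2] - rng[1]) * 255)
}

# Rescale to [0, 1]; constant input maps to 0.
rescale01 <- function(img) {
  rng <- range(img)
  if (rng[2] == rng[1]) return(matrix(0, nrow(img), ncol(img)))
  (img - rng[1]) / (rng[2] - rng[1])
}

# Whole-sample symmetric reflection of indices into 1..n
# (..., 3, 2, 1, 2, 3, ..., n-1, n, n-1, ...).
reflect_index <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  m <- (i - 1L) %% p  # non-negative for positive p
  m <- ifelse(m > (n - 1L), p - m, m)
  as.integer(m + 1L)
}

# Separable convolution with symmetric boundary handling.
conv_sep <- function(img, kr, kc = kr) {
  out <- img
  # rows (vertical pass)
  nr <- nrow(out)
  half <- (length(kr) - 1L) / 2L
  acc <- matrix(0, nr, ncol(out))
  for (t in seq_along(kr)) {
    off <- t - 1L - half
    acc <- acc + kr[t] * out[reflect_index(seq_len(nr) + off, nr), , drop = FALSE]
  }
  out <- acc
  # cols (horizontal pass)
  nc <- ncol(out)
  half <- (length(kc) - 1L) / 2L
  acc <- matrix(0, nrow(out), nc)
  for (t in seq_along(kc)) {
    off <- t - 1L - half
    acc <- acc + kc[t] * out[, reflect_index(seq_len(nc) + off, nc), drop = FALSE]
  }
  acc
}

gaussian_kernel <- function(sigma) {
  half <- max(1L, ceiling(3 * sigma))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian smoothing with symmetric boundaries
#'
#' @param img Numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return Smoothed matrix, same size.
#' @export
gaussian_blur <- function(img, sigma) {
  conv_sep(img, gaussian_kernel(sigma))
}

# Laplacian of Gaussian response (not rescaled).
log_response <- function(img, sigma) {
  g <- gaussian_blur(img, sigma)
  nr <- nrow(g); nc <- ncol(g)
  up <- g[reflect_index(seq_len(nr) - 1L, nr), , drop = FALSE]
  dn <- g[reflect_index(seq_len(nr) + 1L, nr), , drop = FALSE]
  lf <- g[, reflect_index(seq_len(nc) - 1L, nc), drop = FALSE]
  rt <- g[, reflect_index(seq_len(nc) + 1L, nc), drop = FALSE]
  up + dn + lf + rt - 4 * g
}

# Sobel gradient components (symmetric boundaries). Returns list(gx, gy).
sobel_gradients <- function(img) {
  sm <- c(1, 2, 1); df <- c(-1, 0, 1)
  list(
    gx = conv_sep(img, kr = sm, kc = df),
    gy = conv_sep(img, kr = df, kc = sm)
  )
}

# Sobel gradient magnitude.
sobel_magnitude <- function(img) {
  g <- sobel_gradients(img)
  sqrt(g$gx^2 + g$gy^2)
}

# Uniform rotation-invariant local binary pattern, radius 1 / 8 neighbors.
# Output values are 0..9 (pattern codes): 0..8 = number of "on" bits for
# uniform patterns, 9 = non-uniform.
lbp_uniform <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  bits <- vector("list", 8L)
  for (t in seq_along(offs)) {
    o <- offs[[t]]
    nb <- img[reflect_index(seq_len(nr) + o[1], nr),
              reflect_index(seq_len(nc) + o[2], nc), drop = FALSE]
    bits[[t]] <- (nb >= img) * 1
  }
  transitions <- matrix(0, nr, nc)
  ones <- matrix(0, nr, nc)
  for (t in seq_along(bits)) {
    nxt <- bits[[if (t == 8L) 1L else t + 1L]]
    transitions <- transitions + (bits[[t]] != nxt)
    ones <- ones + bits[[t]]
  }
  out <- ones
  out[transitions > 2] <- 9
  out
}

#' Bilinear image resize
#'
#' @param img Numeric matrix.
#' @param out_h,out_w Output height and width in pixels.
#' @return Resized matrix.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  nr <- nrow(img); nc <- ncol(img)
  if (out_h == nr && out_w == nc) return(img)
  # map output pixel centers onto input pixel-center coordinates
  ry <- (seq_len(out_h) - 0.5) * nr / out_h + 0.5 - 0.5
  rx <- (seq_len(out_w) - 0.5) * nc / out_w + 0.5 - 0.5
  interp_grid(img, ry, rx)
}

# Bilinear sample img at the grid defined by row coords ry and col coords rx
# (1-based, fractional). Out-of-range coordinates are reflected.
interp_grid <- function(img, ry, rx) {
  nr <- nrow(img); nc <- ncol(img)
  y0 <- floor(ry); x0 <- floor(rx)
  fy <- ry - y0; fx <- rx - x0
  y0i <- reflect_index(as.integer(y0), nr)
  y1i <- reflect_index(as.integer(y0) + 1L, nr)
  x0i <- reflect_index(as.integer(x0), nc)
  x1i <- reflect_index(as.integer(x0) + 1L, nc)
  a <- img[y0i, x0i, drop = FALSE]; b <- img[y0i, x1i, drop = FALSE]
  d <- img[y1i, x0i, drop = FALSE]; e <- img[y1i, x1i, drop = FALSE]
  wfy <- matrix(fy, length(ry), length(rx))
  wfx <- matrix(fx, length(ry), length(rx), byrow = TRUE)
  (1 - wfy) * ((1 - wfx) * a + wfx * b) + wfy * ((1 - wfx) * d + wfx * e)
}

# Bilinear sample at arbitrary (possibly scattered) coordinates.
interp_points <- function(img, ry, rx) {
  nr <- nrow(img); nc <- ncol(img)
  y0 <- floor(ry); x0 <- floor(rx)
  fy <- ry - y0; fx <- rx - x0
  y0i <- reflect_index(as.integer(y0), nr)
  y1i <- reflect_index(as.integer(y0) + 1L, nr)
  x0i <- reflect_index(as.integer(x0), nc)
  x1i <- reflect_index(as.integer(x0) + 1L, nc)
  a <- img[cbind(y0i, x0i)]; b <- img[cbind(y0i, x1i)]
  d <- img[cbind(y1i, x0i)]; e <- img[cbind(y1i, x1i)]
  (1 - fy) * ((1 - fx) * a + fx * b) + fy * ((1 - fx) * d + fx * e)
}

# Warp an image through a 2x2 linear map A about the frame center using
# inverse mapping + bilinear interpolation; vacated pixels are filled by
# symmetric reflection. `A` maps source coords to destination coords in
# (x, y) order; translation `t` (in pixels, (dx, dy)) is applied after A.
warp_linear <- function(img, A, t = c(0, 0), nearest = FALSE) {
  nr <- nrow(img); nc <- ncol(img)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  Ai <- solve(A)
  dst <- expand.grid(y = seq_len(nr), x = seq_len(nc))
  dx <- dst$x - cx - t[1]
  dy <- dst$y - cy - t[2]
  sx <- Ai[1, 1] * dx + Ai[1, 2] * dy + cx
  sy <- Ai[2, 1] * dx + Ai[2, 2] * dy + cy
  vals <- if (nearest) {
    img[cbind(reflect_index(as.integer(round(sy)), nr),
              reflect_index(as.integer(round(sx)), nc))]
  } else {
    interp_points(img, sy, sx)
  }
  matrix(vals, nr, nc)
}

# Integer translation with symmetric reflection fill. dx > 0 shifts right,
# dy > 0 shifts down.
translate_reflect <- function(img, dx, dy) {
  nr <- nrow(img); nc <- ncol(img)
  img[reflect_index(seq_len(nr) - as.integer(dy), nr),
      reflect_index(seq_len(nc) - as.integer(dx), nc), drop = FALSE]
}
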