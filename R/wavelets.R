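# Single-level 2D discrete wavelet transforms (decimated and undecimated)
# over periodized signals, for orthogonal wavelets. Used for despeckling,
# the UDWT augmentation scenario and the wavelet radiomics image types.

# Orthonormal analysis filters (decomposition low/high pass). Coiflet
# coefficients follow the standard published values (verified against
# PyWavelets 1.9.0 to full double precision).
.wavelet_filters <- list(
  haar = list(
    dec_lo = c(0.7071067811865476, 0.7071067811865476),
    dec_hi = c(-0.7071067811865476, 0.7071067811865476)
  ),
  coif1 = list(
    dec_lo = c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
               0.8525720202116004, 0.3378976624574818, -0.07273261951252645),
    dec_hi = c(0.07273261951252645, 0.3378976624574818, -0.8525720202116004,
               0.3848648468648578, 0.07273261951252645, -0.015655728135791993)
  ),
  coif2 = list(
    dec_lo = c(-0.000720549445520347, -0.0018232088709110323,
               0.005611434819368834, 0.02368017194684777, -0.05943441864643109,
               -0.07648859907828076, 0.4170051844232391, 0.8127236354494135,
               0.3861100668227629, -0.0673725547237256, -0.04146493678687178,
               0.01638733646320364),
    dec_hi = c(-0.01638733646320364, -0.04146493678687178, 0.0673725547237256,
               0.3861100668227629, -0.8127236354494135, 0.4170051844232391,
               0.07648859907828076, -0.05943441864643109, -0.02368017194684777,
               0.005611434819368834, 0.0018232088709110323,
               -0.000720549445520347)
  )
)

#' Supported wavelet names
#' @return Character vector of wavelet family names usable across the package.
#' @export
wavelet_names <- function() names(.wavelet_filters)

get_wavelet <- function(name) {
  f <- .wavelet_filters[[name]]
  if (is.null(f)) {
    abort(sprintf("unknown wavelet '%s'; supported: %s",
                  name, paste(wavelet_names(), collapse = ", ")))
  }
  f
}

# Cache of orthogonal single-level analysis matrices keyed by "n:wavelet".
.wavelet_cache <- new.env(parent = emptyenv())

# n x n orthogonal matrix whose first n/2 rows are even circular shifts of
# the synthesis scaling filter and last n/2 rows of the synthesis wavelet
# filter; analysis is W %*% x, perfect reconstruction is t(W) %*% y.
wavelet_matrix <- function(n, wavelet) {
  key <- paste0(n, ":", wavelet)
  got <- .wavelet_cache[[key]]
  if (!is.null(got)) return(got)
  if (n %% 2 != 0) abort("periodized DWT needs an even length")
  f <- get_wavelet(wavelet)
  g <- rev(f$dec_lo)   # synthesis scaling filter
  gh <- rev(f$dec_hi)  # synthesis wavelet filter
  L <- length(g)
  if (n < L) abort(sprintf("signal length %d shorter than wavelet filter", n))
  W <- matrix(0, n, n)
  half <- n / 2L
  for (k in 0:(half - 1L)) {
    pos <- ((2L * k + 0:(L - 1L)) %% n) + 1L
    W[k + 1L, pos] <- W[k + 1L, pos] + g
    W[half + k + 1L, pos] <- W[half + k + 1L, pos] + gh
  }
  .wavelet_cache[[key]] <- W
  W
}

#' Single-level 2D discrete wavelet transform
#'
#' Periodized orthogonal transform. Odd-sized inputs are reflected by one
#' row/column to an even size (recorded so [idwt2()] can undo it).
#'
#' @param img Numeric matrix.
#' @param wavelet One of [wavelet_names()].
#' @return List with subband matrices `LL`, `LH`, `HL`, `HH` and the padding
#'   bookkeeping needed for exact inversion.
#' @export
dwt2 <- function(img, wavelet = "coif1") {
  orig <- dim(img)
  pr <- nrow(img) %% 2L; pc <- ncol(img) %% 2L
  if (pr) img <- rbind(img, img[nrow(img), , drop = FALSE])
  if (pc) img <- cbind(img, img[, ncol(img), drop = FALSE])
  nr <- nrow(img); nc <- ncol(img)
  Wr <- wavelet_matrix(nr, wavelet)
  Wc <- wavelet_matrix(nc, wavelet)
  Y <- Wr %*% img %*% t(Wc)
  hr <- nr / 2L; hc <- nc / 2L
  list(
    LL = Y[1:hr, 1:hc, drop = FALSE],
    LH = Y[1:hr, (hc + 1):nc, drop = FALSE],
    HL = Y[(hr + 1):nr, 1:hc, drop = FALSE],
    HH = Y[(hr + 1):nr, (hc + 1):nc, drop = FALSE],
    wavelet = wavelet, padded = c(pr, pc), orig_dim = orig
  )
}

#' Inverse of [dwt2()]
#'
#' @param dec List returned by [dwt2()].
#' @return Reconstructed matrix with the original dimensions.
#' @export
idwt2 <- function(dec) {
  Y <- rbind(cbind(dec$LL, dec$LH), cbind(dec$HL, dec$HH))
  nr <- nrow(Y); nc <- ncol(Y)
  Wr <- wavelet_matrix(nr, dec$wavelet)
  Wc <- wavelet_matrix(nc, dec$wavelet)
  X <- t(Wr) %*% Y %*% Wc
  X[seq_len(dec$orig_dim[1]), seq_len(dec$orig_dim[2]), drop = FALSE]
}

# Circular 1D convolution along rows or cols via shifted accumulation.
circ_filter <- function(img, taps, along = c("rows", "cols")) {
  along <- match.arg(along)
  n <- if (along == "rows") nrow(img) else ncol(img)
  acc <- matrix(0, nrow(img), ncol(img))
  for (j in seq_along(taps)) {
    off <- j - 1L
    idx <- ((seq_len(n) - 1L + off) %% n) + 1L
    acc <- acc + taps[j] * (if (along == "rows") img[idx, , drop = FALSE]
                            else img[, idx, drop = FALSE])
  }
  acc
}

#' Single-level undecimated (stationary) 2D wavelet transform
#'
#' Shift-invariant decomposition without downsampling; all four subbands
#' have the size of the input. Periodic boundary handling.
#'
#' @param img Numeric matrix.
#' @param wavelet One of [wavelet_names()].
#' @return List with subband matrices `LL`, `LH`, `HL`, `HH`.
#' @export
udwt2 <- function(img, wavelet = "coif2") {
  f <- get_wavelet(wavelet)
  lo_r <- circ_filter(img, f$dec_lo, "rows")
  hi_r <- circ_filter(img, f$dec_hi, "rows")
  list(
    LL = circ_filter(lo_r, f$dec_lo, "cols"),
    LH = circ_filter(lo_r, f$dec_hi, "cols"),
    HL = circ_filter(hi_r, f$dec_lo, "cols"),
    HH = circ_filter(hi_r, f$dec_hi, "cols")
  )
}

#' Wavelet despeckling of an 8-bit image
#'
#' Single-level DWT, soft thresholding of the detail subbands at the
#' universal threshold `sigma * sqrt(2 log n)` (noise scale estimated from
#' the median absolute deviation of the diagonal subband), inverse
#' transform, and re-quantization to 8-bit. The approximation subband is
#' never thresholded.
#'
#' @param img 8-bit grayscale matrix.
#' @param wavelet One of [wavelet_names()] (default `"coif1"`).
#' @return Despeckled 8-bit matrix of the same size.
#' @export
despeckle_dwt <- function(img, wavelet = "coif1") {
  dec <- dwt2(img, wavelet)
  sigma <- median(abs(dec$HH)) / 0.6745
  thr <- sigma * sqrt(2 * log(length(img)))
  soft <- function(m) sign(m) * pmax(abs(m) - thr, 0)
  dec$LH <- soft(dec$LH); dec$HL <- soft(dec$HL); dec$HH <- soft(dec$HH)
  out <- idwt2(dec)
  round(pmin(pmax(out, 0), 255))
}
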