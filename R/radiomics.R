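# Native 2D radiomics: intensity discretization, the five gray-level
# texture matrices (GLCM, GLRLM, GLSZM, GLDM, NGTDM), first-order
# statistics, and extraction over a configurable stack of filtered image
# derivatives. Feature definitions follow the standard radiomics
# conventions for 2D regions; every feature has a defined finite limit on
# degenerate (single-level) regions.

#' Radiomics extraction configuration
#'
#' The default image-type stack has 11 entries (original, five pointwise
#' derivatives, Laplacian-of-Gaussian, gradient magnitude, local binary
#' pattern, and the three stationary-wavelet detail subbands), which with
#' the 93 features per type yields 1023 features per image-mask pair.
#' Shape/morphology features are deliberately not part of the feature
#' space (the signatures must be extractable from a plain box).
#'
#' @param bin_width Discretization bin width in gray levels (default 25).
#' @param wavelet Wavelet for the subband image types (default `"coif1"`).
#' @param log_sigma Laplacian-of-Gaussian scale in pixels (default 3).
#' @param image_types Ordered subset of [radiomics_image_types()].
#' @param classes Ordered subset of [radiomics_classes()].
#' @return A `radiomics_config` list.
#' @export
radiomics_config <- function(bin_width = 25, wavelet = "coif1", log_sigma = 3,
                             image_types = radiomics_image_types(),
                             classes = radiomics_classes()) {
  stopifnot(bin_width > 0)
  image_types <- match.arg(image_types, radiomics_image_types(),
                           several.ok = TRUE)
  classes <- match.arg(classes, radiomics_classes(), several.ok = TRUE)
  structure(list(bin_width = bin_width, wavelet = wavelet,
                 log_sigma = log_sigma, image_types = image_types,
                 classes = classes),
            class = "radiomics_config")
}

#' @rdname radiomics_config
#' @export
radiomics_image_types <- function() {
  c("original", "LoG", "squared", "squareroot", "logarithm", "exponential",
    "gradient", "lbp", "wavelet_LH", "wavelet_HL", "wavelet_HH")
}

#' @rdname radiomics_config
#' @export
radiomics_classes <- function() {
  c("firstorder", "glcm", "glrlm", "glszm", "gldm", "ngtdm")
}

# Number of features per class (fixed sets).
class_feature_counts <- function() {
  c(firstorder = 18L, glcm = 24L, glrlm = 16L, glszm = 16L, gldm = 14L,
    ngtdm = 5L)
}

#' Derived image stack for radiomics extraction
#'
#' Filters are applied to the full frame (so tissue context around the ROI
#' enters the filtered values) and each derivative is min-max rescaled to
#' 8-bit. Wavelet types use the stationary (undecimated) transform so the
#' subbands stay pixel-aligned with the mask.
#'
#' @param image 8-bit matrix.
#' @param config A [radiomics_config()].
#' @return Named list of 8-bit matrices, one per configured image type.
#' @export
image_type_stack <- function(image, config = radiomics_config()) {
  types <- config$image_types
  need_wavelet <- any(grepl("^wavelet_", types))
  wv <- if (need_wavelet) udwt2(image, config$wavelet) else NULL
  x01 <- rescale01(image)
  out <- lapply(types, function(ty) {
    switch(ty,
      original = image,
      LoG = rescale_8bit(log_response(image, config$log_sigma)),
      squared = rescale_8bit(x01^2),
      squareroot = rescale_8bit(sqrt(x01)),
      logarithm = rescale_8bit(log1p(x01)),
      exponential = rescale_8bit(exp(x01)),
      gradient = rescale_8bit(sobel_magnitude(image)),
      lbp = rescale_8bit(lbp_uniform(image)),
      wavelet_LH = rescale_8bit(wv$LH),
      wavelet_HL = rescale_8bit(wv$HL),
      wavelet_HH = rescale_8bit(wv$HH),
      abort(sprintf("image-type filter '%s' failed: unknown type", ty))
    )
  })
  names(out) <- types
  out
}

#' Discretize ROI intensities into gray levels
#'
#' `level(p) = floor((I(p) - min_ROI) / bin_width) + 1`, giving levels
#' `1..Ng` inside the mask and `NA` outside.
#'
#' @param image Numeric matrix.
#' @param mask Logical matrix, same size, nonempty.
#' @param bin_width Bin width in intensity units.
#' @return List with `levels` (matrix, NA outside mask) and `ng`.
#' @export
discretize <- function(image, mask, bin_width = 25) {
  if (!any(mask)) abort("empty mask: nothing to discretize")
  lo <- min(image[mask])
  lv <- matrix(NA_real_, nrow(image), ncol(image))
  lv[mask] <- floor((image[mask] - lo) / bin_width) + 1
  list(levels = lv, ng = max(lv, na.rm = TRUE))
}

# Crop a levels matrix to the mask bounding box (all texture statistics are
# translation invariant, so this only saves work).
crop_levels <- function(lv) {
  idx <- which(!is.na(lv), arr.ind = TRUE)
  r <- range(idx[, 1]); c <- range(idx[, 2])
  lv[r[1]:r[2], c[1]:c[2], drop = FALSE]
}

# ---- texture matrices -------------------------------------------------------

.offsets2d <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))

# Safe integer range: empty when lo > hi (avoids the descending 1:0 trap).
seq2 <- function(lo, hi) if (lo > hi) integer(0) else lo:hi

# Pair counts between lv and its (dr,dc)-shifted copy, in-mask pairs only,
# as an Ng x Ng matrix (not symmetrized).
pair_counts <- function(lv, ng, dr, dc) {
  nr <- nrow(lv); nc <- ncol(lv)
  r1 <- seq2(max(1L, 1L - dr), min(nr, nr - dr))
  c1 <- seq2(max(1L, 1L - dc), min(nc, nc - dc))
  if (length(r1) == 0 || length(c1) == 0) return(matrix(0, ng, ng))
  a <- lv[r1, c1, drop = FALSE]
  b <- lv[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(matrix(0, ng, ng))
  idx <- (a[ok] - 1) * ng + b[ok]
  matrix(tabulate(idx, nbins = ng * ng), ng, ng, byrow = TRUE)
}

#' Gray-level texture matrices of a discretized ROI
#'
#' * `GLCM`: symmetric co-occurrence counts at distance 1, one matrix per
#'   2D direction (0, 45, 90, 135 degrees).
#' * `GLRLM`: run-length counts per direction; out-of-mask pixels break
#'   runs.
#' * `GLSZM`: zone sizes of 8-connected equal-level regions (single
#'   matrix).
#' * `GLDM`: gray level x dependence counts (8-neighborhood, equal-level
#'   dependence, the center pixel counted so dependence >= 1).
#' * `NGTDM`: per-level counts `n_i` and summed absolute differences `s_i`
#'   from the mean of valid neighbors.
#'
#' @param levels Discretized matrix as from [discretize()] (`$levels`).
#' @param kind One of `"GLCM"`, `"GLRLM"`, `"GLSZM"`, `"GLDM"`, `"NGTDM"`.
#' @param ng Number of gray levels (defaults to the max level present).
#' @return For GLCM/GLRLM a list of per-direction matrices; for GLSZM/GLDM
#'   a single matrix (rows = gray level); for NGTDM a data frame with
#'   columns `level`, `n`, `s`.
#' @export
texture_matrix <- function(levels, kind, ng = max(levels, na.rm = TRUE)) {
  kind <- match.arg(kind, c("GLCM", "GLRLM", "GLSZM", "GLDM", "NGTDM"))
  lv <- crop_levels(levels)
  switch(kind,
    GLCM = lapply(.offsets2d, function(o) {
      m <- pair_counts(lv, ng, o[1], o[2])
      m + t(m)
    }),
    GLRLM = glrlm_matrices(lv, ng),
    GLSZM = glszm_matrix(lv, ng),
    GLDM = gldm_matrix(lv, ng),
    NGTDM = ngtdm_table(lv, ng)
  )
}

# Run-length matrices for the four 2D directions.
glrlm_matrices <- function(lv, ng) {
  nr <- nrow(lv); nc <- ncol(lv)
  seqs_for <- function(dir) {
    switch(dir,
      h = split(lv, row(lv)),
      v = split(lv, col(lv)),
      d1 = split(lv, row(lv) - col(lv)),   # 45 degrees
      d2 = split(lv, row(lv) + col(lv))    # 135 degrees
    )
  }
  max_run <- max(nr, nc)
  lapply(c("h", "v", "d1", "d2"), function(dir) {
    vals <- integer(0); lens <- integer(0)
    for (s in seqs_for(dir)) {
      r <- rle(as.vector(s))
      keep <- !is.na(r$values)
      if (!any(keep)) next
      vals <- c(vals, r$values[keep])
      lens <- c(lens, r$lengths[keep])
    }
    R <- matrix(0, ng, max_run)
    if (length(vals) > 0) {
      cnt <- tabulate((vals - 1L) * max_run + lens, nbins = ng * max_run)
      R <- matrix(cnt, ng, max_run, byrow = TRUE)
    }
    # trim trailing all-zero run lengths
    last <- max(c(1L, which(colSums(R) > 0)))
    R[, seq_len(last), drop = FALSE]
  })
}

# Zone-size matrix: 8-connected components of equal level.
glszm_matrix <- function(lv, ng) {
  nr <- nrow(lv); nc <- ncol(lv)
  lab <- matrix(seq_len(nr * nc), nr, nc)
  lab[is.na(lv)] <- NA
  shifts <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                 c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  repeat {
    new <- lab
    for (s in shifts) {
      rs <- s[1]; cs <- s[2]
      r1 <- seq2(max(1, 1 - rs), min(nr, nr - rs))
      c1 <- seq2(max(1, 1 - cs), min(nc, nc - cs))
      if (length(r1) == 0 || length(c1) == 0) next
      a <- lv[r1, c1, drop = FALSE]
      b <- lv[r1 + rs, c1 + cs, drop = FALSE]
      la <- new[r1, c1, drop = FALSE]
      lb <- new[r1 + rs, c1 + cs, drop = FALSE]
      same <- !is.na(a) & !is.na(b) & a == b & lb < la
      if (any(same)) la[same] <- lb[same]
      new[r1, c1] <- la
    }
    # pointer jumping: labels are flat indices, so chasing label chains
    # compresses whole zones in O(log diameter) sweeps
    v <- as.vector(new)
    ok <- which(!is.na(v))
    repeat {
      v2 <- v
      v2[ok] <- v[v[ok]]
      if (identical(v2, v)) break
      v <- v2
    }
    new <- matrix(v, nr, nc)
    if (identical(new, lab)) break
    lab <- new
  }
  ok <- !is.na(lab)
  zones <- table(lab[ok])
  zlevel <- lv[ok][match(as.integer(names(zones)), lab[ok])]
  max_size <- max(as.integer(zones))
  S <- matrix(0, ng, max_size)
  for (k in seq_along(zones)) {
    S[zlevel[k], zones[k]] <- S[zlevel[k], zones[k]] + 1
  }
  S
}

# Count equal-level in-mask neighbors for every in-mask pixel.
neighbor_stats <- function(lv) {
  nr <- nrow(lv); nc <- ncol(lv)
  shifts <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                 c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  eq <- matrix(0, nr, nc)     # equal-level neighbors
  nsum <- matrix(0, nr, nc)   # sum of neighbor levels
  ncnt <- matrix(0, nr, nc)   # number of valid neighbors
  for (s in shifts) {
    rs <- s[1]; cs <- s[2]
    nb <- matrix(NA_real_, nr, nc)
    r1 <- seq2(max(1, 1 - rs), min(nr, nr - rs))
    c1 <- seq2(max(1, 1 - cs), min(nc, nc - cs))
    if (length(r1) == 0 || length(c1) == 0) next
    nb[r1, c1] <- lv[r1 + rs, c1 + cs]
    valid <- !is.na(nb)
    eq <- eq + (valid & !is.na(lv) & nb == lv & !is.na(lv))
    nsum[valid] <- nsum[valid] + nb[valid]
    ncnt <- ncnt + valid
  }
  list(eq = eq, nsum = nsum, ncnt = ncnt)
}

# Gray level x dependence matrix (alpha = 0, distance 1; dependence
# includes the center pixel, so columns index 1..9).
gldm_matrix <- function(lv, ng) {
  st <- neighbor_stats(lv)
  ok <- !is.na(lv)
  dep <- st$eq[ok] + 1
  lev <- lv[ok]
  idx <- (lev - 1) * 9 + dep
  cnt <- tabulate(idx, nbins = ng * 9)
  D <- matrix(cnt, ng, 9, byrow = TRUE)
  last <- max(c(1L, which(colSums(D) > 0)))
  D[, seq_len(last), drop = FALSE]
}

# Neighborhood gray-tone difference table.
ngtdm_table <- function(lv, ng) {
  st <- neighbor_stats(lv)
  ok <- !is.na(lv) & st$ncnt > 0
  lev <- lv[ok]
  abar <- st$nsum[ok] / st$ncnt[ok]
  d <- abs(lev - abar)
  n_i <- tabulate(lev, nbins = ng)
  s_i <- numeric(ng)
  agg <- rowsum(d, group = lev)
  s_i[as.integer(rownames(agg))] <- agg[, 1]
  data.frame(level = seq_len(ng), n = n_i, s = s_i)
}

# ---- feature formulas -------------------------------------------------------

.eps <- 2.220446e-16

entropy2 <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0) return(0)
  -sum(p * log2(p))
}

firstorder_features <- function(intens, levels_vec) {
  x <- intens
  n <- length(x)
  m <- mean(x)
  v <- mean((x - m)^2)
  q <- quantile(x, c(0.10, 0.25, 0.5, 0.75, 0.90), names = FALSE, type = 7)
  mid <- x[x >= q[1] & x <= q[5]]
  hist_p <- tabulate(levels_vec) / n
  m2 <- v
  skew <- if (m2 > 0) mean((x - m)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - m)^4) / m2^2 else 0
  c(
    Energy = sum(x^2),
    TotalEnergy = sum(x^2),
    Entropy = entropy2(hist_p),
    Minimum = min(x),
    Percentile10 = q[1],
    Percentile90 = q[5],
    Maximum = max(x),
    Mean = m,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - m)),
    RobustMeanAbsoluteDeviation =
      if (length(mid) > 0) mean(abs(mid - mean(mid))) else 0,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = skew,
    Kurtosis = kurt,
    Variance = v,
    Uniformity = sum(hist_p^2)
  )
}

glcm_features_one <- function(P) {
  tot <- sum(P)
  if (tot == 0) P <- P + 1 / length(P) else P <- P / tot
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(i * P); muy <- sum(j * P)
  sigx <- sqrt(sum((i - mux)^2 * P)); sigy <- sqrt(sum((j - muy)^2 * P))
  # p_{x+y} over k = 2..2Ng and p_{x-y} over k = 0..Ng-1
  ksum <- as.vector(i + j); kdiff <- as.vector(abs(i - j))
  psum <- rowsum(as.vector(P), ksum)[, 1]
  ks <- sort(unique(ksum))
  pdiff_all <- rowsum(as.vector(P), kdiff)[, 1]
  kd <- sort(unique(kdiff))
  da <- sum(kd * pdiff_all)
  HX <- entropy2(px); HY <- entropy2(py); HXY <- entropy2(as.vector(P))
  pxy <- outer(px, py)
  HXY1 <- -sum(P * log2(pxy + .eps))
  HXY2 <- -sum(pxy[pxy > 0] * log2(pxy[pxy > 0]))
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0))
  corr <- if (sigx > 0 && sigy > 0) {
    (sum(i * j * P) - mux * muy) / (sigx * sigy)
  } else 1
  mcc <- if (ng == 1) 1 else {
    nzk <- py > 0
    B <- P[, nzk, drop = FALSE] /
      matrix(py[nzk], ng, sum(nzk), byrow = TRUE)
    Q <- B %*% t(P[, nzk, drop = FALSE])
    nzr <- px > 0
    Q[nzr, ] <- Q[nzr, , drop = FALSE] / px[nzr]
    Q[!nzr, ] <- 0
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    if (length(ev) < 2) 1 else sqrt(max(min(ev[2], 1), 0))
  }
  offdiag <- i != j
  c(
    Autocorrelation = sum(i * j * P),
    JointAverage = mux,
    ClusterProminence = sum((i + j - mux - muy)^4 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterTendency = sum((i + j - mux - muy)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = entropy2(pdiff_all),
    DifferenceVariance = sum((kd - da)^2 * pdiff_all),
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + ((i - j) / ng)^2)),
    Id = sum(P / (1 + abs(i - j))),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    InverseVariance = sum(P[offdiag] / (i[offdiag] - j[offdiag])^2),
    MaximumProbability = max(P),
    SumAverage = sum(ks * psum),
    SumEntropy = entropy2(psum),
    SumSquares = sum((i - mux)^2 * P),
    MCC = mcc
  )
}

# Shared size-weighted features for run-length (GLRLM) and size-zone
# (GLSZM) style matrices M (rows = gray level, cols = run length / size).
rl_style_features <- function(M, n_pixels, axis_names) {
  nr_ <- sum(M)
  if (nr_ == 0) M[1, 1] <- nr_ <- 1
  ng <- nrow(M); nl <- ncol(M)
  i <- matrix(seq_len(ng), ng, nl)
  l <- matrix(seq_len(nl), ng, nl, byrow = TRUE)
  p <- M / nr_
  gi <- rowSums(M); lj <- colSums(M)
  mu_i <- sum(i * p); mu_l <- sum(l * p)
  vals <- c(
    sum(p / l^2),                        # small/short emphasis
    sum(p * l^2),                        # large/long emphasis
    sum(gi^2) / nr_,                     # gray level non-uniformity
    sum(gi^2) / nr_^2,                   # ... normalized
    sum(lj^2) / nr_,                     # size/run non-uniformity
    sum(lj^2) / nr_^2,                   # ... normalized
    nr_ / n_pixels,                      # percentage
    sum((i - mu_i)^2 * p),               # gray level variance
    sum((l - mu_l)^2 * p),               # size/run variance
    entropy2(as.vector(p)),              # entropy
    sum(p / i^2),                        # low gray level
    sum(p * i^2),                        # high gray level
    sum(p / (i^2 * l^2)),                # small + low
    sum(p * i^2 / l^2),                  # small + high
    sum(p * l^2 / i^2),                  # large + low
    sum(p * i^2 * l^2)                   # large + high
  )
  names(vals) <- axis_names
  vals
}

glrlm_feature_names <- c(
  "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
  "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
  "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
  "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LongRunHighGrayLevelEmphasis")

glszm_feature_names <- c(
  "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
  "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
  "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LargeAreaHighGrayLevelEmphasis")

gldm_features <- function(D, n_pixels) {
  nz <- sum(D)
  ng <- nrow(D); nd <- ncol(D)
  i <- matrix(seq_len(ng), ng, nd)
  j <- matrix(seq_len(nd), ng, nd, byrow = TRUE)
  p <- D / nz
  gi <- rowSums(D); dj <- colSums(D)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  c(
    SmallDependenceEmphasis = sum(p / j^2),
    LargeDependenceEmphasis = sum(p * j^2),
    GrayLevelNonUniformity = sum(gi^2) / nz,
    DependenceNonUniformity = sum(dj^2) / nz,
    DependenceNonUniformityNormalized = sum(dj^2) / nz^2,
    GrayLevelVariance = sum((i - mu_i)^2 * p),
    DependenceVariance = sum((j - mu_j)^2 * p),
    DependenceEntropy = entropy2(as.vector(p)),
    LowGrayLevelEmphasis = sum(p / i^2),
    HighGrayLevelEmphasis = sum(p * i^2),
    SmallDependenceLowGrayLevelEmphasis = sum(p / (i^2 * j^2)),
    SmallDependenceHighGrayLevelEmphasis = sum(p * i^2 / j^2),
    LargeDependenceLowGrayLevelEmphasis = sum(p * j^2 / i^2),
    LargeDependenceHighGrayLevelEmphasis = sum(p * i^2 * j^2)
  )
}

ngtdm_features <- function(tab) {
  n <- sum(tab$n)
  present <- tab$n > 0
  p <- tab$n / n
  s <- tab$s
  lev <- tab$level
  ngp <- sum(present)
  pi_ <- p[present]; si_ <- s[present]; li_ <- lev[present]
  coars_den <- sum(pi_ * si_)
  coarseness <- if (coars_den > 0) 1 / coars_den else 1e6
  if (ngp <= 1) {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  } else {
    # all double sums below run over ordered pairs of present levels
    dif <- outer(li_, li_, `-`)
    contrast <- sum(outer(pi_, pi_) * dif^2) / (ngp * (ngp - 1)) *
      sum(si_) / n
    bus_den <- sum(abs(outer(li_ * pi_, li_ * pi_, `-`)))
    busyness <- if (bus_den > 0) coars_den / bus_den else 0
    complexity <- sum(abs(dif) * outer(pi_ * si_, pi_ * si_, `+`) /
                        outer(pi_, pi_, `+`)) / n
    strength <- if (sum(si_) > 0) {
      sum(outer(pi_, pi_, `+`) * dif^2) / sum(si_)
    } else 0
  }
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}

#' Features of one class from one ROI
#'
#' @param levels Discretized ROI (`$levels` from [discretize()]).
#' @param intensities Raw ROI intensity values (needed for `firstorder`).
#' @param class One of [radiomics_classes()].
#' @param ng Number of gray levels.
#' @return Named numeric vector with the class's fixed feature set.
#' @export
class_features <- function(levels, intensities = NULL,
                           class = radiomics_classes(),
                           ng = max(levels, na.rm = TRUE)) {
  class <- match.arg(class)
  if (class == "firstorder") {
    lvv <- levels[!is.na(levels)]
    return(firstorder_features(intensities, as.integer(lvv)))
  }
  n_pixels <- sum(!is.na(levels))
  if (class == "glcm") {
    mats <- texture_matrix(levels, "GLCM", ng)
    per_dir <- vapply(mats, glcm_features_one, numeric(24L))
    return(rowMeans(per_dir))
  }
  if (class == "glrlm") {
    mats <- texture_matrix(levels, "GLRLM", ng)
    per_dir <- vapply(mats, rl_style_features, numeric(16L),
                      n_pixels = n_pixels, axis_names = glrlm_feature_names)
    return(rowMeans(per_dir))
  }
  if (class == "glszm") {
    S <- texture_matrix(levels, "GLSZM", ng)
    return(rl_style_features(S, n_pixels, glszm_feature_names))
  }
  if (class == "gldm") {
    D <- texture_matrix(levels, "GLDM", ng)
    return(gldm_features(D, n_pixels))
  }
  tab <- texture_matrix(levels, "NGTDM", ng)
  ngtdm_features(tab)
}

#' Extract the full radiomics feature vector of an image-mask pair
#'
#' For each configured image type the ROI is re-discretized on the
#' filtered image and every configured feature class is computed. Feature
#' names follow `<image_type>_<class>_<feature>`; the default
#' configuration yields 1023 features.
#'
#' @param image 8-bit matrix (the original frame).
#' @param mask Logical matrix (manual mask, box mask or whole-image
#'   fallback); must be nonempty.
#' @param config A [radiomics_config()].
#' @param mask_source Provenance tag stored on the result.
#' @param stack Optional precomputed [image_type_stack()] (to share filter
#'   work across mask sources for the same image).
#' @return A named numeric vector of class `feature_vector` with
#'   attribute `mask_source`.
#' @export
extract_features <- function(image, mask, config = radiomics_config(),
                             mask_source = "manual", stack = NULL) {
  if (!any(mask)) abort("empty mask")
  stack <- stack %||% image_type_stack(image, config)
  out <- numeric(0)
  for (ty in config$image_types) {
    im <- stack[[ty]]
    dz <- discretize(im, mask, config$bin_width)
    intens <- im[mask]
    for (cl in config$classes) {
      f <- class_features(dz$levels, intens, cl, dz$ng)
      names(f) <- paste(ty, cl, names(f), sep = "_")
      out <- c(out, f)
    }
  }
  structure(out, mask_source = mask_source, class = "feature_vector")
}

#' Extract features for a whole cohort into a wide tibble
#'
#' @param images List of `annotated_image` objects.
#' @param masks Either the string `"manual"` (use each image's ground-truth
#'   mask), a list of masks, or a list of `bbox`/`detection`/`NULL` entries
#'   (boxes become filled-rectangle masks; `NULL` becomes the whole-image
#'   fallback mask).
#' @param config A [radiomics_config()].
#' @param mask_source Tag recorded in the `mask_source` column.
#' @param stacks Optional list of precomputed image stacks.
#' @return Tibble: `id`, `label`, `mask_source`, then one numeric column
#'   per feature.
#' @export
extract_cohort <- function(images, masks = "manual",
                           config = radiomics_config(),
                           mask_source = if (identical(masks, "manual"))
                             "manual" else "detector-box",
                           stacks = NULL) {
  rows <- purrr::imap(images, function(im, i) {
    mask <- if (identical(masks, "manual")) {
      im$gt_mask
    } else {
      mk <- masks[[i]]
      if (is.matrix(mk)) mk else box_to_mask(mk, dim(im$image))
    }
    fv <- extract_features(im$image, mask, config,
                           mask_source = mask_source,
                           stack = stacks[[i]] %||% NULL)
    c(list(id = sprintf("phantom_%03d", i), label = im$label,
           mask_source = mask_source), as.list(unclass(fv)))
  })
  purrr::map_dfr(rows, as_tibble)
}

#' Z-score normalize a feature table
#'
#' Statistics are computed on the given table unless `reference_stats` is
#' supplied (then they are reused unchanged — the protocol for applying a
#' feature-selection subset's normalization to later classification
#' subsets). Zero-variance features map to 0 and are flagged.
#'
#' @param table Wide tibble from [extract_cohort()] (non-numeric columns
#'   pass through untouched).
#' @param reference_stats Optional stats tibble from a previous call.
#' @return List with `table` (normalized), `stats` (tibble: feature, mean,
#'   sd, constant).
#' @export
zscore_normalize <- function(table, reference_stats = NULL) {
  numcols <- names(table)[vapply(table, is.numeric, logical(1))]
  numcols <- setdiff(numcols, c("id", "seed"))
  if (is.null(reference_stats)) {
    if (nrow(table) < 2) abort("need >= 2 rows to estimate normalization stats")
    stats <- tibble(
      feature = numcols,
      mean = vapply(numcols, function(cn) mean(table[[cn]]), numeric(1),
                    USE.NAMES = FALSE),
      sd = vapply(numcols, function(cn) sd(table[[cn]]), numeric(1),
                  USE.NAMES = FALSE)
    )
    stats$constant <- stats$sd < 1e-12
  } else {
    stats <- reference_stats
  }
  out <- table
  for (k in seq_len(nrow(stats))) {
    cn <- stats$feature[k]
    if (!cn %in% names(out)) next
    out[[cn]] <- if (stats$constant[k]) 0 else
      (out[[cn]] - stats$mean[k]) / stats$sd[k]
  }
  list(table = out, stats = stats)
}
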