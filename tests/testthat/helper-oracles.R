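# Shared fixtures and independent oracles. Every oracle here is a direct,
# brute-force restatement of the definition it checks, kept free of the
# package's own computational shortcuts.

small_phantom <- function(label = "malignant", seed = 3, h = 160, w = 180,
                          ...) {
  generate_phantom(phantom_params(label, seed = seed, height = h, width = w,
                                  ...))
}

# Pixel-set IoU for integer-aligned boxes on a finite grid.
pixel_iou <- function(a, b, grid = 64L) {
  mk <- function(bx) {
    m <- matrix(FALSE, grid, grid)
    m[(bx$y + 1):(bx$y + bx$h), (bx$x + 1):(bx$x + bx$w)] <- TRUE
    m
  }
  ma <- mk(a); mb <- mk(b)
  sum(ma & mb) / sum(ma | mb)
}

# O(n^2) pairwise rank AUC.
pairwise_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Stratified-bootstrap test of a paired AUC difference.
bootstrap_auc_p <- function(scores_a, scores_b, y, reps = 5000, seed = 42) {
  obs <- pairwise_auc(scores_a, y) - pairwise_auc(scores_b, y)
  pos <- which(y == 1); neg <- which(y == 0)
  withr::with_seed(seed, {
    d <- vapply(seq_len(reps), function(r) {
      idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
      yy <- y[idx]
      pairwise_auc(scores_a[idx], yy) - pairwise_auc(scores_b[idx], yy)
    }, numeric(1))
  })
  se <- sd(d)
  2 * pnorm(-abs(obs / se))
}

# Exhaustive pair enumeration for a GLCM offset (no symmetrization).
brute_pair_counts <- function(lv, ng, dr, dc) {
  M <- matrix(0, ng, ng)
  for (r in seq_len(nrow(lv))) for (c in seq_len(ncol(lv))) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 < 1 || r2 > nrow(lv) || c2 < 1 || c2 > ncol(lv)) next
    a <- lv[r, c]; b <- lv[r2, c2]
    if (is.na(a) || is.na(b)) next
    M[a, b] <- M[a, b] + 1
  }
  M
}

# Exhaustive run enumeration for one GLRLM direction.
brute_runs <- function(lv, ng, dir = c("h", "v", "d1", "d2")) {
  dir <- match.arg(dir)
  seqs <- switch(dir,
    h = split(lv, row(lv)), v = split(lv, col(lv)),
    d1 = split(lv, row(lv) - col(lv)), d2 = split(lv, row(lv) + col(lv)))
  R <- matrix(0, ng, max(dim(lv)))
  for (s in seqs) {
    s <- as.vector(s)
    i <- 1
    while (i <= length(s)) {
      if (is.na(s[i])) { i <- i + 1; next }
      j <- i
      while (j < length(s) && !is.na(s[j + 1]) && s[j + 1] == s[i]) j <- j + 1
      R[s[i], j - i + 1] <- R[s[i], j - i + 1] + 1
      i <- j + 1
    }
  }
  last <- max(c(1L, which(colSums(R) > 0)))
  R[, seq_len(last), drop = FALSE]
}

# Exhaustive dependence enumeration (GLDM, alpha = 0, center counted).
brute_gldm <- function(lv, ng) {
  D <- matrix(0, ng, 9)
  for (r in seq_len(nrow(lv))) for (c in seq_len(ncol(lv))) {
    if (is.na(lv[r, c])) next
    dep <- 1
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nrow(lv) || c2 < 1 || c2 > ncol(lv)) next
      if (!is.na(lv[r2, c2]) && lv[r2, c2] == lv[r, c]) dep <- dep + 1
    }
    D[lv[r, c], dep] <- D[lv[r, c], dep] + 1
  }
  last <- max(c(1L, which(colSums(D) > 0)))
  D[, seq_len(last), drop = FALSE]
}

# Random discretized ROI with a random NA (out-of-mask) pattern.
random_levels <- function(seed, n = 5, ng = 4, na_frac = 0.2) {
  withr::with_seed(seed, {
    lv <- matrix(sample.int(ng, n * n, replace = TRUE), n, n)
    lv[runif(n * n) < na_frac] <- NA
    if (all(is.na(lv))) lv[1, 1] <- 1
  })
  lv
}
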