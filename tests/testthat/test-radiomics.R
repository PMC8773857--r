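test_that("discretization follows the floor rule from the ROI minimum", {
  m <- matrix(TRUE, 1, 3)
  d <- discretize(matrix(c(0, 25, 50), 1, 3), m, 25)
  expect_equal(as.vector(d$levels), c(1, 2, 3))
  d2 <- discretize(matrix(c(0, 24, 0), 1, 3), m, 25)
  expect_equal(d2$ng, 1)
  const <- discretize(matrix(7, 4, 4), matrix(TRUE, 4, 4), 25)
  expect_true(all(const$levels == 1))
  expect_error(discretize(matrix(1, 2, 2), matrix(FALSE, 2, 2), 25), "empty")
})

test_that("GLCM pair counts match hand enumeration before symmetrization", {
  lv <- matrix(c(1, 1, 2, 2), 1, 4)
  m <- boxsig:::pair_counts(lv, 2, 0, 1)
  # pairs (1,1), (1,2), (2,2) each counted once
  expect_equal(m, matrix(c(1, 1, 0, 1), 2, 2, byrow = TRUE),
               ignore_attr = TRUE)
})

test_that("constant ROIs give the documented degenerate limits", {
  lv <- matrix(1, 4, 4)
  glrlm <- texture_matrix(lv, "GLRLM", 1)
  expect_equal(glrlm[[1]], matrix(c(0, 0, 0, 4), 1, 4))  # 4 runs of length 4
  ng <- texture_matrix(lv, "NGTDM", 1)
  expect_equal(ng$s, 0)
  fo <- class_features(lv, rep(50, 16), "firstorder", 1)
  expect_equal(unname(fo["Entropy"]), 0)
  expect_equal(unname(fo["Uniformity"]), 1)
  gl <- class_features(lv, NULL, "glcm", 1)
  expect_equal(unname(gl["Contrast"]), 0)
  expect_equal(unname(gl["Correlation"]), 1)
  expect_false(any(is.na(c(fo, gl,
                           class_features(lv, NULL, "glszm", 1),
                           class_features(lv, NULL, "gldm", 1),
                           class_features(lv, NULL, "ngtdm", 1)))))
})

test_that("checkerboard GLCM contrast equals the squared level difference", {
  cb <- matrix(1, 8, 8)
  cb[(row(cb) + col(cb)) %% 2 == 0] <- 2
  # horizontal offset: every adjacent pair is discordant by exactly 1 level
  m <- boxsig:::pair_counts(cb, 2, 0, 1)
  P <- (m + t(m)) / sum(m + t(m))
  i <- matrix(1:2, 2, 2); j <- t(i)
  expect_equal(sum((i - j)^2 * P), 1)
})

test_that("texture matrices equal exhaustive enumeration on random ROIs", {
  for (seed in 1:100) {
    lv <- random_levels(seed)
    ng <- max(lv, na.rm = TRUE)
    # GLCM, all four offsets
    glcm <- texture_matrix(lv, "GLCM", ng)
    offs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
    for (k in seq_along(offs)) {
      brute <- brute_pair_counts(lv, ng, offs[[k]][1], offs[[k]][2])
      expect_equal(glcm[[k]], brute + t(brute), ignore_attr = TRUE)
    }
    # GLRLM, all four directions
    glrlm <- texture_matrix(lv, "GLRLM", ng)
    dirs <- c("h", "v", "d1", "d2")
    for (k in seq_along(dirs)) {
      expect_equal(unname(glrlm[[k]]), unname(brute_runs(lv, ng, dirs[k])),
                   ignore_attr = TRUE)
    }
    # GLDM
    expect_equal(unname(texture_matrix(lv, "GLDM", ng)),
                 unname(brute_gldm(lv, ng)), ignore_attr = TRUE)
    # GLSZM zone sizes partition the mask
    S <- texture_matrix(lv, "GLSZM", ng)
    sizes <- matrix(seq_len(ncol(S)), ng, ncol(S), byrow = TRUE)
    expect_equal(sum(S * sizes), sum(!is.na(lv)))
  }
})

test_that("every feature is translation invariant", {
  ph <- small_phantom(seed = 5, h = 120, w = 140)
  cfg <- radiomics_config(image_types = "original")
  a <- extract_features(ph$image, ph$gt_mask, cfg)
  shift <- function(m, k) rbind(m[(nrow(m) - k + 1):nrow(m), ],
                                m[1:(nrow(m) - k), ])
  b <- extract_features(shift(ph$image, 7), shift(ph$gt_mask, 7) > 0, cfg)
  expect_equal(unclass(a), unclass(b), tolerance = 1e-12)
})

test_that("the default configuration yields 1023 deterministic features", {
  counts <- boxsig:::class_feature_counts()
  expect_equal(sum(counts), 93L)
  expect_equal(length(radiomics_image_types()) * sum(counts), 1023L)
  ph <- small_phantom(seed = 5, h = 120, w = 140)
  fv <- extract_features(ph$image, ph$gt_mask)
  expect_length(fv, 1023)
  expect_true(all(is.finite(fv)))
  expect_equal(anyDuplicated(names(fv)), 0)
  fv2 <- extract_features(ph$image, ph$gt_mask)
  expect_identical(unclass(fv), unclass(fv2))
  small <- extract_features(ph$image, ph$gt_mask,
                            radiomics_config(image_types = "original",
                                             classes = "firstorder"))
  expect_length(small, 18)
})

test_that("box masks and manual masks give different feature vectors", {
  ph <- small_phantom(seed = 6, h = 120, w = 140)
  cfg <- radiomics_config(image_types = "original")
  manual <- extract_features(ph$image, ph$gt_mask, cfg)
  boxm <- extract_features(ph$image, box_to_mask(ph$gt_box, dim(ph$image)),
                           cfg, mask_source = "detector-box")
  expect_false(isTRUE(all.equal(unclass(manual), unclass(boxm))))
  expect_equal(attr(boxm, "mask_source"), "detector-box")
})

test_that("z-score normalization computes, reuses and flags statistics", {
  tab <- tibble::tibble(id = c("a", "b", "c"), label = c("x", "y", "x"),
                        f1 = c(1, 2, 3), f2 = c(5, 5, 5))
  z <- zscore_normalize(tab)
  expect_equal(mean(z$table$f1), 0)
  expect_equal(sd(z$table$f1), 1)
  expect_true(all(z$table$f2 == 0))
  expect_true(z$stats$constant[z$stats$feature == "f2"])
  # applying reference stats to a new row matches hand arithmetic
  new <- zscore_normalize(tibble::tibble(id = "d", label = "x",
                                         f1 = 4, f2 = 9),
                          reference_stats = z$stats)
  expect_equal(new$table$f1, (4 - 2) / 1)
  expect_equal(new$table$f2, 0)
  expect_error(zscore_normalize(tab[1, ]), "2 rows")
})
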