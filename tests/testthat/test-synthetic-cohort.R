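test_that("phantoms are seed-deterministic, bit for bit", {
  p <- phantom_params("malignant", seed = 1, height = 150, width = 170)
  a <- generate_phantom(p)
  b <- generate_phantom(p)
  expect_identical(a$image, b$image)
  expect_identical(a$gt_mask, b$gt_mask)
  expect_identical(bbox_tbl(a$annotator_boxes), bbox_tbl(b$annotator_boxes))
})

test_that("ground-truth box is the tight bounding box of the mask", {
  a <- small_phantom("malignant", seed = 1)
  expect_equal(bbox_tbl(a$gt_box), bbox_tbl(bbox_from_mask(a$gt_mask)))
  expect_true(any(a$gt_mask))
  # mask fully inside the frame with margin
  idx <- which(a$gt_mask, arr.ind = TRUE)
  expect_true(min(idx) > 1 && max(idx[, 1]) < nrow(a$image) &&
              max(idx[, 2]) < ncol(a$image))
})

test_that("echo contrast controls the lesion/background intensity gap", {
  m <- generate_phantom(phantom_params("malignant", seed = 3,
                                       height = 200, width = 220,
                                       echo_contrast = -40))
  expect_lt(mean(m$image[m$gt_mask]), mean(m$image[!m$gt_mask]))
  b <- generate_phantom(phantom_params("benign", seed = 4,
                                       height = 200, width = 220))
  expect_gt(mean(b$image[b$gt_mask]), mean(b$image[!b$gt_mask]))
})

test_that("class constraints on spiculation are enforced", {
  expect_error(phantom_params("benign", seed = 1, spiculation_amplitude = 0.2),
               "spiculation")
  expect_error(phantom_params("malignant", seed = 1,
                              spiculation_amplitude = 0), "spiculation")
})

test_that("oversized lesions are rejected with an explicit message", {
  p <- phantom_params("benign", seed = 1, height = 100, width = 100,
                      lesion_center = c(50, 50), semi_axes = c(49, 49))
  expect_error(generate_phantom(p), "does not fit")
})

test_that("cohorts have exact counts, derived seeds and a manifest", {
  co <- generate_cohort(4, 3, seed = 7, height = 120, width = 140)
  expect_length(co$images, 7)
  expect_equal(sum(co$manifest$label == "benign"), 4)
  expect_equal(sum(co$manifest$label == "malignant"), 3)
  expect_equal(anyDuplicated(co$manifest$seed), 0)
  empty <- generate_cohort(0, 0, seed = 1)
  expect_length(empty$images, 0)
  expect_equal(nrow(empty$manifest), 0)
})

test_that("cohort export writes images, masks, VOC boxes and a manifest", {
  co <- generate_cohort(1, 1, seed = 7, height = 100, width = 120)
  dir <- tempfile("cohort")
  man <- write_cohort(co, dir)
  expect_true(all(file.exists(man$path)))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  img <- png::readPNG(man$path[1]) * 255
  expect_equal(dim(img), c(100, 120))
  expect_equal(max(abs(img - co$images[[1]]$image)), 0, tolerance = 0.51)
  back <- voc_read(file.path(dir, "phantom_001.xml"))
  expect_equal(back$x[1], co$images[[1]]$gt_box$x)
})

test_that("annotator emulation: zero jitter copies, small jitter stays close", {
  gt <- bbox(40, 30, 60, 50)
  dims <- c(160, 180)
  same <- emulate_annotators(gt, 3, jitter_sd = 0, seed = 5, dims = dims)
  expect_equal(bbox_tbl(same), bbox_tbl(list(gt, gt, gt)))
  # Monte-Carlo: boxes jittered at sd 0.02 keep IoU > 0.5 essentially always
  draws <- purrr::map(1:100, function(s) {
    emulate_annotators(gt, 100, jitter_sd = 0.02, seed = s, dims = dims)
  })
  ious <- box_iou(bbox_tbl(unlist(draws, recursive = FALSE)), gt)
  expect_length(ious, 1e4)
  expect_gte(mean(ious > 0.5), 0.99)
  # boxes near the frame edge are clipped inside
  edge <- bbox(0, 0, 60, 50)
  clipped <- emulate_annotators(edge, 3, jitter_sd = 0.05, seed = 9,
                                dims = dims)
  tb <- bbox_tbl(clipped)
  expect_true(all(tb$x >= 0 & tb$y >= 0 &
                  tb$x + tb$w <= dims[2] & tb$y + tb$h <= dims[1]))
})

test_that("default classes separate on first-order and texture features", {
  co <- generate_cohort(12, 12, seed = 11, height = 160, width = 180)
  cfg <- radiomics_config(image_types = "original",
                          classes = c("firstorder", "glcm"))
  tab <- extract_cohort(co$images, "manual", cfg)
  y <- tab$label
  p_first <- t.test(tab$original_firstorder_Mean[y == "benign"],
                    tab$original_firstorder_Mean[y == "malignant"])$p.value
  p_tex <- t.test(tab$original_glcm_Contrast[y == "benign"],
                  tab$original_glcm_Contrast[y == "malignant"])$p.value
  expect_lt(p_first, 0.01)
  expect_lt(p_tex, 0.01)
})
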