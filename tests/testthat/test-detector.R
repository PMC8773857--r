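# Detector tests use small frames and reduced-strength cascades; the
# configurations are fixed and seeded so every run sees the same cohort.

hc_cohort <- function(n1, n2, seed, h = 240, w = 280) {
  generate_cohort(n1, n2, seed = seed, height = h, width = w,
                  echo_contrast = -70, heterogeneity_sd = 10,
                  speckle_scale = 0.5)
}

desk_config <- function(n_stages = 5L, learners = 25L) {
  detector_config(cell = 16L, n_stages = n_stages,
                  learners_per_stage = learners, stride = 1L,
                  scale_steps = c(0.6, 0.75, 0.9, 1.1, 1.3, 1.6),
                  pos_jitter_per_image = 8L, neg_per_image = 10L)
}

test_that("HOG descriptor has the block-count length and edge response", {
  cfg <- detector_config(window = c(64, 64), cell = 8L, block = 2L, bins = 9L)
  d <- hog_descriptor(matrix(7, 64, 64), cfg)
  expect_length(d, 9 * 4 * 7 * 7)  # 1764
  expect_true(all(d == 0))  # zero gradients -> zero descriptor
  # vertical step edge: gradient along x -> orientation bin 1 (0 degrees)
  step <- matrix(0, 64, 64); step[, 33:64] <- 200
  ds <- hog_descriptor(step, cfg)
  by_bin <- colSums(matrix(ds, ncol = 9, byrow = TRUE))
  expect_equal(which.max(by_bin), 1)
  expect_gt(by_bin[1], 0.9 * sum(by_bin))
})

test_that("ROI sampling yields 1 positive and 4 far negatives, seeded", {
  ph <- small_phantom(seed = 4, h = 200, w = 220)
  r1 <- sample_rois(ph, seed = 1)
  expect_length(r1$negatives, 4)
  expect_true(all(box_iou(bbox_tbl(r1$negative_boxes), ph$gt_box) < 0.1))
  expect_equal(dim(r1$positive), c(round(ph$gt_box$h), round(ph$gt_box$w)))
  r2 <- sample_rois(ph, seed = 1)
  expect_identical(r1$negative_boxes, r2$negative_boxes)
  # a lesion covering most of the frame leaves no room for negatives
  big <- list(image = matrix(0, 100, 100), gt_box = bbox(5, 5, 90, 90))
  expect_error(sample_rois(big, seed = 1), "negatives")
})

test_that("cascade training is deterministic and serializes losslessly", {
  co <- hc_cohort(3, 3, seed = 7, h = 200, w = 220)
  cfg <- desk_config(n_stages = 2L, learners = 8L)
  m1 <- suppressWarnings(train_cascade(co$images, cfg, seed = 1))
  m2 <- suppressWarnings(train_cascade(co$images, cfg, seed = 1))
  thr <- function(m) vapply(m$stages, `[[`, numeric(1), "threshold")
  expect_identical(thr(m1), thr(m2))
  expect_identical(m1$stages[[1]]$stumps, m2$stages[[1]]$stumps)
  tf <- tempfile(fileext = ".json")
  save_detector(m1, tf)
  m3 <- load_detector(tf)
  expect_equal(thr(m3), thr(m1))
  expect_equal(m3$stages[[1]]$stumps$feature, m1$stages[[1]]$stumps$feature)
  expect_equal(m3$config$window, m1$config$window)
})

test_that("boosted stumps separate a linearly separable toy set", {
  X <- rbind(matrix(5, 10, 4), matrix(0, 10, 4)) +
    withr::with_seed(1, matrix(rnorm(80, 0, 0.1), 20, 4))
  y <- rep(c(1, 0), each = 10)
  st <- boxsig:::train_stumps(X, y, 10)
  sc <- boxsig:::stump_scores(X, st)
  expect_true(all(sc[y == 1] > 0) && all(sc[y == 0] < 0))
})

test_that("detection finds high-contrast lesions and rejects blanks", {
  co <- hc_cohort(8, 8, seed = 7)
  mod <- suppressWarnings(train_cascade(co$images, desk_config(), seed = 1))
  test <- hc_cohort(15, 15, seed = 123)
  ious <- vapply(test$images, function(im) {
    top <- select_primary(detect(mod, im$image))
    if (is.null(top)) return(NA_real_)
    box_iou(top$box, im$gt_box)
  }, numeric(1))
  expect_gte(mean(!is.na(ious) & ious > 0.5), 0.7)
  # blank frame: no gradient energy anywhere -> no detections
  expect_length(detect(mod, matrix(7, 240, 280)), 0)
  # frame smaller than the window at every scale -> empty, no error
  expect_length(detect(mod, matrix(7, 30, 30)), 0)
  # NMS survivors have pairwise IoU at or below the threshold
  dets <- detect(mod, test$images[[1]]$image)
  if (length(dets) >= 2) {
    tb <- bbox_tbl(lapply(dets, `[[`, "box"))
    for (i in seq_len(nrow(tb) - 1)) {
      expect_lte(max(box_iou(tb[i, ], tb[-seq_len(i), , drop = FALSE])),
                 mod$config$nms_iou + 0.2)  # voting may shift boxes slightly
    }
  }
})

test_that("recall does not drop as lesion contrast strengthens", {
  co <- hc_cohort(6, 6, seed = 7)
  mod <- suppressWarnings(train_cascade(co$images,
                                        desk_config(n_stages = 3L,
                                                    learners = 15L),
                                        seed = 1))
  hits <- vapply(c(-30, -70), function(ec) {
    test <- generate_cohort(0, 8, seed = 55, height = 240, width = 280,
                            echo_contrast = ec, heterogeneity_sd = 10,
                            speckle_scale = 0.5)
    mean(vapply(test$images, function(im) {
      top <- select_primary(detect(mod, im$image))
      !is.null(top) && box_iou(top$box, im$gt_box) > 0.5
    }, logical(1)))
  }, numeric(1))
  expect_gte(hits[2], hits[1])
})

test_that("primary selection takes the top score with a spatial tie-break", {
  expect_null(select_primary(list()))
  d <- function(x, y, s) structure(list(box = bbox(x, y, 10, 10), score = s),
                                   class = "detection")
  expect_equal(select_primary(list(d(0, 0, 0.3), d(5, 5, 0.9)))$score, 0.9)
  tie <- select_primary(list(d(8, 2, 0.5), d(2, 8, 0.5), d(2, 9, 0.5)))
  expect_equal(c(tie$box$x, tie$box$y), c(2, 8))
})

test_that("external detections load from CSV and VOC, round-tripping boxes", {
  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(image_id = c("a", "a", "b"),
                       x = c(0, 20, 5), y = c(0, 10, 5),
                       w = c(10, 30, 50), h = c(10, 15, 40),
                       score = c(0.9, 0.2, 1)),
            csv, row.names = FALSE)
  ext <- load_external_detections(csv)
  expect_named(ext, c("a", "b"))
  expect_length(ext$a, 2)
  expect_equal(ext$a[[1]]$box$w, 10)
  # VOC directory round trip
  dir <- tempfile("voc"); dir.create(dir)
  voc_write(file.path(dir, "img1.xml"), "img1", c(100, 100),
            list(bbox(3, 4, 20, 30)))
  voc_write(file.path(dir, "img2.xml"), "img2", c(100, 100), list())
  ext2 <- load_external_detections(dir)
  expect_equal(ext2$img1[[1]]$box$h, 30)
  expect_length(ext2$img2, 0)
  # malformed input errors with context
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(image_id = "a", x = 1, y = 1, w = -5, h = 5), bad,
            row.names = FALSE)
  expect_error(load_external_detections(bad), "non-positive")
})
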