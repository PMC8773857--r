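test_that("IoU matches hand values and behaves at the extremes", {
  b <- bbox(0, 0, 10, 10)
  expect_equal(box_iou(b, b), 1)
  expect_equal(box_iou(b, bbox(20, 20, 5, 5)), 0)
  expect_equal(box_iou(b, bbox(5, 0, 10, 10)), 50 / 150)
  expect_equal(box_iou(b, bbox(5, 0, 10, 10)), box_iou(bbox(5, 0, 10, 10), b))
  expect_error(box_iou(b, list(x = 0, y = 0, w = 0, h = 5)))
})

test_that("analytic IoU equals brute-force pixel counting exactly", {
  n <- 2000
  boxes <- withr::with_seed(11, {
    rand_box <- function() {
      x <- sample(0:40, 1); y <- sample(0:40, 1)
      bbox(x, y, sample(1:(64 - x), 1), sample(1:(64 - y), 1))
    }
    list(a = replicate(n, rand_box(), simplify = FALSE),
         b = replicate(n, rand_box(), simplify = FALSE))
  })
  analytic <- box_iou(bbox_tbl(boxes$a), bbox_tbl(boxes$b))
  brute <- vapply(seq_len(n), function(i) pixel_iou(boxes$a[[i]], boxes$b[[i]]),
                  numeric(1))
  expect_equal(analytic, brute, tolerance = 1e-12)
})

test_that("localization error reproduces hand arithmetic and metric axioms", {
  dims <- c(100, 100)
  b <- bbox(10, 10, 50, 50)
  expect_equal(box_le(b, b, dims), 0)
  # center offset (0.06, 0.08) in normalized units, same size
  expect_equal(box_le(b, bbox(16, 18, 50, 50), dims), 0.1)
  # widths differing by 0.1 normalized, same center
  expect_equal(box_le(bbox(25, 25, 50, 50), bbox(20, 25, 60, 50), dims), 0.1)
  # symmetry and non-negativity over random pairs
  pairs <- withr::with_seed(3, replicate(200, list(
    a = bbox(runif(1, 0, 40), runif(1, 0, 40), runif(1, 5, 50), runif(1, 5, 50)),
    b = bbox(runif(1, 0, 40), runif(1, 0, 40), runif(1, 5, 50), runif(1, 5, 50))
  ), simplify = FALSE))
  for (p in pairs[1:20]) {
    expect_equal(box_le(p$a, p$b, dims), box_le(p$b, p$a, dims))
    expect_gte(box_le(p$a, p$b, dims), 0)
  }
  expect_error(box_le(b, b, NULL), "dims")
})

test_that("the joint outcome rule reproduces the three reference decisions", {
  s <- tibble::tibble(iou = c(0.88, 0.48, 0), le = c(4e-04, 0.01, 0.07))
  expect_equal(joint_outcome(s), c("TP", "TP", "FP"))
  # a miss is a false negative
  expect_equal(joint_outcome(tibble::tibble(iou = NA_real_, le = NA_real_)),
               "FN")
})

test_that("joint rule degenerates to pure-IoU and pure-LE scoring", {
  s <- tibble::tibble(iou = c(0.6, 0.45, 0.3), le = c(0.5, 0.01, 0.01))
  iou_only <- joint_outcome(s, list(iou_tp = 0.5, le_tp = 0, iou_floor = 1))
  expect_equal(iou_only, c("TP", "FP", "FP"))
  le_only <- joint_outcome(s, list(iou_tp = 1, le_tp = 0.1, iou_floor = 0))
  expect_equal(le_only, c("FP", "TP", "TP"))
})

test_that("annotator averaging and dataset summaries are plain arithmetic", {
  expect_equal(per_image_mean(tibble::tibble(iou = 0.7, le = 0.2)),
               tibble::tibble(iou = 0.7, le = 0.2))
  expect_equal(per_image_mean(tibble::tibble(iou = c(0.4, 0.6),
                                             le = c(0, 0.2)))$iou, 0.5)
  expect_equal(per_image_mean(tibble::tibble(iou = c(1, 1, 1),
                                             le = c(0, 0.2, 0.1)))$le, 0.1)
  expect_error(per_image_mean(tibble::tibble(iou = numeric(), le = numeric())))
  s <- dataset_summary(tibble::tibble(iou = c(0.2, 0.4, 0.6),
                                      le = c(0.1, 0.1, 0.1)))
  expect_equal(s$iou_mean, 0.4)
  expect_equal(s$iou_sd, 0.2)
  expect_equal(s$le_sd, 0)
  one <- dataset_summary(tibble::tibble(iou = 0.5, le = 0.1))
  expect_equal(one$iou_sd, 0)
  expect_false(one$sd_defined)
})

test_that("recall/precision/F1 follow the counting rules", {
  m <- precision_recall_f1(tp = 8, fp = 2, fn = 2)
  expect_equal(unlist(m), c(recall = 0.8, precision = 0.8, f1 = 0.8))
  # zero false negatives: recall falls back to TP / N
  m2 <- precision_recall_f1(tp = 5, fp = 0, fn = 0, n_ground_truths = 10)
  expect_equal(m2$recall, 0.5)
  m3 <- precision_recall_f1(tp = 0, fp = 3, fn = 1)
  expect_equal(unlist(m3), c(recall = 0, precision = 0, f1 = 0))
  expect_error(precision_recall_f1(0, 0, 0, 0), "zero")
})

test_that("recall curves are monotone and hit the endpoints", {
  perfect <- tibble::tibble(iou = rep(1, 5), le = rep(0, 5))
  rc <- recall_curve(perfect, "iou", thresholds = c(0.1, 0.5, 0.9))
  expect_equal(rc$recall, rep(1, 3))
  empty <- recall_curve(tibble::tibble(iou = numeric(), le = numeric()), "iou")
  expect_equal(unique(empty$recall), 0)
  scores <- withr::with_seed(7, tibble::tibble(iou = runif(500),
                                               le = runif(500)))
  iou_rec <- recall_curve(scores, "iou")$recall
  expect_true(all(diff(iou_rec) <= 0))
  le_rec <- recall_curve(scores, "le")$recall
  expect_true(all(diff(le_rec) >= 0))
  # recall at IoU 0.5 equals the counting-rule recall with IoU-only outcomes
  outc <- joint_outcome(scores, list(iou_tp = 0.5, le_tp = 0, iou_floor = 1))
  expect_equal(iou_rec[recall_curve(scores, "iou")$threshold == 0.5],
               sum(outc == "TP") / nrow(scores))
})

test_that("multi-annotator evaluation pools outcomes and averages scores", {
  dims <- c(100, 100)
  gt <- bbox(20, 20, 40, 40)
  users <- list(gt, bbox(22, 20, 40, 40), bbox(20, 24, 40, 40))
  dets <- list(structure(list(box = bbox(21, 21, 40, 40), score = 1),
                         class = "detection"),
               NULL)
  rep <- evaluate_detections(dets, list(users, users), dims)
  expect_equal(rep$counts$tp, 3)
  expect_equal(rep$counts$fn, 3)
  expect_equal(rep$counts$n_ground_truths, 6)
  expect_equal(nrow(rep$per_image), 2)
  expect_true(is.na(rep$per_image$iou[2]))
  expect_equal(rep$metrics$recall, 0.5)
})
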