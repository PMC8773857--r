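# Desk-scale trainable sliding-window lesion detector: HOG descriptors,
# discrete-AdaBoost stump stages chained into a rejection cascade with
# hard-negative bootstrapping, multi-scale detection with NMS, and a
# reader for detections produced by external detectors.

#' Detector configuration
#'
#' @param window `"auto"` (median ground-truth box size of the training
#'   set, snapped to the cell grid) or `c(h, w)` in pixels (multiples of
#'   `cell`).
#' @param cell HOG cell size in pixels.
#' @param block HOG block size in cells (L2-normalized, stride one cell).
#' @param bins Number of unsigned orientation bins over 0..180 degrees.
#' @param n_stages Number of cascade stages.
#' @param learners_per_stage Boosted stumps per stage.
#' @param stage_recall Fraction of training positives each stage must pass
#'   (sets the stage threshold).
#' @param scale_steps Object-size multipliers searched at detection time.
#' @param stride Window stride in cells.
#' @param score_threshold Minimum final score for a detection to be kept.
#' @param nms_iou Non-maximum-suppression IoU threshold.
#' @param smooth_sigma Gaussian despeckling scale (pixels) applied to the
#'   frame before gradients are computed, at training and detection alike;
#'   suppresses speckle gradients so lesion boundaries dominate the HOG.
#' @param neg_per_image Negatives sampled per training image.
#' @param pos_jitter_per_image Extra jittered positive crops per training
#'   image (slightly shifted/rescaled ground-truth boxes); diversifies the
#'   positive pool so stage thresholds generalize beyond the exact
#'   ground-truth alignment.
#' @return A `detector_config` list.
#' @export
detector_config <- function(window = "auto", cell = 8L, block = 2L, bins = 9L,
                            n_stages = 10L, learners_per_stage = 50L,
                            stage_recall = 0.99,
                            scale_steps = c(0.8, 1, 1.25), stride = 2L,
                            score_threshold = 0, nms_iou = 0.3,
                            smooth_sigma = 3, neg_per_image = 4L,
                            pos_jitter_per_image = 3L) {
  stopifnot(n_stages >= 1, stride >= 1, all(scale_steps > 0),
            n_stages %in% c(1:100))
  structure(list(
    window = window, cell = as.integer(cell), block = as.integer(block),
    bins = as.integer(bins), n_stages = as.integer(n_stages),
    learners_per_stage = as.integer(learners_per_stage),
    stage_recall = stage_recall, scale_steps = scale_steps,
    stride = as.integer(stride), score_threshold = score_threshold,
    nms_iou = nms_iou, smooth_sigma = smooth_sigma,
    neg_per_image = as.integer(neg_per_image),
    pos_jitter_per_image = as.integer(pos_jitter_per_image)
  ), class = "detector_config")
}

# ---- HOG --------------------------------------------------------------------

# Per-cell orientation histograms for a whole image.
# Returns array [cells_r, cells_c, bins].
hog_cells <- function(img, cell, bins) {
  nr <- nrow(img); nc <- ncol(img)
  ncr <- nr %/% cell; ncc <- nc %/% cell
  img <- img[seq_len(ncr * cell), seq_len(ncc * cell), drop = FALSE]
  nr <- nrow(img); nc <- ncol(img)
  gx <- img[, reflect_index(seq_len(nc) + 1L, nc), drop = FALSE] -
        img[, reflect_index(seq_len(nc) - 1L, nc), drop = FALSE]
  gy <- img[reflect_index(seq_len(nr) + 1L, nr), , drop = FALSE] -
        img[reflect_index(seq_len(nr) - 1L, nr), , drop = FALSE]
  mag <- sqrt(gx^2 + gy^2)
  ang <- (atan2(gy, gx) * 180 / pi) %% 180
  bin <- pmin(floor(ang / (180 / bins)), bins - 1L) + 1L
  cr <- (seq_len(nr) - 1L) %/% cell
  cc <- (seq_len(nc) - 1L) %/% cell
  cell_id <- outer(cr, cc * ncr, `+`) + 1L  # column-major cell index
  out <- array(0, c(ncr, ncc, bins))
  for (b in seq_len(bins)) {
    v <- mag * (bin == b)
    s <- rowsum(as.vector(v), group = as.vector(cell_id))
    ids <- as.integer(rownames(s))
    plane <- numeric(ncr * ncc)
    plane[ids] <- s[, 1]
    out[, , b] <- matrix(plane, ncr, ncc)
  }
  out
}

# L2-normalized block descriptors from a cell-histogram array.
# Returns list(mat = [n_blocks_r * n_blocks_c, block^2 * bins] matrix laid
# out column-major in (block_r, block_c)).
hog_blocks <- function(cells, block) {
  ncr <- dim(cells)[1]; ncc <- dim(cells)[2]; bins <- dim(cells)[3]
  nbr <- ncr - block + 1L; nbc <- ncc - block + 1L
  if (nbr < 1 || nbc < 1) return(list(mat = NULL, nbr = 0L, nbc = 0L))
  feat <- matrix(0, nbr * nbc, block * block * bins)
  colf <- 0L
  for (dc in 0:(block - 1L)) for (dr in 0:(block - 1L)) {
    for (b in seq_len(bins)) {
      colf <- colf + 1L
      sub <- cells[dr + seq_len(nbr), dc + seq_len(nbc), b, drop = FALSE]
      feat[, colf] <- as.vector(sub)
    }
  }
  nrm <- sqrt(rowSums(feat^2))
  nz <- nrm > 1e-12
  feat[nz, ] <- feat[nz, , drop = FALSE] / nrm[nz]
  list(mat = feat, nbr = nbr, nbc = nbc)
}

#' HOG descriptor of a single patch
#'
#' The patch is resampled to the configured window, gradients are binned
#' into unsigned orientation histograms per cell, and blocks of cells are
#' L2-normalized and concatenated. A constant patch yields the all-zero
#' descriptor. For a 64 x 64 window with 8-pixel cells, 2 x 2 blocks and 9
#' bins the descriptor has length 7 * 7 * 36 = 1764.
#'
#' @param patch Numeric matrix.
#' @param config A [detector_config()] whose `window` is concrete.
#' @return Numeric descriptor vector of fixed length.
#' @export
hog_descriptor <- function(patch, config = detector_config(window = c(64, 64))) {
  win <- config$window
  if (identical(win, "auto")) abort("config window must be concrete (c(h, w))")
  patch <- resize_bilinear(patch, win[1], win[2])
  cells <- hog_cells(patch, config$cell, config$bins)
  blk <- hog_blocks(cells, config$block)
  as.vector(t(blk$mat))
}

# Descriptors for all sliding windows of an image at native scale.
# Returns list(desc, boxes) where boxes are in image pixels.
window_descriptors <- function(img, config) {
  win <- config$window; cell <- config$cell
  wr_cells <- win[1] %/% cell; wc_cells <- win[2] %/% cell
  cells <- hog_cells(img, cell, config$bins)
  blk <- hog_blocks(cells, config$block)
  if (is.null(blk$mat)) return(list(desc = NULL, boxes = NULL))
  nbr <- blk$nbr; nbc <- blk$nbc
  wbr <- wr_cells - config$block + 1L  # blocks per window, rows
  wbc <- wc_cells - config$block + 1L
  if (wbr < 1 || wbc < 1 || nbr < wbr || nbc < wbc) {
    return(list(desc = NULL, boxes = NULL))
  }
  pos_r <- seq(1L, nbr - wbr + 1L, by = config$stride)
  pos_c <- seq(1L, nbc - wbc + 1L, by = config$stride)
  grid <- expand.grid(r = pos_r, c = pos_c)
  nwin <- nrow(grid)
  blocklen <- config$block^2 * config$bins
  desc <- matrix(0, nwin, wbr * wbc * blocklen)
  # gather per within-window block position
  for (j in 0:(wbc - 1L)) for (i in 0:(wbr - 1L)) {
    rows_idx <- (grid$c + j - 1L) * nbr + (grid$r + i)
    cols_out <- ((j * wbr + i) * blocklen + 1L):((j * wbr + i + 1L) * blocklen)
    desc[, cols_out] <- blk$mat[rows_idx, , drop = FALSE]
  }
  boxes <- tibble(
    x = (grid$c - 1L) * cell, y = (grid$r - 1L) * cell,
    w = win[2], h = win[1]
  )
  list(desc = desc, boxes = boxes)
}

# ---- ROI sampling -----------------------------------------------------------

#' Sample training regions of interest from one annotated image
#'
#' One positive patch (the ground-truth box crop) and `n_neg` random
#' negative crops, each with IoU below 0.1 against the ground truth.
#'
#' @param annotated An `annotated_image`.
#' @param seed Integer seed (negative placement is seeded).
#' @param n_neg Number of negatives (default 4).
#' @param window Negative crop size `c(h, w)`; defaults to the gt box size.
#' @return List with `positive` (matrix), `negatives` (list of matrices),
#'   and the corresponding boxes.
#' @export
sample_rois <- function(annotated, seed, n_neg = 4L, window = NULL) {
  img <- annotated$image
  gt <- annotated$gt_box
  dims <- dim(img)
  win <- window %||% c(round(gt$h), round(gt$w))
  crop <- function(b) {
    img[(round(b$y) + 1):(round(b$y) + round(b$h)),
        (round(b$x) + 1):(round(b$x) + round(b$w)), drop = FALSE]
  }
  neg_boxes <- withr::with_seed(seed, {
    out <- list(); tries <- 0L
    while (length(out) < n_neg && tries < 500L) {
      tries <- tries + 1L
      if (win[1] > dims[1] || win[2] > dims[2]) break
      x <- floor(runif(1, 0, dims[2] - win[2] + 1))
      y <- floor(runif(1, 0, dims[1] - win[1] + 1))
      cand <- bbox(x, y, win[2], win[1])
      if (box_iou(cand, gt) < 0.1) out <- c(out, list(cand))
    }
    out
  })
  if (length(neg_boxes) < n_neg) {
    abort(sprintf(
      "could not place %d negatives with IoU < 0.1 (lesion too large for the frame?)",
      n_neg))
  }
  list(
    positive = crop(gt), positive_box = gt,
    negatives = lapply(neg_boxes, crop), negative_boxes = neg_boxes
  )
}

# ---- boosting ---------------------------------------------------------------

# Train `rounds` discrete-AdaBoost decision stumps on X (n x p), y in {0,1}.
# Returns list(stumps = data.frame(feature, threshold, polarity, alpha)).
train_stumps <- function(X, y, rounds) {
  n <- nrow(X); p <- ncol(X)
  ord <- apply(X, 2, order)                       # n x p sort orders
  idx <- ord + matrix((seq_len(p) - 1L) * n, n, p, byrow = TRUE)
  Xs <- matrix(X[idx], n, p)                      # sorted values per column
  w <- rep(1 / n, n)
  stumps <- vector("list", rounds)
  for (t in seq_len(rounds)) {
    wp <- w * (y == 1); wn <- w * (y == 0)
    Wp <- matrix(wp[ord], n, p); Wn <- matrix(wn[ord], n, p)
    cp <- apply(Wp, 2, cumsum); cn <- apply(Wn, 2, cumsum)
    tp <- sum(wp); tn <- sum(wn)
    # stump "x >= thr is positive", threshold after sorted position i:
    # error = (positives below) + (negatives at-or-above) = cp[i] + (tn - cn[i])
    err_ge <- cp + (tn - cn)
    err_lt <- 1 - err_ge                           # reversed polarity
    e1 <- min(err_ge); e2 <- min(err_lt)
    if (e1 <= e2) {
      k <- which(err_ge == e1, arr.ind = TRUE)[1, ]
      polarity <- 1
      err <- e1
    } else {
      k <- which(err_lt == e2, arr.ind = TRUE)[1, ]
      polarity <- -1
      err <- e2
    }
    i <- k[1]; j <- k[2]
    thr <- if (i < n) (Xs[i, j] + Xs[i + 1L, j]) / 2 else Xs[n, j] + 1e-9
    err <- max(min(err, 1 - 1e-10), 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    pred <- if (polarity == 1) X[, j] >= thr else X[, j] < thr
    agree <- (pred == (y == 1))
    w <- w * exp(ifelse(agree, -alpha, alpha))
    w <- w / sum(w)
    stumps[[t]] <- data.frame(feature = j, threshold = thr,
                              polarity = polarity, alpha = alpha)
    if (err <= 1e-9) { stumps <- stumps[seq_len(t)]; break }
  }
  do.call(rbind, stumps)
}

stump_scores <- function(X, stumps) {
  s <- numeric(nrow(X))
  for (t in seq_len(nrow(stumps))) {
    f <- stumps$feature[t]
    pred <- if (stumps$polarity[t] == 1) X[, f] >= stumps$threshold[t]
            else X[, f] < stumps$threshold[t]
    s <- s + stumps$alpha[t] * (2 * pred - 1)
  }
  s
}

# ---- cascade training -------------------------------------------------------

#' Train a HOG cascade lesion detector
#'
#' Each stage is a boosted ensemble of decision stumps whose threshold is
#' set to pass at least `stage_recall` of the training positives; stage
#' `k` is trained against the negatives surviving stages `1..k-1`, refilled
#' by hard-negative mining on the training images. If negatives are
#' exhausted before all stages are built, training stops early with a
#' warning and returns the shallower cascade.
#'
#' @param train_set List of `annotated_image` objects.
#' @param config A [detector_config()].
#' @param seed Integer seed (ROI sampling and mining order).
#' @return A `detector_model`: stages, resolved config, training metadata.
#' @export
train_cascade <- function(train_set, config = detector_config(), seed = 1L) {
  stopifnot(length(train_set) >= 1)
  cell <- config$cell
  if (identical(config$window, "auto")) {
    gt <- bbox_tbl(lapply(train_set, `[[`, "gt_box"))
    snap <- function(v) max(3L * cell, as.integer(round(v / cell)) * cell)
    config$window <- c(snap(median(gt$h)), snap(median(gt$w)))
  }
  # Training windows come from the same multi-scale sliding grids used at
  # detection time, so train and test descriptors share one representation:
  # positives are the grid windows best overlapping the ground truth,
  # negatives are far windows (IoU < 0.1) from the same grids.
  harvest <- purrr::imap(train_set, function(im, i) {
    smoothed <- if (config$smooth_sigma > 0) {
      gaussian_blur(im$image, config$smooth_sigma)
    } else im$image
    per_scale <- purrr::compact(lapply(config$scale_steps, function(s) {
      rs <- round(dim(im$image) / s)
      if (any(rs < config$window)) return(NULL)
      img_s <- resize_bilinear(smoothed, rs[1], rs[2])
      wd <- window_descriptors(img_s, config)
      if (is.null(wd$desc)) return(NULL)
      bx <- wd$boxes
      bx$x <- bx$x * s; bx$y <- bx$y * s; bx$w <- bx$w * s; bx$h <- bx$h * s
      list(desc = wd$desc, iou = box_iou(bx, im$gt_box))
    }))
    if (length(per_scale) == 0) {
      abort("image too small for the detector window at every scale")
    }
    desc <- do.call(rbind, lapply(per_scale, `[[`, "desc"))
    iou <- unlist(lapply(per_scale, `[[`, "iou"))
    n_pos <- 1L + config$pos_jitter_per_image
    pos_idx <- order(iou, decreasing = TRUE)[seq_len(n_pos)]
    pos_idx <- pos_idx[iou[pos_idx] > 0.4]
    neg_pool <- which(iou < 0.1)
    withr::with_seed(child_seed(seed, i), {
      neg_idx <- sample(neg_pool, min(config$neg_per_image, length(neg_pool)))
      # a capped reservoir of far windows kept for hard-negative mining
      pool_idx <- sample(neg_pool, min(250L, length(neg_pool)))
    })
    list(pos = desc[pos_idx, , drop = FALSE],
         neg = desc[neg_idx, , drop = FALSE],
         pool = desc[setdiff(pool_idx, neg_idx), , drop = FALSE])
  })
  pos <- do.call(rbind, lapply(harvest, `[[`, "pos"))
  neg <- do.call(rbind, lapply(harvest, `[[`, "neg"))
  pool <- do.call(rbind, lapply(harvest, `[[`, "pool"))
  if (is.null(pos) || nrow(pos) == 0) {
    abort("no training window overlapped a ground-truth box; enlarge scale_steps")
  }

  stages <- list()
  for (k in seq_len(config$n_stages)) {
    if (is.null(neg) || nrow(neg) == 0) {
      warn(sprintf("negatives exhausted after %d stages; returning shallower cascade",
                   length(stages)))
      break
    }
    X <- rbind(pos, neg)
    y <- c(rep(1, nrow(pos)), rep(0, nrow(neg)))
    stumps <- train_stumps(X, y, config$learners_per_stage)
    sc_pos <- stump_scores(pos, stumps)
    thr <- quantile(sc_pos, 1 - config$stage_recall, type = 1) - 1e-9
    stages[[k]] <- list(stumps = stumps, threshold = unname(thr))
    # hard negatives: survivors of the new stage, topped up by mining the
    # reservoir of far windows through the whole cascade so far
    sc_neg <- stump_scores(neg, stumps)
    neg <- neg[sc_neg >= thr, , drop = FALSE]
    if (nrow(neg) < nrow(pos) && k < config$n_stages && nrow(pool) > 0) {
      keep <- rep(TRUE, nrow(pool))
      for (st in stages) {
        if (!any(keep)) break
        sc <- stump_scores(pool[keep, , drop = FALSE], st$stumps)
        keep[keep] <- sc >= st$threshold
      }
      if (any(keep)) {
        add <- which(keep)[seq_len(min(sum(keep), 2L * nrow(pos)))]
        neg <- rbind(neg, pool[add, , drop = FALSE])
        pool <- pool[-add, , drop = FALSE]
      }
    }
  }
  structure(list(stages = stages, config = config,
                 n_pos = nrow(pos), seed = seed),
            class = "detector_model")
}

#' @export
print.detector_model <- function(x, ...) {
  cat(sprintf("<detector_model %d stages, window %dx%d, %d stumps/stage>\n",
              length(x$stages), x$config$window[1], x$config$window[2],
              x$config$learners_per_stage))
  invisible(x)
}

# ---- detection --------------------------------------------------------------

#' Run the cascade detector on an image
#'
#' Multi-scale sliding window; a window survives only if it passes every
#' stage (so acceptance is monotone in stage index); survivors are scored
#' by their cumulative stage margin and pruned with NMS. Windows with an
#' all-zero descriptor (no gradient energy) are discarded up front.
#'
#' @param model A `detector_model`.
#' @param image 8-bit matrix.
#' @return List of `detection` objects (box + score), sorted by score
#'   descending; empty list if nothing survives.
#' @export
detect <- function(model, image) {
  cfg <- model$config
  if (cfg$smooth_sigma > 0) image <- gaussian_blur(image, cfg$smooth_sigma)
  out <- list()
  for (s in cfg$scale_steps) {
    rs <- round(dim(image) / s)
    if (any(rs < cfg$window)) next
    img_s <- resize_bilinear(image, rs[1], rs[2])
    wd <- window_descriptors(img_s, cfg)
    if (is.null(wd$desc)) next
    keep <- rowSums(abs(wd$desc)) > 1e-9
    margin <- numeric(nrow(wd$desc))
    for (st in model$stages) {
      if (!any(keep)) break
      sc <- stump_scores(wd$desc[keep, , drop = FALSE], st$stumps)
      ok <- sc >= st$threshold
      margin[keep] <- margin[keep] + (sc - st$threshold)
      keep[keep] <- ok
    }
    if (!any(keep)) next
    bx <- wd$boxes[keep, , drop = FALSE]
    sc <- margin[keep]
    for (i in seq_len(nrow(bx))) {
      b <- bbox(bx$x[i] * s, bx$y[i] * s, bx$w[i] * s, bx$h[i] * s)
      out <- c(out, list(structure(list(box = b, score = sc[i]),
                                   class = "detection")))
    }
  }
  out <- Filter(function(d) d$score >= model$config$score_threshold, out)
  if (length(out) == 0) return(list())
  out <- out[order(vapply(out, `[[`, numeric(1), "score"), decreasing = TRUE)]
  kept <- nms(out, cfg$nms_iou)
  # box voting: each kept detection is replaced by the score-weighted mean
  # of all surviving windows overlapping it and rescored by the cluster
  # mass (total margin of its voters) — a lesion attracts many windows
  # across positions and scales, an isolated speckle fluke does not
  all_boxes <- bbox_tbl(lapply(out, `[[`, "box"))
  all_scores <- vapply(out, `[[`, numeric(1), "score")
  voted <- lapply(kept, function(d) {
    ov <- box_iou(all_boxes, d$box) > 0.4
    w <- pmax(all_scores[ov], 1e-6)
    b <- all_boxes[ov, , drop = FALSE]
    vb <- bbox(sum(w * b$x) / sum(w), sum(w * b$y) / sum(w),
               sum(w * b$w) / sum(w), sum(w * b$h) / sum(w))
    structure(list(box = vb, score = sum(w)), class = "detection")
  })
  voted[order(vapply(voted, `[[`, numeric(1), "score"), decreasing = TRUE)]
}

# Greedy non-maximum suppression; input sorted by score descending.
nms <- function(detections, iou_thr) {
  kept <- list()
  for (d in detections) {
    clash <- any(vapply(kept, function(k) box_iou(k$box, d$box) > iou_thr,
                        logical(1)))
    if (!clash) kept <- c(kept, list(d))
  }
  kept
}

#' Pick the primary (highest-score) detection
#'
#' Ties are broken by the lexicographically smallest `(x, y)` corner.
#'
#' @param detections List of `detection` objects.
#' @return A single `detection`, or `NULL` if the list is empty.
#' @export
select_primary <- function(detections) {
  if (length(detections) == 0) return(NULL)
  sc <- vapply(detections, `[[`, numeric(1), "score")
  xs <- vapply(detections, function(d) d$box$x, numeric(1))
  ys <- vapply(detections, function(d) d$box$y, numeric(1))
  ord <- order(-sc, xs, ys)
  detections[[ord[1]]]
}

#' @export
print.detection <- function(x, ...) {
  cat(sprintf("<detection %s score=%.3f>\n", format(x$box), x$score))
  invisible(x)
}

# ---- model serialization and external detections ----------------------------

#' Save / load a detector model as JSON
#'
#' @param model A `detector_model`.
#' @param path JSON file path.
#' @return `save_detector`: `path` invisibly. `load_detector`: the model.
#' @export
save_detector <- function(model, path) {
  payload <- list(
    config = model$config[setdiff(names(model$config), NULL)],
    n_pos = model$n_pos, seed = model$seed,
    stages = lapply(model$stages, function(st) {
      list(threshold = st$threshold, stumps = st$stumps)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- p$config
  config <- detector_config(
    window = as.integer(cfg$window), cell = cfg$cell, block = cfg$block,
    bins = cfg$bins, n_stages = cfg$n_stages,
    learners_per_stage = cfg$learners_per_stage,
    stage_recall = cfg$stage_recall, scale_steps = cfg$scale_steps,
    stride = cfg$stride, score_threshold = cfg$score_threshold,
    nms_iou = cfg$nms_iou, smooth_sigma = cfg$smooth_sigma,
    neg_per_image = cfg$neg_per_image
  )
  stages <- lapply(seq_along(p$stages$threshold), function(k) {
    list(threshold = p$stages$threshold[k],
         stumps = as.data.frame(p$stages$stumps[[k]]))
  })
  structure(list(stages = stages, config = config, n_pos = p$n_pos,
                 seed = p$seed), class = "detector_model")
}

#' Read detections produced by an external detector
#'
#' Accepts either a CSV with columns `image_id, x, y, w, h` (optional
#' `score`, default 1) or a directory of VOC-style XML files (one per
#' image; see [voc_read()] for the corner dialect). Boxes are returned in
#' the package's 0-based half-open convention.
#'
#' @param path CSV file or directory of `.xml` files.
#' @return Named list: per image id, a list of `detection` objects (empty
#'   for images annotated with no objects).
#' @export
load_external_detections <- function(path) {
  rows <- if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.xml$", full.names = TRUE)
    purrr::map_dfr(files, function(f) {
      df <- voc_read(f)
      if (nrow(df) == 0) {
        id <- xml2::xml_text(xml2::xml_find_first(xml2::read_xml(f),
                                                  "./filename"))
        return(tibble(image_id = id, x = NA_real_, y = NA_real_,
                      w = NA_real_, h = NA_real_, score = NA_real_))
      }
      df$score <- 1
      df[, c("image_id", "x", "y", "w", "h", "score")]
    })
  } else {
    df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                   error = function(e) abort(sprintf(
                     "malformed detections CSV '%s': %s", path,
                     conditionMessage(e))))
    need <- c("image_id", "x", "y", "w", "h")
    if (!all(need %in% names(df))) {
      abort(sprintf("detections CSV '%s' must have columns %s",
                    path, paste(need, collapse = ", ")))
    }
    bad <- which(!is.na(df$w) & (df$w <= 0 | df$h <= 0))
    if (length(bad) > 0) {
      abort(sprintf("detections CSV '%s': non-positive box size at row %d",
                    path, bad[1]))
    }
    df$score <- df$score %||% 1
    as_tibble(df[, c("image_id", "x", "y", "w", "h", "score")])
  }
  split(rows, rows$image_id) |>
    purrr::map(function(g) {
      g <- g[!is.na(g$x), , drop = FALSE]
      purrr::pmap(g[, c("x", "y", "w", "h", "score")],
                  function(x, y, w, h, score) {
                    structure(list(box = bbox(x, y, w, h), score = score),
                              class = "detection")
                  })
    })
}
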