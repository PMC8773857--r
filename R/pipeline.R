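# End-to-end orchestration: generate phantom pools, augment, train and run
# the detector, evaluate detections, extract per-mask-source radiomics,
# select signatures, classify, and compare mask sources against the
# manual-segmentation gold standard.

#' Experiment configuration
#'
#' Two seeded phantom pools mirror the study design: a detection pool
#' (train/validation/test split) and a classification pool (feature
#' selection subset + classification train/test). Every stochastic stage
#' draws its own child seed from `seed`.
#'
#' @param seed Master integer seed.
#' @param n_detection `c(benign, malignant)` counts of the detection pool.
#' @param n_classification Counts of the classification pool.
#' @param height,width Phantom frame size. The desk-scale default (280 x
#'   320) keeps a full run in the minutes range; pass 600 x 700 for
#'   full-size frames.
#' @param dataset_spec Augmentation assembly (`"D1"`..`"D8"`) recorded for
#'   the detector-training stage.
#' @param augment_training If `TRUE`, the detector trains on the augmented
#'   set (slower); otherwise on the original frames, with the multiplier
#'   still recorded.
#' @param detector [detector_config()] used for the cascade; the default is
#'   the desk-scale configuration (coarse 16-pixel cells, dense stride, six
#'   scales, jittered positives) validated on the phantom cohorts.
#' @param box_source `"detector"` (run the cascade on the classification
#'   pool) or `"external"` (simulated external detector: jittered
#'   ground-truth boxes read back through the detections adapter).
#' @param external_jitter_sd Box jitter of the simulated external
#'   detector, normalized units.
#' @param radiomics [radiomics_config()] for feature extraction.
#' @param classifiers Named list of [knn_spec()] per mask source (default:
#'   weighted KNN for `manual`, subspace-ensemble KNN for the box source).
#' @param folds LASSO cross-validation folds.
#' @param thresholds Joint IoU/LE outcome thresholds.
#' @param split_fractions Classification pool fractions
#'   `c(feature_selection, train, test)`.
#' @param output_dir Optional artifact directory.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(seed = 1L,
                              n_detection = c(20L, 20L),
                              n_classification = c(70L, 70L),
                              height = 280L, width = 320L,
                              dataset_spec = "D6",
                              augment_training = FALSE,
                              detector = detector_config(
                                cell = 16L, n_stages = 5L,
                                learners_per_stage = 25L, stride = 1L,
                                scale_steps = c(0.6, 0.75, 0.9, 1.1, 1.3, 1.6),
                                pos_jitter_per_image = 8L,
                                neg_per_image = 10L),
                              box_source = c("external", "detector"),
                              external_jitter_sd = 0.02,
                              radiomics = radiomics_config(
                                image_types = c("original", "LoG",
                                                "gradient", "wavelet_HH")),
                              classifiers = NULL,
                              folds = 10L,
                              thresholds = joint_thresholds(),
                              split_fractions = c(0.5, 0.285, 0.215),
                              output_dir = NULL) {
  box_source <- match.arg(box_source)
  cfg <- list(
    seed = as.integer(seed), n_detection = n_detection,
    n_classification = n_classification,
    height = as.integer(height), width = as.integer(width),
    dataset_spec = dataset_spec, augment_training = augment_training,
    detector = detector, box_source = box_source,
    external_jitter_sd = external_jitter_sd, radiomics = radiomics,
    classifiers = classifiers, folds = as.integer(folds),
    thresholds = thresholds, split_fractions = split_fractions,
    output_dir = output_dir
  )
  class(cfg) <- "experiment_config"
  cfg
}

# Stratified 3-way index split by label with given fractions.
split_pool <- function(labels, fractions, seed) {
  stopifnot(abs(sum(fractions) - 1) < 1e-6)
  grp <- character(length(labels))
  withr::with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      n <- length(idx)
      n1 <- round(fractions[1] * n)
      n2 <- round(fractions[2] * n)
      grp[idx[seq_len(n1)]] <- "fs"
      grp[idx[n1 + seq_len(n2)]] <- "train"
      grp[idx[(n1 + n2 + 1):n]] <- "test"
    }
  })
  grp
}

#' Run the full synthetic study
#'
#' Stages: (1) detection pool generation and split, (2) augmentation
#' accounting (and optionally augmented training), (3) cascade training,
#' (4) detection + joint IoU/LE evaluation on the detection test split,
#' (5) classification pool generation and split, (6) box acquisition for
#' every classification image, (7) per-mask-source radiomics extraction
#' with shared filter stacks, (8) normalization on the feature-selection
#' subset and LASSO signature selection per source, (9) KNN training and
#' common-test-split evaluation with DeLong comparisons. The feature
#' selection subset and the classification test split are disjoint by
#' construction, which is asserted.
#'
#' @param config An [experiment_config()].
#' @return A `boxsig_experiment` list: detection report, signatures,
#'   eval report, stage metadata; artifacts on disk when `output_dir`
#'   is set.
#' @export
run_experiment <- function(config = experiment_config()) {
  t0 <- Sys.time()
  seed <- config$seed
  log_stage <- function(fmt, ...) {
    message(sprintf("[boxsig %5.1fs] %s",
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    sprintf(fmt, ...)))
  }

  # --- stage 1: detection pool ----------------------------------------------
  log_stage("generating detection pool (%d benign + %d malignant)",
            config$n_detection[1], config$n_detection[2])
  det_pool <- generate_cohort(config$n_detection[1], config$n_detection[2],
                              seed = child_seed(seed, 11L),
                              height = config$height, width = config$width)
  det_grp <- split_pool(det_pool$manifest$label, c(0.25, 0.375, 0.375),
                        child_seed(seed, 12L))
  train_imgs <- det_pool$images[det_grp == "fs"]      # detector training
  test_imgs <- det_pool$images[det_grp == "test"]

  # --- stage 2: augmentation --------------------------------------------------
  specs <- dataset_specs()
  multiplier <- specs$multiplier[match(config$dataset_spec, specs$id)]
  if (config$augment_training) {
    log_stage("augmenting %d training images with %s (x%d)",
              length(train_imgs), config$dataset_spec, multiplier)
    aug <- assemble_dataset(train_imgs, config$dataset_spec)
    ok <- !is.na(aug$x)
    train_set <- purrr::pmap(aug[ok, ], function(image, x, y, w, h, ...) {
      list(image = image, gt_box = bbox(x, y, w, h), gt_mask = NULL)
    })
    # boxes only; masks are rebuilt from boxes inside sample_rois
    train_set <- purrr::map(train_set, function(t) {
      t$gt_mask <- box_to_mask(t$gt_box, dim(t$image)); t
    })
  } else {
    train_set <- train_imgs
  }

  # --- stage 3-4: detector ----------------------------------------------------
  log_stage("training cascade on %d images", length(train_set))
  model <- train_cascade(train_set, config$detector,
                         seed = child_seed(seed, 13L))
  log_stage("detecting on %d test images", length(test_imgs))
  detections <- purrr::map(test_imgs, function(im) {
    select_primary(detect(model, im$image))
  })
  det_report <- evaluate_detections(
    detections, purrr::map(test_imgs, "annotator_boxes"),
    dims = c(config$height, config$width), thresholds = config$thresholds)
  det_report$recall_iou <- recall_curve(det_report$per_image, "iou")
  det_report$recall_le <- recall_curve(det_report$per_image, "le")

  # --- stage 5: classification pool -------------------------------------------
  log_stage("generating classification pool (%d benign + %d malignant)",
            config$n_classification[1], config$n_classification[2])
  cls_pool <- generate_cohort(config$n_classification[1],
                              config$n_classification[2],
                              seed = child_seed(seed, 21L),
                              height = config$height, width = config$width)
  labels <- cls_pool$manifest$label
  grp <- split_pool(labels, config$split_fractions, child_seed(seed, 22L))
  stopifnot(!any(grp == "fs" & grp == "test"))  # disjoint by construction

  # --- stage 6: boxes for the classification pool ------------------------------
  log_stage("acquiring detection boxes (%s)", config$box_source)
  boxes <- if (config$box_source == "detector") {
    purrr::map(cls_pool$images, function(im) {
      select_primary(detect(model, im$image))
    })
  } else {
    # simulated external detector written to and read back through the
    # detections adapter, so the file pathway is exercised end to end
    csv <- tempfile(fileext = ".csv")
    rows <- purrr::imap_dfr(cls_pool$images, function(im, i) {
      jb <- emulate_annotators(im$gt_box, n_users = 1L,
                               jitter_sd = config$external_jitter_sd,
                               seed = child_seed(seed, 3000L + i),
                               dims = dim(im$image))[[1]]
      tibble(image_id = sprintf("phantom_%03d", i), x = jb$x, y = jb$y,
             w = jb$w, h = jb$h, score = 1)
    })
    utils::write.csv(rows, csv, row.names = FALSE)
    ext <- load_external_detections(csv)
    purrr::map(seq_along(cls_pool$images), function(i) {
      dl <- ext[[sprintf("phantom_%03d", i)]]
      if (is.null(dl) || length(dl) == 0) NULL else dl[[1]]
    })
  }

  # --- stage 7: radiomics -----------------------------------------------------
  log_stage("extracting radiomics (%d image types, %d images x 2 sources)",
            length(config$radiomics$image_types), length(cls_pool$images))
  stacks <- purrr::map(cls_pool$images, function(im) {
    image_type_stack(im$image, config$radiomics)
  })
  tab_manual <- extract_cohort(cls_pool$images, "manual", config$radiomics,
                               mask_source = "manual", stacks = stacks)
  tab_box <- extract_cohort(cls_pool$images, boxes, config$radiomics,
                            mask_source = "detector-box", stacks = stacks)
  tables <- list(manual = tab_manual, `detector-box` = tab_box)

  # --- stage 8: normalization + signatures -------------------------------------
  log_stage("selecting signatures (LASSO, %d-fold CV)", config$folds)
  fs_idx <- grp == "fs"
  sigs <- purrr::imap(tables, function(tab, src) {
    norm_fs <- zscore_normalize(tab[fs_idx, , drop = FALSE])
    normed <- zscore_normalize(tab, reference_stats = norm_fs$stats)$table
    tables[[src]] <<- normed
    cv <- cv_select_lambda(normed[fs_idx, ], labels[fs_idx],
                           k = config$folds, seed = child_seed(seed, 31L))
    select_signature(normed[fs_idx, ], labels[fs_idx], cv$lambda,
                     mask_source = src)
  })

  # --- stage 9: classification + comparison ------------------------------------
  log_stage("training classifiers and comparing mask sources")
  cls_idx <- grp != "fs"
  specs_knn <- config$classifiers %||% list(
    manual = knn_spec("weighted", k = 10L),
    `detector-box` = knn_spec("subspace_ensemble")
  )
  cls_tables <- purrr::map(tables, function(t) t[cls_idx, , drop = FALSE])
  test_frac <- config$split_fractions[3] /
    (config$split_fractions[2] + config$split_fractions[3])
  report <- compare_mask_sources(cls_tables, sigs, specs_knn,
                                 test_fraction = test_frac,
                                 seed = child_seed(seed, 41L))
  # the classification test rows must be disjoint from the FS subset
  test_ids <- which(cls_idx)[report$test_index]
  stopifnot(!any(test_ids %in% which(fs_idx)))

  # the hash identifies the scientific configuration; the artifact
  # directory is not part of it
  hash_cfg <- config[setdiff(names(config), "output_dir")]
  out <- structure(list(
    config = config,
    config_hash = rlang::hash(hash_cfg),
    detection = det_report,
    detector = model,
    signatures = sigs,
    report = report,
    augmentation_multiplier = multiplier,
    groups = list(detection = det_grp, classification = grp),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "boxsig_experiment")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$output_dir
    jsonlite::write_json(list(
      config_hash = out$config_hash, seed = seed,
      augmentation = list(dataset_spec = config$dataset_spec,
                          multiplier = multiplier),
      detection = list(counts = det_report$counts,
                       summary = det_report$summary,
                       metrics = det_report$metrics),
      classification = list(metrics = report$metrics,
                            delong = report$delong)
    ), file.path(od, "report.json"), auto_unbox = TRUE, digits = NA)
    for (src in names(tables)) {
      utils::write.csv(tables[[src]],
                       file.path(od, paste0("features_", gsub("-", "_", src),
                                            ".csv")),
                       row.names = FALSE)
      save_signature(sigs[[src]],
                     file.path(od, paste0("signature_",
                                          gsub("-", "_", src), ".json")))
    }
    save_detector(model, file.path(od, "detector.json"))
  }
  out
}

#' @export
print.boxsig_experiment <- function(x, ...) {
  cat(sprintf("<boxsig_experiment seed=%d hash=%s (%.1fs)>\n",
              x$config$seed, substr(x$config_hash, 1, 8), x$elapsed_s))
  cat(sprintf("  augmentation: %s (x%d per image)\n",
              x$config$dataset_spec, x$augmentation_multiplier))
  cat(sprintf("  detection: recall %.2f precision %.2f (IoU %.2f +/- %.2f)\n",
              x$detection$metrics$recall, x$detection$metrics$precision,
              x$detection$summary$iou_mean %||% NA,
              x$detection$summary$iou_sd %||% NA))
  print(x$report)
  invisible(x)
}
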