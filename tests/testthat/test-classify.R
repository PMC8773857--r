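two_clusters <- function(seed = 1, n = 40, p = 4, sep = 10) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n / 2 * p), n / 2, p),
               matrix(rnorm(n / 2 * p, mean = sep), n / 2, p))
  })
  list(X = X, y = rep(c(0, 1), each = n / 2))
}

test_that("KNN scores behave at the limits and separate clusters", {
  d <- two_clusters()
  # evaluation point coinciding with a training point: that neighbor
  # dominates the inverse-squared-distance weights
  sc <- fit_predict(knn_spec("weighted", k = 5), d$X, d$y,
                    d$X[40, , drop = FALSE])
  expect_gt(sc, 0.999)
  ev <- rbind(matrix(rnorm(20), 5, 4), matrix(rnorm(20, mean = 10), 5, 4))
  for (v in c("weighted", "uniform", "subspace_ensemble")) {
    s <- fit_predict(knn_spec(v, k = 5), d$X, d$y, ev, seed = 3)
    expect_true(all(s[1:5] < 0.5) && all(s[6:10] > 0.5), info = v)
  }
  expect_error(fit_predict(knn_spec("uniform", k = 100), d$X, d$y, ev),
               "exceeds")
})

test_that("a degenerate subspace ensemble equals the uniform variant", {
  d <- two_clusters(seed = 2)
  ev <- withr::with_seed(9, matrix(rnorm(40), 10, 4))
  u <- fit_predict(knn_spec("uniform", k = 7), d$X, d$y, ev)
  e <- fit_predict(knn_spec("subspace_ensemble", n_learners = 1,
                            subspace_dim = 4, ensemble_k = 7),
                   d$X, d$y, ev, seed = 11)
  expect_equal(u, e)
})

test_that("validation schemes are restricted to the study's set", {
  expect_error(validation_scheme("kfold", folds = 3), "5 or 10")
  expect_error(validation_scheme("holdout", holdout_fraction = 0.5), "0.20")
  s <- validation_scheme("holdout", holdout_fraction = 0.25, seed = 2)
  expect_equal(s$holdout_fraction, 0.25)
})

test_that("out-of-sample validation is seeded and sane", {
  d <- two_clusters(n = 60)
  sch <- validation_scheme("kfold", folds = 5, seed = 4)
  v1 <- validate(knn_spec("uniform", k = 5), sch, d$X, d$y)
  v2 <- validate(knn_spec("uniform", k = 5), sch, d$X, d$y)
  expect_identical(v1$scores, v2$scores)
  expect_equal(nrow(v1$scores), 60)  # every sample scored out-of-fold
  expect_equal(v1$metrics$accuracy, 100)  # separable clusters
  # permuted labels: accuracy stays near chance (binomial 3-sd band)
  dd <- withr::with_seed(5, list(X = matrix(rnorm(100 * 4), 100, 4),
                                 y = rep(c(0, 1), 50)))
  vp <- validate(knn_spec("uniform", k = 5),
                 validation_scheme("kfold", folds = 5, seed = 6), dd$X, dd$y)
  expect_gte(vp$metrics$accuracy, 35)
  expect_lte(vp$metrics$accuracy, 65)
  # holdout scheme scores only the held-out fraction
  vh <- validate(knn_spec("uniform", k = 5),
                 validation_scheme("holdout", holdout_fraction = 0.3,
                                   seed = 7), d$X, d$y)
  expect_lt(nrow(vh$scores), 60)
})

test_that("confusion metrics reproduce the standard formulas in percent", {
  # counts consistent with a 36 malignant / 24 benign test split
  m <- confusion_metrics(tp = 30, tn = 21, fp = 3, fn = 6)
  expect_equal(m$sensitivity, 100 * 30 / 36)
  expect_equal(round(m$sensitivity, 2), 83.33)
  expect_equal(m$specificity, 87.5)
  expect_equal(m$accuracy, 85)
  expect_equal(unlist(confusion_metrics(10, 10, 0, 0)),
               c(sensitivity = 100, specificity = 100, accuracy = 100))
  expect_equal(unlist(confusion_metrics(1, 1, 1, 1)),
               c(sensitivity = 50, specificity = 50, accuracy = 50))
  expect_true(is.na(confusion_metrics(0, 5, 5, 0)$sensitivity))
  # accuracy decomposes into prevalence-weighted sensitivity/specificity
  cm <- confusion_metrics(17, 22, 8, 13)
  P <- 30; N <- 30
  expect_equal(cm$accuracy, (cm$sensitivity * P + cm$specificity * N) / (P + N))
})

test_that("AUROC equals the pairwise rank oracle exactly", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3))$auc, 1)
  expect_equal(roc_auc(rep(5, 10), rep(c(0, 1), 5))$auc, 0.5)
  withr::with_seed(13, {
    for (i in 1:5) {
      sc <- round(runif(200), 2)  # rounding forces ties
      y <- rbinom(200, 1, 0.5)
      if (length(unique(y)) < 2) next
      r <- roc_auc(sc, y)
      expect_equal(r$auc, pairwise_auc(sc, y), tolerance = 1e-12)
      expect_equal(r$points$tpr[1], 0)
      expect_equal(utils::tail(r$points$tpr, 1), 1)
    }
  })
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUROC and DeLong agree with the pROC reference", {
  skip_if_not_installed("pROC")
  withr::with_seed(21, {
    y <- rbinom(150, 1, 0.5)
    sa <- y * 1.2 + rnorm(150)
    sb <- y * 0.5 + rnorm(150)
  })
  r <- roc_auc(sa, y)
  pr <- pROC::roc(y, sa, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  dl <- delong_compare(sa, sb, y)
  ref <- pROC::roc.test(pr, pROC::roc(y, sb, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(dl$p, ref$p.value, tolerance = 1e-10)
  expect_equal(abs(dl$z), abs(as.numeric(ref$statistic)), tolerance = 1e-10)
})

test_that("DeLong's test handles identity, antisymmetry and paired power", {
  withr::with_seed(31, {
    y <- rep(c(0, 1), each = 60)
    sa <- y * 1.8 + rnorm(120)
    sb <- y * 0.7 + rnorm(120)
  })
  same <- delong_compare(sa, sa, y)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  ab <- delong_compare(sa, sb, y)
  ba <- delong_compare(sb, sa, y)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  # agreement with a stratified-bootstrap oracle on the same pair
  pboot <- bootstrap_auc_p(sa, sb, y, reps = 2000)
  expect_lt(abs(ab$p - pboot), 0.02)
})

test_that("mask-source comparison emits per-source metrics and DeLong rows", {
  withr::with_seed(41, {
    n <- 80
    base <- matrix(rnorm(n * 6), n, 6)
    y <- rep(c("benign", "malignant"), each = n / 2)
    shift <- (y == "malignant") * 1.5
    tab <- function(noise) {
      X <- base + shift + matrix(rnorm(n * 6, 0, noise), n, 6)
      colnames(X) <- paste0("f", 1:6)
      dplyr::bind_cols(tibble::tibble(label = y), tibble::as_tibble(X))
    }
    tables <- list(manual = tab(0.1), `detector-box` = tab(0.6),
                   fallback = tab(1.2))
  })
  sigs <- purrr::imap(tables, function(t, src) {
    select_signature(t, t$label, 0.01, mask_source = src)
  })
  rep <- compare_mask_sources(tables, sigs, knn_spec("uniform", k = 5),
                              test_fraction = 0.3, seed = 2)
  expect_equal(nrow(rep$metrics), 3)
  expect_equal(nrow(rep$delong), 2)
  expect_true(all(rep$metrics$auroc >= 0 & rep$metrics$auroc <= 1))
  expect_equal(tidy(rep), rep$metrics)
  expect_equal(glance(rep)$reference, "manual")
  # identical tables for two sources -> DeLong p = 1 between them
  t2 <- list(manual = tables$manual, copy = tables$manual)
  s2 <- list(manual = sigs$manual,
             copy = { s <- sigs$manual; s$mask_source <- "copy"; s })
  r2 <- compare_mask_sources(t2, s2, knn_spec("uniform", k = 5),
                             test_fraction = 0.3, seed = 2)
  expect_equal(r2$delong$p, 1)
  # sample mismatch across sources errors
  t3 <- list(manual = tables$manual, copy = tables$manual[c(41:80, 1:40), ])
  expect_error(compare_mask_sources(t3, s2, knn_spec("uniform", k = 5)),
               "identical samples")
})

test_that("degrading box quality never improves the box-derived model", {
  # small phantom cohort; boxes jittered at increasing severity
  co <- generate_cohort(14, 14, seed = 31, height = 160, width = 180)
  cfg <- radiomics_config(image_types = c("original", "gradient"))
  stacks <- purrr::map(co$images, function(im) image_type_stack(im$image, cfg))
  labels <- co$manifest$label
  auc_at <- function(jit, seed) {
    boxes <- purrr::imap(co$images, function(im, i) {
      emulate_annotators(im$gt_box, 1, jitter_sd = jit,
                         seed = seed * 1000 + i, dims = dim(im$image))[[1]]
    })
    tab <- extract_cohort(co$images, boxes, cfg, mask_source = "box",
                          stacks = stacks)
    normed <- zscore_normalize(tab)$table
    sig <- select_signature(normed, labels,
                            lambda_max(normed, labels) * 0.05, "box")
    X <- as.matrix(normed[, sig$features$feature, drop = FALSE])
    fold <- boxsig:::stratified_folds(labels, 3, seed)
    te <- fold == 1
    sc <- fit_predict(knn_spec("uniform", k = 5), X[!te, , drop = FALSE],
                      labels[!te], X[te, , drop = FALSE], seed = seed)
    roc_auc(sc, labels[te])$auc
  }
  med_auc <- vapply(c(0.02, 0.15, 0.5), function(jit) {
    median(vapply(1:3, function(s) auc_at(jit, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_auc) <= 0.05))  # non-increasing up to noise
})
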