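# KNN-family lesion classifiers, validation schemes, confusion metrics,
# ROC/AUROC and DeLong's paired test for correlated AUCs.

#' KNN classifier specification
#'
#' Three presets: `weighted` (inverse-squared-distance voting, k = 10),
#' `uniform` (equal-weight voting, k = 10 — the "medium k" preset), and
#' `subspace_ensemble` (random-subspace ensemble of 1-NN learners whose
#' per-learner scores are averaged).
#'
#' @param variant `"weighted"`, `"uniform"` or `"subspace_ensemble"`.
#' @param k Neighbor count (base learners use `ensemble$k`).
#' @param n_learners,subspace_dim,ensemble_k Ensemble settings; the
#'   subspace dimension defaults to `ceiling(p / 2)` at fit time.
#' @return A `knn_spec` list.
#' @export
knn_spec <- function(variant = c("weighted", "uniform", "subspace_ensemble"),
                     k = 10L, n_learners = 30L, subspace_dim = NULL,
                     ensemble_k = 1L) {
  variant <- match.arg(variant)
  structure(list(variant = variant, k = as.integer(k),
                 n_learners = as.integer(n_learners),
                 subspace_dim = subspace_dim,
                 ensemble_k = as.integer(ensemble_k)),
            class = "knn_spec")
}

pairwise_dist2 <- function(A, B) {
  # squared Euclidean distances, rows of A x rows of B
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, `+`) - 2 * A %*% t(B)
  pmax(d2, 0)
}

knn_scores_core <- function(Xtr, ytr, Xev, k, weighted) {
  d2 <- pairwise_dist2(Xev, Xtr)
  eps <- 1e-8
  vapply(seq_len(nrow(Xev)), function(i) {
    ord <- order(d2[i, ])[seq_len(k)]
    if (weighted) {
      w <- 1 / (d2[i, ord] + eps)
      sum(w * ytr[ord]) / sum(w)
    } else {
      mean(ytr[ord])
    }
  }, numeric(1))
}

#' Score evaluation samples with a KNN model
#'
#' Returns malignancy scores in `[0, 1]`: the (weighted) fraction of
#' malignant neighbors, or for the subspace ensemble the average of the
#' per-learner 1-NN scores over seeded random feature subspaces.
#'
#' @param spec A [knn_spec()].
#' @param X_train,X_eval Feature tables or matrices (signature-restricted,
#'   normalized).
#' @param y_train Binary labels of the training rows.
#' @param seed Seed for the subspace sampling (ignored by the plain
#'   variants).
#' @return Numeric score vector, one per evaluation row.
#' @export
fit_predict <- function(spec, X_train, y_train, X_eval, seed = 1L) {
  Xtr <- as_design(X_train); Xev <- as_design(X_eval)
  ytr <- as_binary(y_train)
  if (spec$variant != "subspace_ensemble" && spec$k > nrow(Xtr)) {
    abort(sprintf("k = %d exceeds the %d training samples", spec$k, nrow(Xtr)))
  }
  switch(spec$variant,
    weighted = knn_scores_core(Xtr, ytr, Xev, spec$k, weighted = TRUE),
    uniform = knn_scores_core(Xtr, ytr, Xev, spec$k, weighted = FALSE),
    subspace_ensemble = {
      p <- ncol(Xtr)
      dim_ <- spec$subspace_dim %||% ceiling(p / 2)
      if (dim_ > p) abort("subspace_dim exceeds the feature count")
      if (spec$ensemble_k > nrow(Xtr)) {
        abort(sprintf("ensemble k = %d exceeds the %d training samples",
                      spec$ensemble_k, nrow(Xtr)))
      }
      scores <- matrix(0, nrow(Xev), spec$n_learners)
      withr::with_seed(seed, {
        for (l in seq_len(spec$n_learners)) {
          fs <- sample.int(p, dim_)
          scores[, l] <- knn_scores_core(Xtr[, fs, drop = FALSE], ytr,
                                         Xev[, fs, drop = FALSE],
                                         spec$ensemble_k, weighted = FALSE)
        }
      })
      rowMeans(scores)
    }
  )
}

#' Validation scheme
#'
#' @param kind `"kfold"` or `"holdout"`.
#' @param folds 5 or 10 (k-fold).
#' @param holdout_fraction 0.20, 0.25 or 0.30 (holdout).
#' @param seed Integer seed for the split.
#' @return A `validation_scheme` list.
#' @export
validation_scheme <- function(kind = c("kfold", "holdout"), folds = 5L,
                              holdout_fraction = 0.30, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "kfold" && !folds %in% c(5L, 10L)) {
    abort("folds must be 5 or 10")
  }
  if (kind == "holdout" && !holdout_fraction %in% c(0.20, 0.25, 0.30)) {
    abort("holdout_fraction must be 0.20, 0.25 or 0.30")
  }
  structure(list(kind = kind, folds = as.integer(folds),
                 holdout_fraction = holdout_fraction, seed = as.integer(seed)),
            class = "validation_scheme")
}

#' Out-of-sample validation of a KNN spec
#'
#' Stratified k-fold (every sample scored out-of-fold) or a single
#' stratified holdout split; outcomes are thresholded at 0.5 for the
#' confusion counts.
#'
#' @param spec A [knn_spec()].
#' @param scheme A [validation_scheme()].
#' @param X Feature table or matrix.
#' @param y Binary labels.
#' @return List with `scores` (tibble: row, fold, y, score), `confusion`
#'   (tp/tn/fp/fn tibble) and `metrics` ([confusion_metrics()] output).
#' @export
validate <- function(spec, scheme, X, y) {
  Xm <- as_design(X); yb <- as_binary(y)
  if (scheme$kind == "kfold") {
    fold <- stratified_folds(yb, scheme$folds, scheme$seed)
    rows <- purrr::map_dfr(seq_len(scheme$folds), function(f) {
      tr <- fold != f; ev <- fold == f
      sc <- fit_predict(spec, Xm[tr, , drop = FALSE], yb[tr],
                        Xm[ev, , drop = FALSE],
                        seed = child_seed(scheme$seed, f))
      tibble(row = which(ev), fold = f, y = yb[ev], score = sc)
    })
    rows <- dplyr::arrange(rows, .data$row)
  } else {
    # fold count approximates the requested holdout fraction as closely as
    # stratification allows
    fold <- stratified_folds(yb, max(2L, round(1 / scheme$holdout_fraction)),
                             scheme$seed)
    ev <- fold == 1L
    sc <- fit_predict(spec, Xm[!ev, , drop = FALSE], yb[!ev],
                      Xm[ev, , drop = FALSE],
                      seed = child_seed(scheme$seed, 99L))
    rows <- tibble(row = which(ev), fold = 1L, y = yb[ev], score = sc)
  }
  cc <- confusion_counts(rows$y, rows$score)
  list(scores = rows, confusion = cc,
       metrics = confusion_metrics(cc$tp, cc$tn, cc$fp, cc$fn))
}

#' Confusion counts at a score threshold
#'
#' A sample is called malignant when its score exceeds the threshold.
#'
#' @param y Binary labels (1 = malignant).
#' @param scores Numeric scores.
#' @param threshold Decision threshold (default 0.5).
#' @return One-row tibble: tp, tn, fp, fn.
#' @export
confusion_counts <- function(y, scores, threshold = 0.5) {
  y <- as_binary(y)
  pred <- scores > threshold
  tibble(
    tp = sum(pred & y == 1), tn = sum(!pred & y == 0),
    fp = sum(pred & y == 0), fn = sum(!pred & y == 1)
  )
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `accuracy = (TP + TN) / total`, reported in percent. A zero denominator
#' yields `NA` for that metric (flagged undefined rather than fabricated).
#'
#' @param tp,tn,fp,fn Confusion counts.
#' @return One-row tibble with the three metrics in percent.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  tibble(
    sensitivity = pct(tp, tp + fn),
    specificity = pct(tn, tn + fp),
    accuracy = pct(tp + tn, tp + tn + fp + fn)
  )
}

#' ROC curve and AUROC
#'
#' The curve sweeps every observed score threshold; the area equals the
#' rank statistic `P(score+ > score-) + 0.5 P(tie)` exactly.
#'
#' @param scores Numeric scores (higher = more malignant).
#' @param labels Binary labels; both classes must be present.
#' @return A `roc_result`: list with `points` (tibble: threshold, fpr,
#'   tpr) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary(labels)
  npos <- sum(y == 1); nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0) abort("both classes are required for a ROC curve")
  # rank-based AUC (midranks handle ties)
  r <- rank(scores)
  auc <- (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- purrr::map_dfr(thr, function(t) {
    pred <- scores >= t
    tibble(threshold = t,
           fpr = sum(pred & y == 0) / nneg,
           tpr = sum(pred & y == 1) / npos)
  })
  structure(list(points = pts, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result AUROC = %.4f, %d points>\n", x$auc,
              nrow(x$points)))
  invisible(x)
}

#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC (AUROC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

# Placement values of each positive against all negatives (and vice
# versa) for one score vector.
placements <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  v10 <- vapply(pos, function(s) mean((s > neg) + 0.5 * (s == neg)),
                numeric(1))
  v01 <- vapply(neg, function(s) mean((pos > s) + 0.5 * (pos == s)),
                numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong's test for two correlated AUCs
#'
#' Paired comparison of the AUROCs of two score vectors computed on the
#' same samples, via the placement-value (structural component)
#' formulation with a two-sided normal p-value.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Binary labels shared by both.
#' @return One-row tibble: `auc_a`, `auc_b`, `z`, `p`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  y <- as_binary(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(y)) {
    abort("scores_a, scores_b and labels must have equal length")
  }
  pa <- placements(scores_a, y); pb <- placements(scores_b, y)
  m <- length(pa$v10); n <- length(pa$v01)
  V10 <- cbind(pa$v10, pb$v10); V01 <- cbind(pa$v01, pb$v01)
  S10 <- stats::cov(V10); S01 <- stats::cov(V01)
  var_diff <- (S10[1, 1] + S10[2, 2] - 2 * S10[1, 2]) / m +
              (S01[1, 1] + S01[2, 2] - 2 * S01[1, 2]) / n
  dauc <- pa$auc - pb$auc
  if (var_diff <= 0) {
    if (abs(dauc) < 1e-12) {
      return(tibble(auc_a = pa$auc, auc_b = pb$auc, z = 0, p = 1))
    }
    abort("zero variance of the AUC difference with unequal AUCs")
  }
  z <- dauc / sqrt(var_diff)
  tibble(auc_a = pa$auc, auc_b = pb$auc, z = z, p = 2 * pnorm(-abs(z)))
}

#' Compare classifiers built from different mask sources
#'
#' The gold-standard comparison design: one feature table per mask source on
#' identical samples; each source gets its own signature and classifier, all are
#' evaluated on a common stratified train/test split, and every non-first
#' source is compared to the first (the manual-segmentation gold standard)
#' with DeLong's test.
#'
#' @param tables Named list of wide feature tables (same rows, same
#'   `label` column); first entry is the reference source.
#' @param signatures Named list of `signature` objects (same names).
#' @param specs Named list of [knn_spec()]s (recycled if length 1).
#' @param test_fraction Fraction held out for testing (stratified).
#' @param seed Integer seed (split + ensemble sampling).
#' @return An `eval_report`: per-source metrics/ROC tibbles plus DeLong
#'   comparisons.
#' @export
compare_mask_sources <- function(tables, signatures, specs,
                                 test_fraction = 0.30, seed = 1L) {
  srcs <- names(tables)
  stopifnot(length(srcs) >= 2, !is.null(srcs),
            identical(sort(srcs), sort(names(signatures))))
  n <- nrow(tables[[1]])
  labs <- tables[[1]]$label
  for (s in srcs) {
    if (nrow(tables[[s]]) != n || !identical(tables[[s]]$label, labs)) {
      abort("feature tables must cover identical samples in the same order")
    }
  }
  if (inherits(specs, "knn_spec")) specs <- setNames(
    rep(list(specs), length(srcs)), srcs)
  y <- as_binary(labs)
  kk <- max(2L, round(1 / test_fraction))
  fold <- stratified_folds(y, kk, seed)
  test <- fold == 1L
  scores <- list(); rocs <- list(); metrics <- list()
  for (s in srcs) {
    feats <- signatures[[s]]$features$feature
    feats <- intersect(feats, names(tables[[s]]))
    Xs <- as.matrix(tables[[s]][, feats, drop = FALSE])
    sc <- fit_predict(specs[[s]], Xs[!test, , drop = FALSE], y[!test],
                      Xs[test, , drop = FALSE],
                      seed = child_seed(seed, match(s, srcs)))
    scores[[s]] <- sc
    rocs[[s]] <- roc_auc(sc, y[test])
    cc <- confusion_counts(y[test], sc)
    metrics[[s]] <- dplyr::bind_cols(
      tibble(mask_source = s, auroc = rocs[[s]]$auc,
             n_features = nrow(signatures[[s]]$features)),
      cc, confusion_metrics(cc$tp, cc$tn, cc$fp, cc$fn))
  }
  ref <- srcs[1]
  delong <- purrr::map_dfr(srcs[-1], function(s) {
    dplyr::mutate(delong_compare(scores[[s]], scores[[ref]], y[test]),
                  comparison = paste(s, "vs", ref), .before = 1)
  })
  structure(list(
    metrics = dplyr::bind_rows(metrics), rocs = rocs, delong = delong,
    scores = scores, test_index = which(test), labels = y,
    reference = ref, seed = seed
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report reference = %s>\n", x$reference))
  print(x$metrics)
  if (nrow(x$delong) > 0) print(x$delong)
  invisible(x)
}

#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$metrics

#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble(
    n_sources = nrow(x$metrics), n_test = length(x$test_index),
    reference = x$reference,
    auroc_reference = x$metrics$auroc[x$metrics$mask_source == x$reference],
    min_delong_p = if (nrow(x$delong) > 0) min(x$delong$p) else NA_real_
  )
}

#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  pts <- purrr::imap_dfr(object$rocs, function(r, s) {
    dplyr::mutate(r$points, mask_source = s)
  })
  ggplot2::ggplot(pts, ggplot2::aes(.data$fpr, .data$tpr,
                                    colour = .data$mask_source)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = "ROC by mask source") +
    ggplot2::theme_minimal()
}
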