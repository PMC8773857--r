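# Radiomics signature selection: L1-penalized logistic regression over a
# descending lambda path (via glmnet) with a stratified, seeded 10-fold
# cross-validated penalty search, per mask-source feature table.

# Coerce a feature table (wide tibble or matrix) to the design matrix.
as_design <- function(X) {
  if (is.matrix(X)) return(X)
  numcols <- names(X)[vapply(X, is.numeric, logical(1))]
  numcols <- setdiff(numcols, c("seed"))
  as.matrix(X[, numcols, drop = FALSE])
}

as_binary <- function(y) {
  if (is.factor(y) || is.character(y)) {
    y <- as.integer(factor(y, levels = sort(unique(as.character(y))))) - 1L
    if (any(!y %in% c(0L, 1L))) abort("labels must be binary")
    return(y)
  }
  if (!all(y %in% c(0, 1))) abort("labels must be binary (0/1)")
  as.integer(y)
}

#' Smallest penalty that zeroes every coefficient
#'
#' For the intercept-only logistic model, `lambda_max = max_j |x_j' (y -
#' mean(y))| / n`; any penalty at or above it yields the null model.
#'
#' @param X Feature table or matrix (assumed pre-normalized).
#' @param y Binary labels.
#' @return Scalar lambda.
#' @export
lambda_max <- function(X, y) {
  X <- as_design(X); y <- as_binary(y)
  max(abs(crossprod(X, y - mean(y)))) / nrow(X)
}

default_lambda_grid <- function(X, y, n = 100) {
  lmax <- lambda_max(X, y)
  exp(seq(log(lmax), log(lmax * 1e-4), length.out = n))
}

#' L1-penalized logistic path
#'
#' Fits the binomial LASSO along a descending, warm-started lambda grid
#' (100 log-spaced values from `lambda_max` down to `lambda_max * 1e-4`
#' by default). Features are assumed already normalized, so no internal
#' re-standardization is applied; the intercept is unpenalized.
#'
#' @param X Feature table or matrix.
#' @param y Binary labels (both classes must be present).
#' @param lambdas Optional decreasing penalty grid.
#' @return A `lasso_path` object wrapping the fit.
#' @export
lasso_path <- function(X, y, lambdas = NULL) {
  Xm <- as_design(X); yb <- as_binary(y)
  if (length(unique(yb)) < 2) abort("both classes must be present in y")
  lambdas <- lambdas %||% default_lambda_grid(Xm, yb)
  fit <- glmnet::glmnet(Xm, yb, family = "binomial",
                        lambda = sort(lambdas, decreasing = TRUE),
                        standardize = FALSE, thresh = 1e-12, maxit = 1e6)
  structure(list(fit = fit, lambdas = fit$lambda,
                 features = colnames(Xm)), class = "lasso_path")
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf("<lasso_path %d features, %d lambdas [%.3g .. %.3g]>\n",
              length(x$features), length(x$lambdas),
              max(x$lambdas), min(x$lambdas)))
  invisible(x)
}

#' Coefficients of a `lasso_path` at a given penalty
#'
#' @param object A `lasso_path`.
#' @param lambda Penalty value.
#' @param ... Unused.
#' @return Named numeric vector (intercept first).
#' @export
coef.lasso_path <- function(object, lambda, ...) {
  cf <- coef(object$fit, s = lambda, exact = FALSE)
  setNames(as.numeric(cf), rownames(cf))
}

#' @method tidy lasso_path
#' @export
tidy.lasso_path <- function(x, lambda = min(x$lambdas), ...) {
  cf <- coef(x, lambda)
  tibble(term = names(cf), estimate = unname(cf), lambda = lambda)
}

# Stratified fold assignment; every fold holds both classes.
stratified_folds <- function(y, k, seed) {
  y <- as_binary(y)
  if (min(table(y)) < k) {
    abort(sprintf("cannot build %d stratified folds: smallest class has %d samples",
                  k, min(table(y))))
  }
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Cross-validated penalty search
#'
#' Stratified, seeded k-fold cross-validation of the binomial deviance
#' along the lambda path; the minimum-deviance rule picks the penalty.
#'
#' @param X Feature table or matrix (pre-normalized).
#' @param y Binary labels.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param lambdas Optional penalty grid.
#' @return List with `lambda` (the selected penalty), `cv` (tibble:
#'   lambda, mean cross-validated deviance, sd) and `n_nonzero` at the
#'   selected penalty.
#' @export
cv_select_lambda <- function(X, y, k = 10, seed = 1L, lambdas = NULL) {
  Xm <- as_design(X); yb <- as_binary(y)
  if (nrow(Xm) < k) abort("need at least k samples for k folds")
  lambdas <- lambdas %||% default_lambda_grid(Xm, yb)
  foldid <- stratified_folds(yb, k, seed)
  cvfit <- glmnet::cv.glmnet(Xm, yb, family = "binomial",
                             lambda = sort(lambdas, decreasing = TRUE),
                             foldid = foldid, type.measure = "deviance",
                             standardize = FALSE, thresh = 1e-10)
  sel <- cvfit$lambda.min
  nz <- cvfit$nzero[match(sel, cvfit$lambda)]
  list(
    lambda = sel,
    cv = tibble(lambda = cvfit$lambda, mean_deviance = cvfit$cvm,
                sd = cvfit$cvsd),
    n_nonzero = unname(nz)
  )
}

#' Select a radiomics signature at a given penalty
#'
#' Features with nonzero coefficients at `lambda`, ordered by absolute
#' coefficient descending.
#'
#' @param X Feature table or matrix (pre-normalized).
#' @param y Binary labels.
#' @param lambda Penalty (typically from [cv_select_lambda()]).
#' @param mask_source Provenance tag (`"manual"`, `"detector-box"`, ...).
#' @return A `signature` object: tibble of features + coefficients,
#'   lambda, intercept, mask_source.
#' @export
select_signature <- function(X, y, lambda, mask_source = "manual") {
  path <- lasso_path(X, y, lambdas = unique(sort(
    c(default_lambda_grid(as_design(X), as_binary(y)), lambda),
    decreasing = TRUE)))
  cf <- coef(path, lambda)
  beta <- cf[-1]
  nz <- which(abs(beta) > 0)
  if (length(nz) == 0) {
    abort(sprintf(
      "no features selected at lambda = %.4g (lambda_max = %.4g); try a smaller penalty",
      lambda, lambda_max(X, y)))
  }
  ord <- nz[order(abs(beta[nz]), decreasing = TRUE)]
  structure(list(
    features = tibble(feature = names(beta)[ord],
                      coefficient = unname(beta[ord])),
    lambda = lambda, intercept = unname(cf[1]), mask_source = mask_source
  ), class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("<signature [%s] %d features, lambda = %.4g>\n",
              x$mask_source, nrow(x$features), x$lambda))
  print(utils::head(x$features, 5))
  invisible(x)
}

#' @method tidy signature
#' @export
tidy.signature <- function(x, ...) {
  dplyr::mutate(x$features, lambda = x$lambda, mask_source = x$mask_source)
}

#' @method glance signature
#' @export
glance.signature <- function(x, ...) {
  tibble(mask_source = x$mask_source, lambda = x$lambda,
         n_features = nrow(x$features))
}

#' Save a signature as JSON
#'
#' @param sig A `signature`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_signature <- function(sig, path) {
  jsonlite::write_json(list(
    mask_source = sig$mask_source, lambda = sig$lambda,
    intercept = sig$intercept, features = sig$features
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
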