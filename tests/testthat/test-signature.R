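sim_design <- function(seed, n = 200, p = 100, n_info = 5, beta = 2) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- sprintf("f%03d", seq_len(p))
    eta <- X[, seq_len(n_info), drop = FALSE] %*% rep(beta, n_info)
    y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  })
  list(X = X, y = y)
}

test_that("penalties at or above lambda_max give the null model", {
  d <- sim_design(1)
  lmax <- lambda_max(d$X, d$y)
  path <- lasso_path(d$X, d$y, lambdas = lmax * c(1.5, 1.2))
  cf <- coef(path, lmax * 1.2)
  expect_true(all(cf[-1] == 0))
  expect_error(select_signature(d$X, d$y, lmax * 1.01), "smaller penalty")
})

test_that("an unpenalized fit matches the glm oracle", {
  d <- sim_design(2, n = 300, p = 5, n_info = 3, beta = 1)
  grid <- c(lambda_max(d$X, d$y) * 10^seq(0, -5, by = -0.5), 0)
  path <- lasso_path(d$X, d$y, lambdas = grid)
  cf <- coef(path, 0)
  oracle <- coef(glm(d$y ~ d$X, family = binomial))
  expect_lt(max(abs(cf - oracle)), 1e-4)
})

test_that("support size grows along falling penalties", {
  d <- sim_design(3)
  path <- lasso_path(d$X, d$y)
  nz <- vapply(path$lambdas, function(l) sum(coef(path, l)[-1] != 0),
               numeric(1))
  # the exact LASSO path lets variables leave the active set transiently,
  # so the support is monotone only as a trend: dips must stay tiny and
  # the rank correlation with the (descending) penalty index must be high
  expect_true(all(cummax(nz) - nz <= 3))
  expect_gt(cor(seq_along(nz), nz, method = "kendall"), 0.85)
  expect_equal(nz[1], 0)  # at lambda_max the model is null
  expect_gt(utils::tail(nz, 1), 10)
})

test_that("KKT conditions hold at the solution", {
  d <- sim_design(4, n = 150, p = 30)
  path <- lasso_path(d$X, d$y)
  lam <- path$lambdas[50]
  cf <- coef(path, lam)
  eta <- cf[1] + d$X %*% cf[-1]
  mu <- 1 / (1 + exp(-eta))
  grad <- crossprod(d$X, d$y - mu) / nrow(d$X)
  zero <- cf[-1] == 0
  expect_true(all(abs(grad[zero]) <= lam + 1e-5))
  if (any(!zero)) {
    expect_lt(max(abs(grad[!zero] - lam * sign(cf[-1][!zero]))), 1e-5)
  }
})

test_that("cross-validated selection is seeded and stratified", {
  d <- sim_design(5)
  a <- cv_select_lambda(d$X, d$y, k = 10, seed = 9)
  b <- cv_select_lambda(d$X, d$y, k = 10, seed = 9)
  expect_identical(a$lambda, b$lambda)
  expect_identical(a$cv, b$cv)
  folds <- boxsig:::stratified_folds(d$y, 10, 9)
  tab <- table(folds, d$y)
  expect_true(all(tab > 0))
  expect_error(boxsig:::stratified_folds(c(0, 1, 1, 1), 3, 1), "stratified")
})

test_that("pure noise selects a near-null model, signal survives", {
  nulls <- vapply(1:5, function(s) {
    d <- withr::with_seed(s, list(X = matrix(rnorm(150 * 40), 150, 40),
                                  y = rbinom(150, 1, 0.5)))
    colnames(d$X) <- paste0("n", 1:40)
    cv <- cv_select_lambda(d$X, d$y, k = 10, seed = s)
    cv$n_nonzero
  }, numeric(1))
  expect_lte(median(nulls), 2)
  d <- sim_design(6)
  cv <- cv_select_lambda(d$X, d$y, k = 10, seed = 1)
  expect_lt(cv$lambda, lambda_max(d$X, d$y))
  expect_gte(cv$n_nonzero, 1)
})

test_that("signatures rank a perfectly predictive column first", {
  withr::with_seed(7, {
    X <- matrix(rnorm(120 * 10), 120, 10)
    colnames(X) <- paste0("v", 1:10)
    y <- rep(c(0, 1), each = 60)
    X[, 4] <- y * 3 + rnorm(120, 0, 0.05)
  })
  cv <- cv_select_lambda(X, y, k = 10, seed = 2)
  sig <- select_signature(X, y, cv$lambda)
  expect_equal(sig$features$feature[1], "v4")
  td <- tidy(sig)
  expect_true(all(c("feature", "coefficient", "lambda") %in% names(td)))
})

test_that("three mask sources yield three tagged signatures", {
  d <- sim_design(8, n = 120, p = 20)
  sigs <- lapply(c("manual", "detector-box", "whole-image-fallback"),
                 function(src) {
    select_signature(d$X, d$y, lambda_max(d$X, d$y) * 0.05, mask_source = src)
  })
  expect_equal(vapply(sigs, function(s) s$mask_source, character(1)),
               c("manual", "detector-box", "whole-image-fallback"))
  tf <- tempfile(fileext = ".json")
  save_signature(sigs[[1]], tf)
  back <- jsonlite::read_json(tf, simplifyVector = TRUE)
  expect_equal(back$mask_source, "manual")
  expect_equal(nrow(back$features), nrow(sigs[[1]]$features))
})
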