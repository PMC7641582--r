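test_that("lag matrix layout is feature-major with zero fill", {
  x <- matrix(1:20, 10, 2)
  expect_equal(lag_matrix(x, 0L), x)

  lm <- lag_matrix(x, c(0L, 1L))
  expect_equal(ncol(lm), 4)
  expect_equal(lm[, 1], x[, 1])          # feature 1, lag 0
  expect_equal(lm[, 2], c(0, x[1:9, 1])) # feature 1, lag 1
  expect_equal(lm[, 3], x[, 2])          # feature 2, lag 0

  lm_neg <- lag_matrix(x, -1L)
  expect_equal(lm_neg[, 1], c(x[2:10, 1], 0))

  expect_error(lag_matrix(x, 0.5), "whole sample")
})

test_that("the default fit and predict windows give 33 and 21 lags at 80 Hz", {
  lsp <- lag_spec()
  expect_length(lsp$fit_lags, 33)
  expect_length(lsp$predict_lags, 21)
  expect_length(default_lambda_grid(), 17)
  expect_equal(range(default_lambda_grid()), c(1, 2^20))
})

test_that("ridge matches OLS at lambda 0 and the normal-equations oracle", {
  set.seed(42)
  X <- matrix(rnorm(80), 20, 4)
  y <- X %*% c(1, -2, 0.5, 3) + rnorm(20, 0, 0.1)
  f0 <- fit_ridge(X, y, 0)
  ols <- lm.fit(cbind(1, X), y)
  expect_equal(unname(f0$coef[, 1]), unname(ols$coefficients[-1]),
               tolerance = 1e-8)

  f <- fit_ridge(X, y, 3.7, intercept = FALSE)
  oracle <- solve(crossprod(X) + 3.7 * diag(4), crossprod(X, y))
  expect_lt(max(abs(f$coef - oracle)), 1e-10)

  expect_error(fit_ridge(X, y, -1), "non-negative")
})

test_that("weight norm shrinks monotonically along the lambda path", {
  set.seed(7)
  X <- matrix(rnorm(200), 40, 5)
  y <- X %*% rnorm(5) + rnorm(40)
  norms <- sapply(default_lambda_grid(), function(l)
    sum(fit_ridge(X, y, l)$coef^2))
  expect_true(all(diff(norms) < 0))
})

test_that("banded ridge reduces to plain ridge and silences an infinite band", {
  set.seed(3)
  X <- matrix(rnorm(150), 30, 5)
  y <- X[, 1:3] %*% c(1, 2, -1) + rnorm(30, 0, 0.2)
  bands <- list(a = 1:3, b = 4:5)

  same <- fit_banded(X, y, bands, c(5, 5))
  plain <- fit_ridge(X, y, 5)
  expect_equal(same$coef, plain$coef, tolerance = 1e-12)

  expect_equal(nrow(banded_grid(2)), 289)

  huge <- fit_banded(X, y, bands, c(5, 1e12))
  expect_lt(max(abs(huge$coef[4:5, ])), 1e-8)
  solo <- fit_ridge(X[, 1:3], y, 5)
  expect_equal(huge$coef[1:3, , drop = FALSE], solo$coef, tolerance = 1e-4)

  expect_error(fit_banded(X, y, list(a = 1:2, b = 4:5), c(1, 1)), "partition")
})

test_that("noiseless simulated data are fit nearly perfectly by LOTO encoding", {
  # trials long enough that each per-trial fit is full rank
  sim <- sim_encoding_dataset(n_per_cell = 2, noise_sd = 0, n_samples = 120)
  fit <- trf_loto(sim$feats, neural_trial_list(sim$neural, zscore = FALSE),
                  sim$lspec, lambda_grid = c(1e-6, 1e4))
  expect_gt(mean(fit$accuracy[, , 1]), 0.99)
  # heavy regularization must do worse
  expect_lt(mean(fit$accuracy[, , 2]), mean(fit$accuracy[, , 1]))
})

test_that("pure-noise responses give near-zero accuracies", {
  sim <- sim_encoding_dataset(n_per_cell = 2, noise_sd = 0)
  n_tr <- length(sim$feats)
  set.seed(5)
  y_list <- lapply(seq_len(n_tr), function(i)
    matrix(rnorm(nrow(sim$feats[[1]]$values) * 4), ncol = 4))
  fit <- trf_loto(sim$feats, y_list, sim$lspec, lambda_grid = 10)
  n_eff <- n_tr * nrow(y_list[[1]])
  expect_lt(abs(mean(fit$accuracy)), 2 / sqrt(n_eff) * 4)
})

test_that("prediction is invariant to the ordering of training trials", {
  sim <- sim_encoding_dataset(n_per_cell = 2, noise_sd = 0.5)
  y <- neural_trial_list(sim$neural, zscore = FALSE)
  fit1 <- trf_loto(sim$feats, y, sim$lspec, lambda_grid = 1)
  perm <- c(2:12, 1)
  fit2 <- trf_loto(sim$feats[perm], y[perm], sim$lspec, lambda_grid = 1)
  expect_equal(fit1$accuracy[1, , 1], fit2$accuracy[12, , 1], tolerance = 1e-9)
})

test_that("a one-sample input shift moves TRF weight mass by one lag", {
  sim <- sim_encoding_dataset(n_per_cell = 1, n_features = 2, noise_sd = 0,
                              kernel_type = "impulse")
  y <- neural_trial_list(sim$neural, zscore = FALSE)
  fit <- trf_loto(sim$feats, y, sim$lspec, lambda_grid = 1e-6)
  m <- trf_model(fit, 1e-6)
  peak0 <- trf_peak_latency(m)

  shifted <- lapply(sim$feats, function(f) {
    f$values <- rbind(0, f$values[-nrow(f$values), , drop = FALSE])
    f
  })
  fit2 <- trf_loto(shifted, y, sim$lspec, lambda_grid = 1e-6)
  peak1 <- trf_peak_latency(trf_model(fit2, 1e-6))
  expect_equal(peak1 - peak0, -12.5)
})

test_that("lambda selection takes the modal argmax with ties toward smaller", {
  mk <- function(participant, condition, best, grid = 2^(2:6)) {
    tibble::tibble(participant = participant, condition = condition,
                   lambda = grid,
                   accuracy = -abs(log2(grid) - log2(best)))
  }
  all16 <- dplyr::bind_rows(lapply(1:6, function(p) mk(p, "c1", 2^4)))
  expect_equal(select_lambda(all16), 2^4)

  split <- dplyr::bind_rows(
    lapply(1:4, function(p) mk(p, "c1", 2^3)),
    lapply(5:6, function(p) mk(p, "c1", 2^5)))
  expect_equal(select_lambda(split), 2^3)

  tie <- dplyr::bind_rows(
    lapply(1:3, function(p) mk(p, "c1", 2^3)),
    lapply(4:6, function(p) mk(p, "c1", 2^5)))
  expect_equal(select_lambda(tie), 2^3)

  expect_error(select_lambda(tibble::tibble(participant = integer(),
                                            condition = character(),
                                            lambda = numeric(),
                                            accuracy = numeric())), "empty")
})

test_that("mean accuracy is unimodal along the lambda path on noisy data", {
  sim <- sim_encoding_dataset(n_per_cell = 2, noise_sd = 2, seed = 4)
  grid <- 2^seq(0, 20, length.out = 9)
  fit <- trf_loto(sim$feats, neural_trial_list(sim$neural), sim$lspec,
                  lambda_grid = grid)
  path <- apply(fit$accuracy, 3, mean)
  k <- which.max(path)
  # non-decreasing to the peak, non-increasing after (tolerance for noise)
  if (k > 1) expect_true(all(diff(path[1:k]) > -0.002))
  if (k < length(path)) expect_true(all(diff(path[k:length(path)]) < 0.002))
})
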