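test_that("PCA reduction orders variance and respects low-rank structure", {
  sim <- sim_encoding_dataset(n_per_cell = 2, n_features = 3, n_sensors = 10,
                              noise_sd = 0)
  expect_warning(red <- decode_setup(sim$neural, n_components = 50),
                 "fewer sensors")
  expect_true(all(diff(red$sdev) <= 1e-12))

  # noiseless separable data have sensor rank = number of features
  red2 <- decode_setup(sim$neural, n_components = 10, zscore = FALSE)
  expect_lt(red2$sdev[4] / red2$sdev[1], 1e-8)

  # back-projection error bounded by the discarded variance
  y <- stmtrf:::neural_trial_list(sim$neural, zscore = FALSE)
  stacked <- do.call(rbind, y)
  centred <- sweep(stacked, 2, red2$center)
  recon <- centred %*% red2$rotation[, 1:3] %*% t(red2$rotation[, 1:3])
  discarded <- sum(centred^2) - sum((centred %*% red2$rotation[, 1:3])^2)
  expect_lt(sum((centred - recon)^2), discarded + 1e-6)
})

test_that("noiseless decoding recovers the generating modulation series", {
  lsp <- lag_spec()
  sim <- sim_encoding_dataset(n_per_cell = 2, n_features = 4, n_sensors = 12,
                              n_samples = 150, noise_sd = 0, lspec = lsp,
                              kernel_type = "impulse", peaks_ms = 87.5)
  red <- decode_setup(sim$neural, n_components = 4, zscore = FALSE)
  fit <- decode(red, sim$feats, lsp, lambda_grid = 0.01)
  expect_equal(dim(fit$accuracy)[2], 4)
  expect_gt(mean(fit$accuracy), 0.99)
})

test_that("modulation cells absent from the ground truth decode at chance", {
  lsp <- lag_spec()
  sim <- sim_encoding_dataset(n_per_cell = 2, n_features = 4, n_sensors = 12,
                              n_samples = 150, noise_sd = 0, lspec = lsp,
                              kernel_type = "impulse", peaks_ms = 87.5)
  # append a 5th feature stream the neural data never saw
  feats5 <- lapply(seq_along(sim$feats), function(i) {
    extra <- synth_feature_stream(150, 1, seed = 9000 + i)
    f <- sim$feats[[i]]
    f$values <- cbind(f$values, prepare(extra, lsp$fit_ms,
                                        zscore = FALSE)$values)
    f
  })
  red <- decode_setup(sim$neural, n_components = 4, zscore = FALSE)
  fit <- decode(red, feats5, lsp, lambda_grid = 0.01)
  acc <- colMeans(fit$accuracy[, , 1])
  expect_true(all(acc[1:4] > 0.95))
  expect_lt(abs(acc[5]), 0.25)
  expect_lt(abs(acc[5]), min(acc[1:4]) / 3)
})

test_that("single-lag decoding resolves the latency of the ground truth", {
  lsp <- lag_spec()
  sim <- sim_encoding_dataset(n_per_cell = 2, n_features = 3, n_sensors = 10,
                              n_samples = 120, noise_sd = 0, lspec = lsp,
                              kernel_type = "impulse", peaks_ms = 50)
  red <- decode_setup(sim$neural, n_components = 3, zscore = FALSE)
  tbl <- single_lag_decode(red, sim$feats, lag_range_ms = c(-50, 250),
                           lambda_grid = c(0.01, 1))
  expect_equal(length(unique(tbl$lag_ms)), 25)
  curve <- tapply(tbl$r, tbl$lag_ms, mean)
  expect_equal(as.numeric(names(curve)[which.max(curve)]), 50)
})

test_that("single-lag decoding of unrelated neural data is flat near zero", {
  lsp <- lag_spec()
  sim <- sim_encoding_dataset(n_per_cell = 1, n_features = 3, n_sensors = 8,
                              n_samples = 80, noise_sd = 0, lspec = lsp)
  set.seed(11)
  noise <- sim$neural
  noise$data[] <- rnorm(length(noise$data))
  red <- decode_setup(noise, n_components = 6)
  tbl <- single_lag_decode(red, sim$feats, lag_range_ms = c(-50, 250),
                           lambda_grid = 10)
  curve <- tapply(tbl$r, tbl$lag_ms, mean)
  expect_lt(max(abs(curve)), 0.2)
})
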