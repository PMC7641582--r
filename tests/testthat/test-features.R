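test_that("envelope feature equals the column sum of the spectrogram", {
  w <- fixture_word()
  env <- envelope_feature(w)
  sg <- spectrogram_feature(w)
  expect_equal(ncol(env$values), 1)
  expect_equal(ncol(sg$values), 24)
  expect_equal(as.vector(env$values), rowSums(sg$values), tolerance = 1e-12)
})

test_that("silence produces a flagged all-zero envelope", {
  s <- audio_waveform(rep(0, 22050), 44100)
  env <- envelope_feature(s)
  expect_true(all(env$values == 0))
  expect_true(attr(env, "silent"))
})

test_that("narrowband tones concentrate energy in the matching channel", {
  bank <- greenwood_bank(24)
  for (k in c(6, 14, 20)) {
    t <- seq(0, 0.4, by = 1 / 44100)
    tone <- audio_waveform(sin(2 * pi * bank$centers[k] * t), 44100)
    sg <- spectrogram_feature(tone, bank = bank)
    expect_equal(unname(which.max(colMeans(sg$values))), k)
  }
})

test_that("compression exponent 1 is the identity", {
  w <- fixture_word()
  a <- spectrogram_feature(w)
  b <- spectrogram_feature(w, compress_exponent = 1)
  expect_equal(a$values, b$values)
  c03 <- spectrogram_feature(w, compress_exponent = 0.3)
  expect_equal(c03$values, a$values^0.3, tolerance = 1e-12)
})

test_that("spectral derivative rectifies onsets and zeroes decays", {
  n <- 40
  const <- matrix(1, n, 2)
  falling <- matrix(rep(seq(1, 0, length.out = n), 2), n)
  step <- matrix(0, n, 1); step[20:n, 1] <- 1
  mk <- function(v) {
    fs <- feature_space(v, 80, "spectrogram")
    spectral_derivative(fs)$values
  }
  expect_true(all(mk(const) == 0))
  expect_true(all(mk(falling) == 0))
  d <- mk(step)
  expect_equal(which(d > 0), 20)

  wrong <- feature_space(const, 80, "stm")
  expect_error(spectral_derivative(wrong), "spectrogram")
})

test_that("feature-space combination concatenates columns and records bands", {
  w <- fixture_word()
  sg <- spectrogram_feature(w)
  der <- spectral_derivative(sg)
  ph <- phonetic_feature(w$segments, duration_ms(w))
  ph$values <- ph$values[seq_len(nrow(sg$values)), , drop = FALSE]

  both <- combine_spaces(sg, ph)
  expect_equal(ncol(both$values), 37)
  expect_named(both$bands, c("spectrogram", "phonetic"))
  expect_equal(both$bands$phonetic, 25:37)

  sgd <- combine_spaces(sg, der)
  expect_equal(ncol(sgd$values), 48)

  expect_identical(combine_spaces(sg)$values, sg$values)
  bad <- ph; bad$rate <- 100
  expect_error(combine_spaces(sg, bad), "rate mismatch")
})

test_that("prepare pads by the extreme lags and z-scores acoustic columns", {
  v <- matrix(rnorm(200), 100, 2)
  fs <- feature_space(v, 80, "spectrogram")
  prepped <- prepare(fs, c(-100, 300))
  expect_equal(nrow(prepped$values), 100 + 8 + 24)
  expect_true(all(prepped$values[1:8, ] == 0))
  expect_true(all(prepped$values[109:132, ] == 0))
  core <- prepped$values[9:108, ]
  expect_lt(max(abs(colMeans(core))), 1e-9)
  expect_lt(max(abs(apply(core, 2, sd) - 1)), 1e-6)

  # constant columns are flagged and left at zero
  fs2 <- feature_space(cbind(v[, 1], 3), 80, "spectrogram")
  p2 <- prepare(fs2, c(0, 0))
  expect_true(all(p2$values[, 2] == 0))

  # phonetic (categorical) spaces are not z-scored
  ph <- feature_space(matrix(rep(c(0, 1), each = 50), 100), 80, "phonetic",
                      acoustic = FALSE)
  p3 <- prepare(ph, c(-100, 300))
  expect_setequal(unique(as.vector(p3$values)), c(0, 1))

  # in combined spaces only acoustic blocks are z-scored
  both <- combine_spaces(fs, feature_space(matrix(rep(c(0, 1), 50), 100), 80,
                                           "phonetic", acoustic = FALSE))
  p4 <- prepare(both, c(0, 0))
  expect_lt(max(abs(colMeans(p4$values[, 1:2]))), 1e-9)
  expect_setequal(unique(as.vector(p4$values[, 3])), c(0, 1))
})

test_that("feature spaces from clear audio do not depend on the detail condition", {
  # the degraded versions differ, but features are built from clear audio
  w <- fixture_word()
  f1 <- spectrogram_feature(w)
  f2 <- spectrogram_feature(w)
  expect_identical(f1$values, f2$values)
})
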