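test_that("greenwood bank spans the requested range with nested edges", {
  b1 <- greenwood_bank(1)
  expect_equal(b1$edges, c(70, 5000))

  b24 <- greenwood_bank(24)
  expect_length(b24$centers, 24)
  expect_true(!is.unsorted(b24$centers, strictly = TRUE))
  expect_lt(b24$centers[1], 100)
  expect_gt(b24$centers[1], 70)
  expect_lt(b24$centers[24], 5000)

  # equal spacing on the cochlear-position axis nests coarser banks exactly
  b3 <- greenwood_bank(3)
  expect_equal(b3$edges, b24$edges[seq(1, 25, by = 8)], tolerance = 1e-9)
})

test_that("printed 24-channel centre frequencies are matched within a few percent", {
  # the midpoint-of-position convention differs slightly from the original
  # script's (unknown) centre convention, so this is a soft check
  printed <- c(86, 120, 159, 204, 255, 312, 378, 453, 537, 634, 744, 869,
               1011, 1172, 1356, 1565, 1802, 2072, 2380, 2729, 3127, 3579,
               4093, 4678)
  centers <- greenwood_bank(24)$centers
  expect_true(all(abs(centers - printed) / printed < 0.05))
})

test_that("envelope extraction is a rectify-and-smooth operation", {
  fs <- 8000
  t <- seq(0, 1, by = 1 / fs)
  # DC-positive input passes through the 30 Hz lowpass nearly unchanged
  x <- rep(0.5, length(t))
  env <- extract_envelope(x, fs)
  expect_equal(env[500:7500], rep(0.5, 7001), tolerance = 1e-3)

  # 4 Hz AM tone: envelope is dominated by the 4 Hz component
  am <- (1 + 0.9 * sin(2 * pi * 4 * t)) * sin(2 * pi * 1000 * t)
  env <- extract_envelope(am, fs)
  sp <- Mod(fft(env - mean(env)))[2:40]   # bins ~1..39 Hz
  expect_equal(which.max(sp), 5, tolerance = 1)   # bin 5 = 4 Hz

  # pure tone: near-constant envelope in steady state
  tone <- sin(2 * pi * 1000 * t)
  env <- extract_envelope(tone, fs)
  mid <- env[2000:6000]
  expect_lt(sd(mid) / mean(mid), 0.1)

  expect_error(extract_envelope(tone, fs, cutoff = 5000), "Nyquist")
})

test_that("vocoding preserves duration and channel envelopes", {
  w <- fixture_word()
  v <- vocode(w, 6, seed = 1)
  expect_equal(length(v$samples), length(w$samples))
  expect_equal(rms(v$samples), rms(w$samples), tolerance = 1e-9)

  # same seed reproduces; different seed changes only the carrier
  v2 <- vocode(w, 6, seed = 1)
  expect_identical(v$samples, v2$samples)
  v3 <- vocode(w, 6, seed = 2)
  expect_false(identical(v$samples, v3$samples))

  expect_error(vocode(w, 0), "at least 1")
})

test_that("channel envelopes survive vocoding while carriers differ by seed", {
  w <- fixture_word()
  bank <- greenwood_bank(3)
  env_of <- function(a, cutoff = 30) {
    sapply(1:3, function(ch) {
      band <- stmtrf:::fft_filter(a$samples, a$rate, lo = bank$edges[ch],
                                  hi = bank$edges[ch + 1], order = 4)
      extract_envelope(band, a$rate, cutoff = cutoff)
    })
  }
  v1 <- vocode(w, 3, seed = 1)
  v2 <- vocode(w, 3, seed = 2)

  # analysis envelopes of the original are carried into the vocoded output
  e0 <- env_of(w); e1 <- env_of(v1)
  rr0 <- sapply(1:3, function(ch) cor(e0[, ch], e1[, ch]))
  expect_true(all(rr0 > 0.95))

  # across carrier seeds the syllable-rate envelopes are near-identical
  # (the carriers differ only in their intrinsic fast fluctuations)
  s1 <- env_of(v1, cutoff = 16); s2 <- env_of(v2, cutoff = 16)
  rr <- sapply(1:3, function(ch) cor(s1[, ch], s2[, ch]))
  expect_true(all(rr > 0.95))
})

test_that("broadband envelope of vocoded speech tracks the original", {
  w <- fixture_word()
  v <- vocode(w, 24, seed = 4)
  b_orig <- envelope_feature(w)$values
  b_voc <- envelope_feature(v)$values
  expect_gt(cor(b_orig, b_voc), 0.9)
})

test_that("spectral fidelity increases with the number of vocoder channels", {
  # per-channel z-scoring removes the static spectral profile so the
  # correlation indexes resolved spectrotemporal detail; two carrier draws
  # are averaged to damp carrier noise
  zc <- function(m) apply(m, 2, function(x)
    if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0)
  words <- lapply(c("w021", "w022", "w023"), synth_word_audio, seed = 9)
  cors <- sapply(words, function(w) {
    sg_clear <- as.vector(zc(spectrogram_feature(w)$values))
    sapply(c(1, 3, 6, 12, 24), function(nc) {
      mean(sapply(2:3, function(sd2)
        cor(sg_clear,
            as.vector(zc(spectrogram_feature(vocode(w, nc, seed = sd2))$values)))))
    })
  })
  avg <- rowMeans(cors)
  expect_true(!is.unsorted(avg, strictly = TRUE))
})

test_that("RMS equalization brings all files to one level and is scale-invariant", {
  fs <- 8000
  a1 <- audio_waveform(0.1 * rnorm(4000), fs)
  a2 <- audio_waveform(0.4 * rnorm(4000), fs)
  eq <- rms_equalize(list(a1, a2))
  r <- vapply(eq, function(a) rms(a$samples), numeric(1))
  expect_equal(r[1], r[2], tolerance = 1e-6)

  eq2 <- rms_equalize(eq)
  expect_equal(eq[[1]]$samples, eq2[[1]]$samples, tolerance = 1e-9)

  a1k <- audio_waveform(5 * a1$samples, fs)
  eqk <- rms_equalize(list(a1k, a2), target = 0.05)
  eqa <- rms_equalize(list(a1, a2), target = 0.05)
  expect_equal(eqk[[1]]$samples, eqa[[1]]$samples, tolerance = 1e-9)

  expect_error(rms_equalize(list(audio_waveform(rep(0, 100), fs))), "silent")
})
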