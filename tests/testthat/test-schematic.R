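test_that("word patterns rasterize to binary matrices", {
  p <- word_pattern("clay")
  expect_true(all(p %in% c(0, 1)))
  expect_equal(nrow(p), 21)   # 7 glyph rows at scale 3
  m <- matrix(c(1, 0, 0, 1), 2)
  expect_identical(word_pattern(m), m)
  expect_error(word_pattern("zzz"), "glyph")
})

test_that("degradation levels behave as identity / 4-pixel / 8-pixel means", {
  p <- word_pattern("clay")
  expect_identical(degrade(p, "high"), p)

  const <- matrix(0.7, 10, 12)
  expect_equal(degrade(const, "low"), const, tolerance = 1e-12)
  expect_equal(degrade(const, "medium"), const, tolerance = 1e-12)

  # mean filtering preserves the total sum
  expect_equal(sum(degrade(p, "low")), sum(p), tolerance = 1e-9)
  expect_equal(sum(degrade(p, "medium")), sum(p), tolerance = 1e-9)
  # and reduces contrast
  expect_lt(sd(degrade(p, "low")), sd(p))
  expect_lt(sd(degrade(p, "medium")), sd(p))
  expect_lt(sd(degrade(p, "low")), sd(degrade(p, "medium")))
})

test_that("noise-and-normalize sums to one with calibrated noise SD", {
  p <- word_pattern("fast")
  out <- noise_and_normalize(p, seed = 4)
  expect_equal(sum(out), 1, tolerance = 1e-9)
  expect_identical(noise_and_normalize(p, seed = 4), out)

  # Monte-Carlo check of the uniform noise SD
  half <- 0.5 * sqrt(3)
  with(list(), {
    set.seed(8)
    draws <- runif(1e5, -half, half)
    expect_equal(sd(draws), 0.5, tolerance = 0.01)
    expect_equal(mean(draws), 0, tolerance = 0.01)
  })
})

test_that("sharpened and prediction-error representations obey their algebra", {
  p <- word_pattern("clay")
  inp <- noise_and_normalize(p, seed = 1)
  pred <- noise_and_normalize(p, seed = 2)

  s <- sharpened(inp, pred)
  expect_equal(sum(s), 1, tolerance = 1e-12)
  u <- matrix(1 / length(inp), nrow(inp), ncol(inp))
  expect_equal(sharpened(inp, u), inp / sum(inp), tolerance = 1e-12)

  # multiplying two aligned positive patterns increases contrast
  pos <- abs(inp) + 0.01
  pos <- pos / sum(pos)
  shp <- sharpened(pos, pos)
  norm_entropy <- function(m) { q <- m / sum(m); -sum(q * log(q)) }
  expect_lt(norm_entropy(shp), norm_entropy(pos))

  pe <- prediction_error(inp, pred)
  expect_equal(pe, inp - pred)
  expect_equal(prediction_error(inp, inp), matrix(0, nrow(inp), ncol(inp)),
               ignore_attr = TRUE)
  expect_equal(prediction_error(inp, 0 * inp), inp)
  expect_equal(prediction_error(2 * inp, pred),
               2 * prediction_error(inp, pred) + pred)

  expect_equal(pe_magnitude(pe), pe_magnitude(-pe))
  expect_equal(pe_magnitude(0 * pe), 0)
  expect_lte(pe_magnitude(pe), pe_magnitude(inp) + pe_magnitude(pred))
})

test_that("fidelity is a scale- and shift-invariant R squared", {
  p <- word_pattern("clay")
  expect_equal(fidelity(p, p), 1)
  expect_equal(fidelity(3 * p + 2, p), 1)
  set.seed(31)
  rs <- replicate(50, fidelity(matrix(rnorm(length(p)), nrow(p)), p))
  expect_lt(mean(rs), 0.05)
})

test_that("the schematic grid reproduces the two coding-scheme signatures", {
  g <- run_schematic_grid(n_reps = 300, seed = 2)
  s <- aggregate(cbind(fidelity, pe_abs) ~ prior + level + scheme, g, mean,
                 na.action = stats::na.pass)
  pick <- function(scheme, prior) {
    x <- s[s$scheme == scheme & s$prior == prior, ]
    x[order(x$level), ]
  }
  pe_mm <- pick("prediction_error", "Mismatch")
  pe_ma <- pick("prediction_error", "Match")
  # prediction error: fidelity rises with detail on mismatch, falls on match
  expect_true(all(diff(pe_mm$fidelity) > 0))
  expect_true(all(diff(pe_ma$fidelity) < 0))

  # sharpened: fidelity rises with detail under both priors
  sh_mm <- pick("sharpened", "Mismatch")
  sh_ma <- pick("sharpened", "Match")
  expect_true(all(diff(sh_mm$fidelity) > 0))
  expect_true(all(diff(sh_ma$fidelity) > 0))

  # total |PE| smallest when expectations match, at every level
  expect_true(all(pe_ma$pe_abs < pe_mm$pe_abs))

  expect_true(all(g$fidelity >= 0 & g$fidelity <= 1))
  expect_true(all(g$pe_abs[!is.na(g$pe_abs)] >= 0))
})
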