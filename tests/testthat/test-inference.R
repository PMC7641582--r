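test_that("top-sensor selection is per hemisphere and per participant", {
  acc <- expand.grid(participant = 1:2, sensor = sprintf("s%02d", 1:10),
                     hemisphere = rep(c("L", "R"), each = 1),
                     stringsAsFactors = FALSE)
  acc$hemisphere <- ifelse(match(acc$sensor, sprintf("s%02d", 1:10)) <= 5,
                           "L", "R")
  # participant 1 peaks on s01/s06, participant 2 on s05/s10
  acc$accuracy <- ifelse(acc$participant == 1,
                         ifelse(acc$sensor %in% c("s01", "s06"), 1, 0),
                         ifelse(acc$sensor %in% c("s05", "s10"), 1, 0))
  sel <- select_top_sensors(acc, k = 1)
  expect_equal(nrow(sel), 4)
  expect_setequal(sel$sensor[sel$participant == 1], c("s01", "s06"))
  expect_setequal(sel$sensor[sel$participant == 2], c("s05", "s10"))

  # k = all sensors reduces to the plain per-hemisphere average
  expect_warning(sel_all <- select_top_sensors(acc, k = 20), "only")
  expect_equal(nrow(sel_all), 20)
})

test_that("repeated-measures ANOVA matches aov on a random dataset", {
  set.seed(21)
  d <- expand.grid(participant = factor(1:21), prior = c("Match", "Mismatch"),
                   detail = c(3, 6, 12))
  d$value <- rnorm(nrow(d)) + as.numeric(d$detail) / 20
  eff <- rm_anova_2x3(d)

  expect_equal(eff$df1[eff$effect == "detail"], 2)
  expect_equal(eff$df2[eff$effect == "detail"], 40)
  expect_equal(eff$df2[eff$effect == "prior:detail"], 40)

  a <- summary(stats::aov(value ~ prior * factor(detail) +
                            Error(participant / (prior * factor(detail))),
                          data = d))
  f_prior <- a[["Error: participant:prior"]][[1]]["prior", "F value"]
  f_detail <- a[["Error: participant:factor(detail)"]][[1]][1, "F value"]
  f_int <- a[["Error: participant:prior:factor(detail)"]][[1]][1, "F value"]
  expect_equal(eff$F[eff$effect == "prior"], f_prior, tolerance = 1e-8)
  expect_equal(eff$F[eff$effect == "detail"], f_detail, tolerance = 1e-8)
  expect_equal(eff$F[eff$effect == "prior:detail"], f_int, tolerance = 1e-8)

  expect_error(rm_anova_2x3(d[-1, ]), "incomplete")
})

test_that("RM-ANOVA type-I error rate is calibrated at the 5% level", {
  set.seed(99)
  n_sims <- 1200
  hits <- logical(n_sims)
  d0 <- expand.grid(participant = 1:10, prior = c("Match", "Mismatch"),
                    detail = c(3, 6, 12))
  for (i in seq_len(n_sims)) {
    d0$value <- rnorm(nrow(d0))
    eff <- rm_anova_2x3(d0)
    hits[i] <- eff$p[eff$effect == "prior:detail"] < 0.05
  }
  expect_gte(mean(hits), 0.03)
  expect_lte(mean(hits), 0.07)
})

test_that("paired t reports dz and handles degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  res <- paired_t(x, x + rnorm(5, 0, 1e-8))
  expect_equal(res$df, 4)
  expect_lt(abs(res$t), 10)   # essentially noise

  set.seed(2)
  a <- rnorm(21); b <- a + 0.5 + rnorm(21, 0, 0.3)
  res2 <- paired_t(b, a)
  expect_equal(res2$df, 20)
  expect_equal(res2$dz, mean(b - a) / sd(b - a), tolerance = 1e-12)

  expect_error(paired_t(x, x + 1), "zero variance")
})

test_that("within-trial shuffling preserves values and destroys structure", {
  v <- matrix(sin(2 * pi * 3 * (1:200) / 80), 200, 2)
  fs <- feature_space(v, 80, "stm")
  sh <- shuffle_within_trial(fs, seed = 5)
  expect_setequal(as.vector(sh$values), as.vector(v))
  expect_false(identical(sh$values, v))
  # same seed, same permutation
  expect_identical(shuffle_within_trial(fs, seed = 5)$values, sh$values)
  # autocorrelation collapses
  ac <- acf(sh$values[, 1], lag.max = 5, plot = FALSE)$acf[-1]
  expect_true(all(abs(ac) < 0.15))
})

test_that("across-trial shuffling permutes whole words within condition", {
  design <- make_design(3, seed = 8)
  feats <- lapply(seq_len(nrow(design)), function(i)
    feature_space(matrix(i, 10, 2), 80, "stm"))
  sh <- shuffle_across_trials(feats, design, seed = 2)
  ids <- vapply(sh, function(f) f$values[1, 1], numeric(1))
  expect_setequal(ids, seq_len(18))
  expect_false(identical(ids, as.numeric(1:18)))
  # permutation stays within condition cells
  cells <- paste(design$prior, design$detail)
  expect_equal(cells[ids], cells)
  # identity excluded over many seeds (when alternatives exist)
  for (s in 1:10) {
    ids_s <- vapply(shuffle_across_trials(feats, design, seed = s),
                    function(f) f$values[1, 1], numeric(1))
    expect_false(identical(ids_s, as.numeric(1:18)))
  }
})

test_that("permutation nulls are centred near zero and rank bounds hold", {
  lsp <- lag_spec(c(0, 250), c(0, 250))
  sim <- sim_encoding_dataset(n_per_cell = 2, n_features = 3, n_sensors = 6,
                              n_samples = 50, noise_sd = 1, lspec = lsp)
  nd <- null_distribution(sim$feats, sim$neural, sim$design, lambda = 32,
                          lspec = lsp, scheme = "within_trial", n_perm = 30,
                          seed = 3)
  expect_equal(nrow(nd), 30 * 6)
  expect_lt(abs(mean(nd$accuracy)), 0.05)

  # observed real-signal accuracy beats every null draw: p <= 1/(n+1)
  fit <- trf_loto(sim$feats, stmtrf:::neural_trial_list(sim$neural), lsp,
                  lambda_grid = 32)
  obs <- mean(fit$accuracy)
  expect_true(obs > max(nd$accuracy))
  p_perm <- (1 + sum(nd$accuracy >= obs)) / (nrow(nd) + 1)
  expect_lte(p_perm, 1 / 101)
})

test_that("z-scoring against the null is exact for constructed cases", {
  null <- tibble::tibble(permutation = rep(1:50, 2),
                         condition = rep(c("a", "b"), each = 50),
                         accuracy = c(rnorm(50, 0, 0.1), rnorm(50, 0.2, 0.2)))
  mu <- tapply(null$accuracy, null$condition, mean)
  sdv <- tapply(null$accuracy, null$condition, sd)
  obs <- tibble::tibble(condition = c("a", "b"),
                        accuracy = c(mu[["a"]], mu[["b"]] + 2 * sdv[["b"]]))
  z <- zscore_vs_null(obs, null)
  expect_equal(z$z, c(0, 2), tolerance = 1e-12)

  degenerate <- tibble::tibble(permutation = 1:10, condition = "a",
                               accuracy = rep(0.3, 10))
  expect_error(zscore_vs_null(obs[1, ], degenerate), "zero standard deviation")
})

test_that("Benjamini-Hochberg control behaves at the boundaries", {
  all_small <- fdr_bh(rep(0.001, 25))
  expect_true(all(all_small$reject))

  one_mid <- fdr_bh(c(0.04, rep(1, 24)))
  expect_false(one_mid$reject[1])   # BH threshold for rank 1 of 25 is 0.002
})

test_that("the interaction contrast isolates the crossover and is antisymmetric", {
  cells <- expand.grid(participant = 1:8, prior = c("Match", "Mismatch"),
                       detail = c(3, 12), unit = c("u1", "u2"),
                       stringsAsFactors = FALSE)
  # u1 carries a crossover; u2 carries nothing
  base <- with(cells, ifelse(unit == "u1" & prior == "Mismatch" & detail == 12, 0.4,
               ifelse(unit == "u1" & prior == "Match" & detail == 12, -0.4, 0)))
  set.seed(13)
  cells$value <- base + rnorm(nrow(cells), 0, 0.05)
  res <- interaction_contrast(cells)
  expect_true(res$significant[res$unit == "u1"])
  expect_false(res$significant[res$unit == "u2"])
  expect_gt(res$contrast[res$unit == "u1"], 0.5)

  flipped <- cells
  flipped$prior <- ifelse(cells$prior == "Match", "Mismatch", "Match")
  res_f <- interaction_contrast(flipped)
  expect_equal(res_f$contrast, -res$contrast, tolerance = 1e-12)

  zero <- cells; zero$value <- 1
  res_0 <- interaction_contrast(zero)
  expect_true(all(res_0$contrast == 0))
})
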