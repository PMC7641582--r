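## Canned multi-participant simulation of the crossover experiment: the
## generator's condition gains implement the detail-by-prior interaction
## (rising encoding gain with sensory detail under Mismatch, falling under
## Match), and the full encode -> accuracy -> lambda-mode -> RM-ANOVA chain
## is run on every simulated dataset.

#' Default crossover condition gains
#'
#' Encoding gain rising with sensory detail under Mismatch (0.5/1/1.5 for
#' 3/6/12 channels) and falling under Match (1.5/1/0.5) -- the simulation's
#' stand-in for prediction-error coding.
#' @return named numeric vector over the 6 design cells.
#' @export
crossover_gains <- function() {
  c("Mismatch:3" = 0.5, "Mismatch:6" = 1, "Mismatch:12" = 1.5,
    "Match:3" = 1.5, "Match:6" = 1, "Match:12" = 0.5)
}

#' Calibration of the permutation-null z-scores under a true null
#'
#' Generates datasets in which the sensor responses are driven by feature
#' streams independent of the analysed features (so no true stimulus-response
#' relation exists), builds the within-trial-shuffle null for each dataset at
#' a fixed lambda, and z-scores the observed per-condition accuracies against
#' it. Under the null these z-scores should be centred on zero.
#'
#' @param n_datasets independent true-null datasets (default 100).
#' @param n_perm permutations per null distribution (default 40).
#' @param n_per_cell trials per design cell (default 3).
#' @param n_features,n_sensors,n_samples simulation sizes.
#' @param lambda fixed ridge penalty (default 32).
#' @param seed integer seed.
#' @return tibble with `dataset`, `condition`, `z`.
#' @export
simulate_null_calibration <- function(n_datasets = 100, n_perm = 40,
                                      n_per_cell = 3, n_features = 3,
                                      n_sensors = 8, n_samples = 50,
                                      lambda = 32, seed = 1) {
  lsp <- lag_spec(c(0, 250), c(0, 250))
  out <- vector("list", n_datasets)
  for (ds in seq_len(n_datasets)) {
    ds_seed <- hash_seed("nullcal", ds, seed = seed)
    design <- make_design(n_per_cell, seed = hash_seed("d", seed = ds_seed))
    truth <- make_ground_truth(n_features, n_sensors, lsp, noise_sd = 1,
                               seed = hash_seed("t", seed = ds_seed))
    feats <- lapply(seq_len(nrow(design)), function(i)
      prepare(synth_feature_stream(n_samples, n_features, bandwidth_hz = NULL,
                                   seed = hash_seed("f", i, seed = ds_seed)),
              lsp$fit_ms, zscore = FALSE))
    unrelated <- lapply(seq_len(nrow(design)), function(i)
      prepare(synth_feature_stream(n_samples, n_features, bandwidth_hz = NULL,
                                   seed = hash_seed("g", i, seed = ds_seed)),
              lsp$fit_ms, zscore = FALSE))
    neural <- synth_neural(unrelated, truth, design,
                           seed = hash_seed("n", seed = ds_seed))
    y <- neural_trial_list(neural)
    fit <- trf_loto(feats, y, lsp, lambda_grid = lambda)
    cells <- cell_key(design$prior, design$detail)
    per_trial <- rowMeans(fit$accuracy[, , 1])
    obs <- tibble::tibble(
      condition = names(tapply(per_trial, cells, mean)),
      accuracy = as.numeric(tapply(per_trial, cells, mean)))
    nd <- null_distribution(feats, neural, design, lambda, lsp,
                            scheme = "within_trial", n_perm = n_perm,
                            seed = ds_seed)
    z <- zscore_vs_null(obs, nd)
    out[[ds]] <- tibble::tibble(dataset = ds, condition = z$condition, z = z$z)
  }
  dplyr::bind_rows(out)
}

#' Simulate one multi-participant encoding experiment
#'
#' Generates a design, band-limited feature streams, and per-participant
#' sensor data with the given condition gains; fits leave-one-trial-out
#' encoding models over the lambda grid; selects lambda as the modal argmax
#' over (participant, condition) cells; and runs the 2 x 3 repeated-measures
#' ANOVA on the per-cell accuracies at the selected lambda.
#'
#' @param seed integer seed for the whole experiment.
#' @param n_participants simulated participants (default 8).
#' @param n_per_cell trials per design cell (default 4).
#' @param n_features stimulus features (default 4).
#' @param n_sensors sensors (default 10).
#' @param n_samples feature-stream samples per trial before padding
#'   (default 60, i.e. 750 ms at 80 Hz).
#' @param noise_sd sensor noise SD (default 1).
#' @param condition_gain named gains per design cell; default
#'   [crossover_gains()]; pass all-1 gains for a null experiment.
#' @param lambda_grid ridge penalties (default a sparse 3-point grid).
#' @param lspec lag specification (default fit and predict over 0-250 ms).
#' @return list with `accuracy` (participant x condition x lambda tibble),
#'   `lambda` (selected), `cells` (per-participant cell accuracies at the
#'   selected lambda, with `prior`/`detail`/`value` columns), `effects`
#'   (RM-ANOVA table), and `condition_means`.
#' @export
simulate_crossover_experiment <- function(seed = 1, n_participants = 8,
                                          n_per_cell = 4, n_features = 4,
                                          n_sensors = 10, n_samples = 60,
                                          noise_sd = 1,
                                          condition_gain = crossover_gains(),
                                          lambda_grid = c(1, 32, 1024),
                                          lspec = lag_spec(c(0, 250), c(0, 250))) {
  design <- make_design(n_per_cell, seed = hash_seed("design", seed = seed))
  truth <- make_ground_truth(n_features, n_sensors, lspec,
                             noise_sd = noise_sd,
                             condition_gain = condition_gain,
                             seed = hash_seed("truth", seed = seed))
  feats <- lapply(seq_len(nrow(design)), function(i) {
    prepare(synth_feature_stream(n_samples, n_features,
                                 seed = hash_seed("feat", i, seed = seed)),
            lspec$fit_ms, zscore = FALSE)
  })
  cells <- cell_key(design$prior, design$detail)
  rows <- vector("list", 0)
  for (pp in seq_len(n_participants)) {
    neural <- synth_neural(feats, truth, design,
                           seed = hash_seed("participant", pp, seed = seed))
    fit <- trf_loto(feats, neural_trial_list(neural), lspec = lspec,
                    lambda_grid = lambda_grid)
    per_trial <- apply(fit$accuracy, c(1, 3), mean)
    for (li in seq_along(lambda_grid)) {
      cm <- tapply(per_trial[, li], cells, mean)
      rows[[length(rows) + 1]] <- tibble::tibble(
        participant = pp, condition = names(cm), lambda = lambda_grid[li],
        accuracy = as.numeric(cm))
    }
  }
  acc <- dplyr::bind_rows(rows)
  lambda_star <- select_lambda(acc)
  at <- acc[acc$lambda == lambda_star, ]
  parts <- strsplit(at$condition, ":")
  at$prior <- vapply(parts, `[`, "", 1)
  at$detail <- as.integer(vapply(parts, `[`, "", 2))
  at$value <- at$accuracy
  effects <- rm_anova_2x3(at)
  cond_means <- dplyr::summarise(dplyr::group_by(at, .data$prior, .data$detail),
                                 accuracy = mean(.data$value), .groups = "drop")
  list(accuracy = acc, lambda = lambda_star, cells = at, effects = effects,
       condition_means = cond_means, design = design, truth = truth)
}
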