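## End-to-end pipeline on synthetic data: design -> word audio -> features ->
## simulated sensor responses -> encoding fits -> lambda selection ->
## condition statistics -> permutation nulls -> acoustics -> schematic ->
## DSS summary. Every stage derives its seed from the single config seed, so
## a rerun with the same config is byte-identical.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    n_per_cell = 4L,
    n_blocks = 3L,
    n_participants = 6L,
    n_sensors = 16L,
    audio_rate = 44100,
    feature_channels = 6L,          # spectrogram bank size used for fitting
    fit_lags_ms = c(-100, 300),
    predict_lags_ms = c(0, 250),
    lambda_grid = 2^seq(0, 20, length.out = 5),
    noise_sd = 1,
    condition_gain = c("Mismatch:3" = 0.5, "Mismatch:6" = 1, "Mismatch:12" = 1.5,
                       "Match:3" = 1.5, "Match:6" = 1, "Match:12" = 0.5),
    n_perm = 10L,
    acoustics_words = 4L,
    acoustics_channels = c(1L, 24L),
    schematic_reps = 50L,
    out_dir = "stmtrf_results"
  )
}

#' Build and validate a pipeline configuration
#'
#' Starts from the package defaults and overrides them with the supplied
#' values (a named list or a YAML file path). Unknown keys are rejected.
#'
#' @param config named list of overrides, or a YAML file path, or `NULL` for
#'   the defaults.
#' @return validated config list (class `pipeline_config`).
#' @export
pipeline_config <- function(config = NULL) {
  defaults <- pipeline_defaults()
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  stopifnot(cfg$n_per_cell >= 1, cfg$n_participants >= 2,
            cfg$n_sensors >= 2, cfg$noise_sd >= 0, cfg$n_perm >= 1,
            all(cfg$lambda_grid > 0))
  needed <- as.vector(outer(c("Match", "Mismatch"), c(3, 6, 12), cell_key))
  if (!all(needed %in% names(cfg$condition_gain))) {
    stop("condition_gain must name all 6 design cells")
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic-data pipeline
#'
#' Simulates the experiment at the configured scale, fits encoding models for
#' every participant, selects lambda, tests the detail-by-prior interaction,
#' builds a permutation null, summarises stimulus acoustics and the
#' schematic coding-scheme simulation, and denoises the TRFs with DSS.
#' All result tables are written under `config$out_dir` together with a
#' provenance manifest (config hash, seed, package version).
#'
#' @param config a [pipeline_config()] (or overrides accepted by it).
#' @return invisibly, a list with the main results (`design`, `accuracy`,
#'   `lambda`, `effects`, `null`, `zscores`, `acoustics`, `schematic`,
#'   `dss_rms`).
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  lsp <- lag_spec(cfg$fit_lags_ms, cfg$predict_lags_ms)

  message("[design] ", 6 * cfg$n_per_cell, " trials")
  design <- make_design(cfg$n_per_cell, cfg$n_blocks, seed = cfg$seed)
  write_design(design, file.path(cfg$out_dir, "design.csv"))

  message("[audio] synthesizing ", length(unique(design$word_id)), " words")
  words <- rms_equalize(synth_word_set(design, rate = cfg$audio_rate,
                                       seed = cfg$seed))

  message("[features] ", cfg$feature_channels, "-channel spectrogram")
  bank <- greenwood_bank(cfg$feature_channels)
  feats <- lapply(design$word_id, function(id) {
    prepare(spectrogram_feature(words[[id]], bank = bank), lsp$fit_ms)
  })

  n_samp <- max(vapply(feats, function(f) nrow(f$values), 1L))
  feats_padded <- lapply(feats, pad_to_length, n_samples = n_samp)

  truth <- make_ground_truth(cfg$feature_channels, cfg$n_sensors, lsp,
                             noise_sd = cfg$noise_sd,
                             condition_gain = cfg$condition_gain,
                             seed = cfg$seed)

  message("[fit] ", cfg$n_participants, " simulated participants")
  acc_rows <- vector("list", cfg$n_participants)
  fits <- vector("list", cfg$n_participants)
  for (pp in seq_len(cfg$n_participants)) {
    neural <- synth_neural(feats, truth, design,
                           seed = hash_seed("participant", pp, seed = cfg$seed))
    fit <- trf_loto(feats_padded, neural_trial_list(neural), lspec = lsp,
                    lambda_grid = cfg$lambda_grid, space_id = "spectrogram")
    fits[[pp]] <- list(fit = fit, neural = neural)
    per_trial <- apply(fit$accuracy, c(1, 3), mean)   # over sensors
    cells <- cell_key(design$prior, design$detail)
    for (li in seq_along(cfg$lambda_grid)) {
      cond_means <- tapply(per_trial[, li], cells, mean)
      acc_rows[[pp]] <- dplyr::bind_rows(
        acc_rows[[pp]],
        tibble::tibble(participant = pp, condition = names(cond_means),
                       lambda = cfg$lambda_grid[li],
                       accuracy = as.numeric(cond_means)))
    }
  }
  acc <- dplyr::bind_rows(acc_rows)
  data.table::fwrite(acc, file.path(cfg$out_dir, "accuracy.csv"))

  lambda_star <- select_lambda(acc)
  jsonlite::write_json(list(lambda = lambda_star),
                       file.path(cfg$out_dir, "lambda.json"),
                       auto_unbox = TRUE, digits = NA)

  message("[stats] RM-ANOVA at lambda = ", signif(lambda_star, 3))
  at_star <- acc[acc$lambda == lambda_star, ]
  parts <- strsplit(at_star$condition, ":")
  at_star$prior <- vapply(parts, `[`, "", 1)
  at_star$detail <- as.integer(vapply(parts, `[`, "", 2))
  at_star$value <- at_star$accuracy
  effects <- rm_anova_2x3(at_star)
  data.table::fwrite(effects, file.path(cfg$out_dir, "effects.csv"))

  message("[permute] ", cfg$n_perm, " within-trial permutations")
  null <- null_distribution(feats_padded, fits[[1]]$neural, design, lambda_star,
                            lspec = lsp, scheme = "within_trial",
                            n_perm = cfg$n_perm,
                            seed = hash_seed("null", seed = cfg$seed))
  data.table::fwrite(null, file.path(cfg$out_dir, "null.csv"))
  obs1 <- at_star[at_star$participant == 1,
                  c("participant", "condition", "accuracy")]
  zs <- zscore_vs_null(obs1, null)
  data.table::fwrite(zs, file.path(cfg$out_dir, "zscores.csv"))

  message("[acoustics] ", cfg$acoustics_words, " words x channels ",
          paste(cfg$acoustics_channels, collapse = "/"))
  aw <- words[seq_len(min(cfg$acoustics_words, length(words)))]
  grids <- lapply(cfg$acoustics_channels, function(nc)
    modulation_magnitude(aw, nc, seed = cfg$seed))
  names(grids) <- paste0("ch", cfg$acoustics_channels)
  for (nm in names(grids)) {
    write_grid(apply(grids[[nm]], c(2, 3), mean),
               file.path(cfg$out_dir, paste0("magnitude_", nm, ".csv")))
  }
  contrast <- NULL
  if (length(grids) >= 2) {
    contrast <- channel_contrast(grids[[length(grids)]], grids[[1]])
    write_grid(contrast$t, file.path(cfg$out_dir, "magnitude_contrast_t.csv"))
  }

  message("[schematic] ", cfg$schematic_reps, " reps")
  schem <- run_schematic_grid(n_reps = cfg$schematic_reps,
                              seed = hash_seed("schematic", seed = cfg$seed))
  schem_summary <- dplyr::summarise(
    dplyr::group_by(schem, .data$prior, .data$level, .data$scheme),
    fidelity = mean(.data$fidelity), pe_abs = mean(.data$pe_abs),
    .groups = "drop")
  data.table::fwrite(schem_summary, file.path(cfg$out_dir, "schematic.csv"))

  message("[dss] TRF denoising")
  fit1 <- fits[[1]]$fit
  li <- which(cfg$lambda_grid == lambda_star)
  trf_trials <- lapply(seq_len(dim(fit1$per_trial_coefs)[4]), function(tr)
    fit1$per_trial_coefs[, , li, tr])
  dec <- dss_fit(trf_trials)
  den <- dss_denoise(trf_trials, dec, n_keep = 3)
  avg <- Reduce(`+`, den) / length(den)
  left <- fits[[1]]$neural$sensors$hemisphere == "L"
  # RMS over left sensors of the lag profile (averaged over features).
  nl <- length(fit1$lags)
  lag_profile <- sapply(seq_len(nl), function(li2) {
    rows <- seq(li2, nrow(avg), by = nl)
    sensor_rms(matrix(colMeans(avg[rows, , drop = FALSE]), nrow = 1),
               which(left))
  })
  dss_rms <- tibble::tibble(lag_ms = fit1$lags / lsp$rate * 1000,
                            rms = as.numeric(lag_profile))
  data.table::fwrite(dss_rms, file.path(cfg$out_dir, "dss_rms.csv"))

  manifest <- list(package = "stmtrf",
                   version = as.character(utils::packageVersion("stmtrf")),
                   config = unclass(cfg),
                   config_hash = rlang::hash(unclass(cfg)),
                   seed = cfg$seed)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(design = design, accuracy = acc, lambda = lambda_star,
                 effects = effects, null = null, zscores = zs,
                 acoustics = list(grids = grids, contrast = contrast),
                 schematic = schem_summary, dss_rms = dss_rms))
}
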