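## Decoding direction: project sensors to principal components, then map the
## lagged neural matrix back to the stimulus spectrotemporal modulation time
## series (and its single-lag variant to resolve latency).

#' Reduce sensor data to principal components
#'
#' Principal components are fitted on the concatenation of all trials'
#' (z-scored) sensor data and each trial is projected onto the leading
#' `n_components`.
#'
#' @param epochs an `epoched_neural`.
#' @param n_components components to retain (default 50; reduced with a
#'   warning when there are fewer sensors).
#' @param zscore z-score each sensor series per trial first (default TRUE).
#' @return list with `trials` (per-trial time x component matrices),
#'   `rotation`, `center`, `sdev` (component SDs over the training
#'   concatenation).
#' @export
decode_setup <- function(epochs, n_components = 50, zscore = TRUE) {
  y_list <- neural_trial_list(epochs, zscore = zscore)
  n_sens <- ncol(y_list[[1]])
  if (n_sens < n_components) {
    warning("fewer sensors (", n_sens, ") than requested components (",
            n_components, "); retaining ", n_sens)
    n_components <- n_sens
  }
  stacked <- do.call(rbind, y_list)
  pc <- stats::prcomp(stacked, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  trials <- lapply(y_list, function(m) sweep(m, 2, pc$center) %*% rot)
  list(trials = trials, rotation = rot, center = pc$center,
       sdev = pc$sdev[seq_len(k)])
}

#' Decode stimulus modulations from neural components
#'
#' Leave-one-trial-out ridge decoding of each of the 25 spectrotemporal
#' modulation time series from the lagged neural components.
#'
#' @param reduced output of [decode_setup()].
#' @param targets list of prepared target `feature_space`s (e.g. STM), one
#'   per trial, zero-padded to the epoch length.
#' @param lspec a [lag_spec()].
#' @param lambda_grid ridge penalties.
#' @return a `trf_cv` object with one output unit per modulation cell.
#' @export
decode <- function(reduced, targets, lspec = lag_spec(),
                   lambda_grid = default_lambda_grid()) {
  n_samp <- nrow(reduced$trials[[1]])
  y_list <- lapply(targets, function(f) pad_to_length(f, n_samp)$values)
  trf_loto(reduced$trials, y_list, lspec = lspec, lambda_grid = lambda_grid,
           direction = "decoding",
           space_id = targets[[1]]$space_id)
}

#' Single-lag decoding
#'
#' Fits and evaluates a separate decoding model at each lag between
#' `lag_range_ms[1]` and `lag_range_ms[2]` (one sample shift per model);
#' lambda is optimized independently per lag (argmax of the mean accuracy
#' over trials and output units, ties toward smaller lambda).
#'
#' @inheritParams decode
#' @param lag_range_ms lag range in ms (default -50..250).
#' @param rate sampling rate (default 80 Hz).
#' @return tibble with columns `lag_ms`, `lambda`, `trial`, `output`, `r`.
#' @export
single_lag_decode <- function(reduced, targets, lag_range_ms = c(-50, 250),
                              lambda_grid = default_lambda_grid(),
                              rate = NEURAL_RATE) {
  n_samp <- nrow(reduced$trials[[1]])
  y_list <- lapply(targets, function(f) pad_to_length(f, n_samp)$values)
  lags_ms <- seq(lag_range_ms[1], lag_range_ms[2], by = 1000 / rate)
  out <- vector("list", length(lags_ms))
  for (i in seq_along(lags_ms)) {
    lsp <- lag_spec(fit_ms = rep(lags_ms[i], 2), predict_ms = rep(lags_ms[i], 2),
                    rate = rate)
    fit <- trf_loto(reduced$trials, y_list, lspec = lsp,
                    lambda_grid = lambda_grid, direction = "decoding",
                    space_id = targets[[1]]$space_id)
    mean_acc <- apply(fit$accuracy, 3, mean)
    li <- which.max(mean_acc)   # first (smallest lambda) on ties
    tbl <- accuracy_table(fit, lambda = fit$lambda_grid[li])
    tbl$lag_ms <- lags_ms[i]
    out[[i]] <- tbl[, c("lag_ms", "lambda", "trial", "output", "r")]
  }
  dplyr::bind_rows(out)
}
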