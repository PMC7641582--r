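## Stimulus feature spaces. All spaces are time x feature matrices at the
## neural sampling rate (80 Hz); acoustic spaces are z-scored per trial and
## zero-padded to the extreme model lags by prepare().

NEURAL_RATE <- 80

#' Construct a feature space
#'
#' @param values time x feature numeric matrix.
#' @param rate sampling rate in Hz.
#' @param space_id identity: one of `"envelope"`, `"spectrogram"`,
#'   `"spectral_derivative"`, `"stm"`, `"phonetic"` or a combined id.
#' @param feature_labels optional column labels.
#' @param acoustic logical: is this an acoustic space (z-scored by
#'   [prepare()])?
#' @param bands optional named list of column index ranges (feature-space
#'   blocks for banded ridge).
#' @return A `feature_space` object.
#' @export
feature_space <- function(values, rate, space_id,
                          feature_labels = colnames(values),
                          acoustic = TRUE, bands = NULL) {
  values <- as.matrix(values)
  stopifnot(all(is.finite(values)))
  if (is.null(feature_labels)) feature_labels <- paste0("f", seq_len(ncol(values)))
  colnames(values) <- feature_labels
  if (is.null(bands)) bands <- stats::setNames(list(seq_len(ncol(values))), space_id)
  structure(list(values = values, rate = rate, space_id = space_id,
                 feature_labels = feature_labels, acoustic = acoustic,
                 bands = bands, pad_pre_ms = 0, pad_post_ms = 0),
            class = "feature_space")
}

#' @export
print.feature_space <- function(x, ...) {
  cat(sprintf("<feature_space %s: %d samples x %d features @ %g Hz>\n",
              x$space_id, nrow(x$values), ncol(x$values), x$rate))
  invisible(x)
}

#' Broadband envelope feature (1 feature)
#'
#' Sum of the 24 Greenwood-channel envelopes of the clear waveform,
#' resampled to 80 Hz. Identical to the column sum of
#' [spectrogram_feature()].
#'
#' @param audio clear (pre-vocoding) `audio_waveform`.
#' @param bank channel bank (default 24-channel Greenwood).
#' @param rate_out output sampling rate (Hz).
#' @return `feature_space` with one column.
#' @export
envelope_feature <- function(audio, bank = greenwood_bank(24),
                             rate_out = NEURAL_RATE) {
  sg <- spectrogram_feature(audio, bank = bank, rate_out = rate_out)
  v <- matrix(rowSums(sg$values), ncol = 1)
  if (all(abs(v) < 1e-12)) attr(v, "silent") <- TRUE
  fs <- feature_space(v, rate_out, "envelope", feature_labels = "envelope")
  attr(fs, "silent") <- isTRUE(attr(v, "silent"))
  fs
}

#' Spectrogram feature (24 channel envelopes)
#'
#' Envelope of each spectral channel of a 24-channel Greenwood bank, at 80
#' Hz. `compress_exponent` applies an optional compressive power-law (e.g.
#' 0.3) to the non-negative envelope values before any later z-scoring.
#'
#' @inheritParams envelope_feature
#' @param compress_exponent `NULL` (none) or a positive exponent.
#' @return `feature_space` with `bank$n_channels` columns.
#' @export
spectrogram_feature <- function(audio, bank = greenwood_bank(24),
                                rate_out = NEURAL_RATE,
                                compress_exponent = NULL) {
  stopifnot(inherits(audio, "audio_waveform"))
  env <- sapply(seq_len(bank$n_channels), function(ch) {
    band <- fft_filter(audio$samples, audio$rate,
                       lo = bank$edges[ch], hi = bank$edges[ch + 1], order = 4)
    resample_to(extract_envelope(band, audio$rate), audio$rate, rate_out)
  })
  env <- pmax(as.matrix(env), 0)
  if (!is.null(compress_exponent)) env <- env^compress_exponent
  feature_space(env, rate_out, "spectrogram",
                feature_labels = sprintf("ch%02d", seq_len(bank$n_channels)))
}

#' Half-wave rectified spectral derivative (spectral onsets)
#'
#' Per-channel first temporal difference of the spectrogram with negative
#' values set to zero. The first sample is zero so the length is preserved.
#'
#' @param spectrogram a `feature_space` with `space_id == "spectrogram"`.
#' @return `feature_space` with the same number of columns.
#' @export
spectral_derivative <- function(spectrogram) {
  stopifnot(inherits(spectrogram, "feature_space"))
  if (spectrogram$space_id != "spectrogram") {
    stop("spectral_derivative expects a spectrogram feature space")
  }
  d <- apply(spectrogram$values, 2, function(col) c(0, pmax(diff(col), 0)))
  feature_space(as.matrix(d), spectrogram$rate, "spectral_derivative",
                feature_labels = sub("^ch", "d", spectrogram$feature_labels))
}

#' Concatenate feature spaces column-wise
#'
#' Records the column block of each component space so banded ridge can
#' regularize them independently.
#'
#' @param ... `feature_space`s with equal time axes and rates.
#' @return combined `feature_space` with `space_id` like
#'   `"spectrogram+phonetic"`.
#' @export
combine_spaces <- function(...) {
  spaces <- list(...)
  if (length(spaces) == 1) return(spaces[[1]])
  rates <- vapply(spaces, function(s) s$rate, numeric(1))
  if (length(unique(rates)) != 1) stop("rate mismatch between feature spaces")
  ns <- vapply(spaces, function(s) nrow(s$values), integer(1))
  if (length(unique(ns)) != 1) stop("time axis mismatch between feature spaces")
  vals <- do.call(cbind, lapply(spaces, function(s) s$values))
  ids <- vapply(spaces, function(s) s$space_id, "")
  widths <- vapply(spaces, function(s) ncol(s$values), integer(1))
  ends <- cumsum(widths)
  bands <- stats::setNames(
    lapply(seq_along(spaces), function(i) (ends[i] - widths[i] + 1):ends[i]),
    ids)
  fs <- feature_space(vals, rates[1], paste(ids, collapse = "+"),
                      acoustic = all(vapply(spaces, function(s) s$acoustic, TRUE)),
                      bands = bands)
  fs$component_acoustic <- stats::setNames(
    vapply(spaces, function(s) s$acoustic, TRUE), ids)
  fs
}

#' Prepare a feature space for model fitting
#'
#' Resamples to the neural rate if needed, z-scores acoustic feature columns
#' per trial (each time series to mean 0, SD 1; constant columns are left at
#' zero and flagged), and zero-pads before onset by `|min lag|` and after
#' offset by `|max lag|` so information at the word edges can inform the lag
#' model.
#'
#' @param space a `feature_space`.
#' @param lags_ms length-2 numeric, the extreme fit lags in ms (default
#'   `c(-100, 300)`).
#' @param zscore override the space's `acoustic` flag (`NULL` = use it). In
#'   combined spaces only the acoustic component blocks are z-scored.
#' @param rate_out target rate (default 80 Hz).
#' @return the prepared `feature_space` with padding metadata set.
#' @export
prepare <- function(space, lags_ms = c(-100, 300), zscore = NULL,
                    rate_out = NEURAL_RATE) {
  stopifnot(inherits(space, "feature_space"))
  v <- space$values
  if (space$rate != rate_out) {
    v <- apply(v, 2, resample_to, fs_in = space$rate, fs_out = rate_out)
    v <- matrix(v, ncol = ncol(space$values),
                dimnames = list(NULL, colnames(space$values)))
  }
  do_z <- if (is.null(zscore)) space$acoustic else zscore
  if (!is.null(space$component_acoustic) && is.null(zscore)) {
    for (id in names(space$bands)) {
      if (isTRUE(space$component_acoustic[[id]])) {
        cols <- space$bands[[id]]
        v[, cols] <- zscore_cols(v[, cols, drop = FALSE])
      }
    }
  } else if (isTRUE(do_z)) {
    v <- zscore_cols(v)
  }
  pre <- ms_to_samples(abs(min(lags_ms, 0)), rate_out)
  post <- ms_to_samples(max(lags_ms, 0), rate_out)
  pad0 <- function(k) matrix(0, k, ncol(v), dimnames = list(NULL, colnames(v)))
  v <- rbind(pad0(pre), v, pad0(post))
  out <- space
  out$values <- v
  out$rate <- rate_out
  out$pad_pre_ms <- pre / rate_out * 1000
  out$pad_post_ms <- post / rate_out * 1000
  out
}

# Zero-pad a prepared space's time axis up to n_samples rows (rectangular
# epoch arrays need a common length across words of different durations).
pad_to_length <- function(space, n_samples) {
  k <- n_samples - nrow(space$values)
  stopifnot(k >= 0)
  if (k > 0) {
    space$values <- rbind(space$values,
                          matrix(0, k, ncol(space$values),
                                 dimnames = list(NULL, colnames(space$values))))
  }
  space
}
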