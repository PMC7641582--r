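## Simulated sensor responses: lagged linear convolution of stimulus
## features with known response functions, scaled by a condition-dependent
## encoding gain (the simulation's stand-in for prediction-error coding) plus
## Gaussian sensor noise.

#' Construct simulation ground truth
#'
#' The generating temporal response function is a smooth kernel over the lag
#' axis with a dominant peak (default 87.5 ms) and a weaker opposite-polarity
#' secondary peak (default 150 ms), multiplied by random feature-by-sensor
#' loadings.
#'
#' @param n_features number of stimulus features.
#' @param n_sensors number of sensors.
#' @param lspec a [lag_spec()]; the generating lags are its predict window.
#' @param peaks_ms latencies of the two kernel peaks.
#' @param peak_amps amplitudes of the two peaks.
#' @param kernel_type `"smooth"` (Gaussian bumps, default) or `"impulse"`
#'   (a one-sample response at the lag nearest `peaks_ms[1]`, which makes the
#'   stimulus-to-sensor mapping exactly invertible for decoding-consistency
#'   checks).
#' @param peak_width_ms Gaussian width of the smooth kernel peaks.
#' @param noise_sd sensor noise SD (>= 0).
#' @param condition_gain named numeric multiplier per design cell
#'   (names `"Match:3"` ... `"Mismatch:12"`); defaults to 1 everywhere.
#' @param seed integer seed.
#' @return a `ground_truth` object: list with `weights` (lags x features x
#'   sensors), `lags`, `lag_ms`, `noise_sd`, `condition_gain`, `seed`.
#' @export
make_ground_truth <- function(n_features, n_sensors, lspec = lag_spec(),
                              peaks_ms = c(87.5, 150), peak_amps = c(1, -0.5),
                              kernel_type = c("smooth", "impulse"),
                              peak_width_ms = 18,
                              noise_sd = 1, condition_gain = NULL, seed = 1) {
  kernel_type <- match.arg(kernel_type)
  stopifnot(noise_sd >= 0)
  if (is.null(condition_gain)) {
    condition_gain <- stats::setNames(
      rep(1, 6), as.vector(outer(c("Match", "Mismatch"), c(3, 6, 12), cell_key)))
  }
  needed <- as.vector(outer(c("Match", "Mismatch"), c(3, 6, 12), cell_key))
  if (!all(needed %in% names(condition_gain))) {
    stop("condition_gain must cover all 6 design cells")
  }
  with_seed(hash_seed("truth", seed = seed), {
    lags <- lspec$predict_lags
    lag_ms <- lags / lspec$rate * 1000
    kernel <- numeric(length(lags))
    if (kernel_type == "impulse") {
      kernel[which.min(abs(lag_ms - peaks_ms[1]))] <- 1
    } else {
      for (i in seq_along(peaks_ms)) {
        kernel <- kernel +
          peak_amps[i] * exp(-0.5 * ((lag_ms - peaks_ms[i]) / peak_width_ms)^2)
      }
    }
    loadings <- matrix(stats::rnorm(n_features * n_sensors), n_features)
    w <- array(0, c(length(lags), n_features, n_sensors))
    for (j in seq_len(n_features)) for (s in seq_len(n_sensors)) {
      w[, j, s] <- kernel * loadings[j, s]
    }
    structure(list(weights = w, lags = lags, lag_ms = lag_ms,
                   noise_sd = noise_sd, condition_gain = condition_gain,
                   seed = seed, rate = lspec$rate),
              class = "ground_truth")
  })
}

#' Construct an epoched neural container
#'
#' @param data trials x sensors x samples array.
#' @param sensors tibble with `name`, `hemisphere` (`"L"`/`"R"`), `x`
#'   (layout coordinate).
#' @param rate sampling rate (Hz).
#' @param t0_ms time of the first sample relative to stimulus onset.
#' @return an `epoched_neural` object.
#' @export
epoched_neural <- function(data, sensors, rate = NEURAL_RATE, t0_ms = 0) {
  stopifnot(length(dim(data)) == 3, dim(data)[2] == nrow(sensors))
  structure(list(data = data, sensors = tibble::as_tibble(sensors),
                 rate = rate, t0_ms = t0_ms),
            class = "epoched_neural")
}

#' @export
print.epoched_neural <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_neural: %d trials x %d sensors x %d samples @ %g Hz>\n",
              d[1], d[2], d[3], x$rate))
  invisible(x)
}

#' Synthetic planar sensor layout
#'
#' Sensors are placed on a left/right coordinate and assigned to hemispheres
#' by the sign of that coordinate (half per side).
#'
#' @param n_sensors number of sensors (even).
#' @return tibble with `name`, `x`, `hemisphere`.
#' @export
make_sensor_layout <- function(n_sensors) {
  x <- seq(-1, 1, length.out = n_sensors + 2)[-c(1, n_sensors + 2)]
  x <- x + ifelse(x == 0, 1e-3, 0)
  tibble::tibble(name = sprintf("MEG%03d", seq_len(n_sensors)),
                 x = x, hemisphere = ifelse(x < 0, "L", "R"))
}

#' Simulate epoched sensor responses from stimulus features
#'
#' Each trial's sensor series is `gain * (lagged features . truth weights)`
#' plus white Gaussian noise, where the gain depends on the trial's design
#' cell. Trials are zero-padded to a common epoch length.
#'
#' @param features list of prepared `feature_space`s, one per design row
#'   (ordered as `design`). All must share the neural rate.
#' @param truth a `ground_truth` from [make_ground_truth()].
#' @param design tibble from [make_design()].
#' @param n_sensors number of sensors (must match `truth`).
#' @param seed seed for the noise draws.
#' @return an `epoched_neural`; attribute `"n_valid"` gives each trial's
#'   unpadded sample count.
#' @export
synth_neural <- function(features, truth, design, n_sensors = dim(truth$weights)[3],
                         seed = 1) {
  stopifnot(inherits(truth, "ground_truth"), length(features) == nrow(design))
  n_feat <- dim(truth$weights)[2]
  if (ncol(features[[1]]$values) != n_feat) {
    stop("feature count (", ncol(features[[1]]$values),
         ") does not match ground-truth weights (", n_feat, ")")
  }
  if (n_sensors != dim(truth$weights)[3]) {
    stop("n_sensors does not match ground-truth weights")
  }
  rate <- features[[1]]$rate
  lens <- vapply(features, function(f) nrow(f$values), 1L)
  n_samp <- max(lens)
  if (n_samp <= max(abs(truth$lags))) {
    stop("epoch shorter than the longest ground-truth lag")
  }
  nl <- length(truth$lags)
  w_flat <- matrix(0, nl * n_feat, n_sensors)
  for (j in seq_len(n_feat)) {
    w_flat[((j - 1) * nl + 1):(j * nl), ] <- truth$weights[, j, ]
  }
  layout <- make_sensor_layout(n_sensors)
  data <- array(0, c(nrow(design), n_sensors, n_samp))
  with_seed(hash_seed("neural", seed = seed), {
    for (tr in seq_len(nrow(design))) {
      f <- pad_to_length(features[[tr]], n_samp)
      X <- lag_matrix(f$values, truth$lags)
      gain <- truth$condition_gain[[cell_key(design$prior[tr], design$detail[tr])]]
      y <- gain * (X %*% w_flat)
      if (truth$noise_sd > 0) {
        y <- y + matrix(stats::rnorm(length(y), 0, truth$noise_sd), nrow(y))
      }
      data[tr, , ] <- t(y)
    }
  })
  out <- epoched_neural(data, layout, rate = rate,
                        t0_ms = -features[[1]]$pad_pre_ms)
  attr(out, "n_valid") <- lens
  out
}

#' Synthesize a band-limited feature stream
#'
#' Gaussian noise low-passed to `bandwidth_hz`, mimicking the smoothness of
#' real modulation/envelope time series at the neural rate; used as a known
#' ground-truth stimulus representation in simulations.
#'
#' @param n_samples samples per feature series.
#' @param n_features number of features.
#' @param rate sampling rate (Hz).
#' @param bandwidth_hz low-pass cutoff (Hz); `NULL` leaves the noise white.
#' @param space_id stored feature-space id.
#' @param seed integer seed.
#' @return a `feature_space` (not yet prepared).
#' @export
synth_feature_stream <- function(n_samples, n_features, rate = NEURAL_RATE,
                                 bandwidth_hz = 12, space_id = "synthetic",
                                 seed = 1) {
  with_seed(hash_seed("featstream", seed = seed), {
    v <- sapply(seq_len(n_features), function(j) {
      x <- stats::rnorm(n_samples)
      if (!is.null(bandwidth_hz)) x <- fft_filter(x, rate, hi = bandwidth_hz,
                                                  order = 4)
      x
    })
    feature_space(matrix(v, n_samples, n_features), rate, space_id)
  })
}

# Per-trial samples x sensors matrices, optionally z-scored per series
# (mean 0, SD 1 per sensor per trial), as used before model fitting.
neural_trial_list <- function(epochs, zscore = TRUE) {
  n_tr <- dim(epochs$data)[1]
  lapply(seq_len(n_tr), function(tr) {
    m <- t(epochs$data[tr, , , drop = TRUE])
    colnames(m) <- epochs$sensors$name
    if (zscore) m <- zscore_cols(m)
    m
  })
}
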