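## Auditory spectrogram front end and 2D spectrotemporal modulation
## decomposition. The modulation filterbank is a separable bank of
## Gabor-type (log-Gaussian, Q ~ 1) bandpass filters applied in the 2D
## Fourier domain of the log-frequency spectrogram, octave-spaced at
## 0.5/1/2/4/8 cycles per octave and 1/2/4/8/16 Hz, with the analytic
## magnitude taken per sweep direction and averaged over frequency channels
## and directions.

#' Modulation axes of the 5 x 5 spectrotemporal grid
#' @return list with `spectral_mods` (cycles/octave) and `temporal_mods` (Hz).
#' @export
modulation_axes <- function() {
  list(spectral_mods = c(0.5, 1, 2, 4, 8), temporal_mods = c(1, 2, 4, 8, 16))
}

#' Constant-Q auditory spectrogram
#'
#' 128 constant-Q channels with logarithmic centre frequencies between 180
#' and 7040 Hz; channel envelopes (analytic magnitude) are integrated with an
#' 8 ms leaky time constant and sampled once per 8 ms frame. No compressive
#' nonlinearity is applied.
#'
#' @param audio an `audio_waveform` with rate of at least `2 * hi`.
#' @param n_channels number of channels (default 128).
#' @param lo,hi frequency range in Hz (defaults 180 and 7040).
#' @param frame_ms frame length in ms (default 8).
#' @param tau_ms integration time constant in ms (default 8).
#' @return frames x channels matrix with attributes `frame_rate` (Hz),
#'   `centers` (Hz) and `channels_per_octave`.
#' @export
auditory_spectrogram <- function(audio, n_channels = 128, lo = 180, hi = 7040,
                                 frame_ms = 8, tau_ms = 8) {
  stopifnot(inherits(audio, "audio_waveform"))
  fs <- audio$rate
  if (fs < 2 * hi) stop("audio rate must be at least ", 2 * hi, " Hz")
  x <- audio$samples
  n <- length(x)
  centers <- 2^seq(log2(lo), log2(hi), length.out = n_channels)
  spacing_oct <- log2(hi / lo) / (n_channels - 1)
  sigma_oct <- 3 * spacing_oct   # filter width; constant Q (~5) across channels

  nfft <- stats::nextn(2L * n, 2)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  k <- seq_len(nfft) - 1
  f_signed <- ifelse(k <= nfft / 2, k, k - nfft) * fs / nfft
  pos <- f_signed > 0
  a <- exp(-1 / (tau_ms / 1000 * fs))

  nf <- ceiling(n / (frame_ms / 1000 * fs))
  frame_idx <- pmin(n, round((seq_len(nf) - 1) * frame_ms / 1000 * fs) + 1)
  out <- matrix(0, nf, n_channels)
  H <- numeric(nfft)
  for (ch in seq_len(n_channels)) {
    H[] <- 0
    H[pos] <- 2 * exp(-0.5 * (log2(f_signed[pos] / centers[ch]) / sigma_oct)^2)
    env <- Mod(stats::fft(X * H, inverse = TRUE)[seq_len(n)]) / nfft
    sm <- stats::filter(env * (1 - a), a, method = "recursive")
    out[, ch] <- as.numeric(sm)[frame_idx]
  }
  colnames(out) <- sprintf("%.0fHz", centers)
  attr(out, "frame_rate") <- 1000 / frame_ms
  attr(out, "centers") <- centers
  attr(out, "channels_per_octave") <- 1 / spacing_oct
  out
}

# 2D modulation filtering of an auditory spectrogram. Returns the full
# pre-averaging tensor: frames x channels x 5 scales x 5 rates x 2 sweep
# directions (= 6400 dimensions per frame for the 128-channel front end).
stm_decompose_spectrogram <- function(spec, axes = modulation_axes(),
                                      q_sigma = 0.5) {
  nf <- nrow(spec); nc <- ncol(spec)
  frame_rate <- attr(spec, "frame_rate")
  cpo <- attr(spec, "channels_per_octave")
  nt2 <- stats::nextn(2L * nf, 2)
  nc2 <- stats::nextn(2L * nc, 2)
  padded <- matrix(0, nt2, nc2)
  padded[seq_len(nf), seq_len(nc)] <- spec
  FF <- stats::fft(padded)

  kt <- seq_len(nt2) - 1
  wt <- ifelse(kt <= nt2 / 2, kt, kt - nt2) * frame_rate / nt2   # Hz
  ks <- seq_len(nc2) - 1
  ws <- ifelse(ks <= nc2 / 2, ks, ks - nc2) * cpo / nc2          # cyc/oct

  gauss_log <- function(w, w0) {
    out <- numeric(length(w))
    nz <- w > 0
    out[nz] <- exp(-0.5 * (log2(w[nz] / w0) / q_sigma)^2)
    out
  }
  # Quadrant masks select one sweep direction (analytic in both axes).
  same_sign <- outer(wt > 0, ws > 0, "&") | outer(wt < 0, ws < 0, "&")
  opp_sign <- outer(wt > 0, ws < 0, "&") | outer(wt < 0, ws > 0, "&")

  sm <- axes$spectral_mods; tm <- axes$temporal_mods
  tensor <- array(0, c(nf, nc, length(sm), length(tm), 2))
  for (si in seq_along(sm)) {
    Hs <- gauss_log(abs(ws), sm[si])
    for (ti in seq_along(tm)) {
      Ht <- gauss_log(abs(wt), tm[ti])
      H2 <- outer(Ht, Hs)
      for (di in 1:2) {
        mask <- if (di == 1) same_sign else opp_sign
        z <- stats::fft(FF * (H2 * mask), inverse = TRUE) / (nt2 * nc2)
        tensor[, , si, ti, di] <- 2 * Mod(z[seq_len(nf), seq_len(nc)])
      }
    }
  }
  dimnames(tensor) <- list(NULL, colnames(spec),
                           paste0(sm, "cpo"), paste0(tm, "Hz"),
                           c("up", "down"))
  attr(tensor, "frame_rate") <- frame_rate
  tensor
}

#' Full spectrotemporal modulation decomposition
#'
#' @param audio an `audio_waveform`.
#' @param axes modulation axes (see [modulation_axes()]).
#' @param ... passed to [auditory_spectrogram()].
#' @return frames x channels x scales x rates x directions array (6400
#'   non-time dimensions for the default 128-channel front end), with
#'   attribute `frame_rate`.
#' @export
stm_decompose <- function(audio, axes = modulation_axes(), ...) {
  stm_decompose_spectrogram(auditory_spectrogram(audio, ...), axes = axes)
}

#' Spectrotemporal modulation feature space (25 features)
#'
#' Magnitude of the 2D modulation decomposition of the auditory spectrogram,
#' averaged over the 128 frequency channels and over the up/down temporal
#' sweep directions, yielding one time series per (spectral modulation,
#' temporal modulation) cell; resampled to 80 Hz.
#'
#' @inheritParams stm_decompose
#' @param rate_out output sampling rate in Hz (default 80).
#' @return `feature_space` with 25 columns labelled `"s<cpo>_t<Hz>"`, in
#'   row-major grid order (spectral modulation varying slowest).
#' @export
stm_feature <- function(audio, axes = modulation_axes(),
                        rate_out = NEURAL_RATE, ...) {
  tensor <- stm_decompose(audio, axes = axes, ...)
  frame_rate <- attr(tensor, "frame_rate")
  # average over channels (2) and directions (5)
  grid_series <- apply(tensor, c(1, 3, 4), mean)
  nf <- dim(grid_series)[1]
  labs <- as.vector(outer(axes$temporal_mods, axes$spectral_mods,
                          function(t, s) sprintf("s%g_t%g", s, t)))
  flat <- matrix(0, nf, 25)
  k <- 0
  for (si in seq_along(axes$spectral_mods)) {
    for (ti in seq_along(axes$temporal_mods)) {
      k <- k + 1
      flat[, k] <- grid_series[, si, ti]
    }
  }
  colnames(flat) <- labs
  v <- apply(flat, 2, resample_to, fs_in = frame_rate, fs_out = rate_out)
  if (nf == 1) v <- matrix(v, nrow = 1, dimnames = list(NULL, labs))
  feature_space(as.matrix(v), rate_out, "stm", feature_labels = labs)
}

# Indices of the 25-column STM layout for a given (scale, rate) cell.
stm_cell_index <- function(si, ti, n_t = 5) (si - 1) * n_t + ti

#' Synthesize a moving-ripple test stimulus
#'
#' A dynamic ripple: log-spaced tone carriers whose amplitudes are modulated
#' by a drifting sinusoid with a set spectral modulation (cycles/octave) and
#' temporal modulation (Hz). Used to probe the modulation filterbank.
#'
#' @param scale_cpo spectral modulation in cycles/octave.
#' @param rate_hz temporal modulation in Hz.
#' @param duration_ms duration in ms.
#' @param rate audio sampling rate in Hz.
#' @param n_carriers number of carriers.
#' @param f_range carrier frequency range in Hz.
#' @param depth modulation depth in (0, 1].
#' @param seed seed for the carrier phases.
#' @return an `audio_waveform`.
#' @export
synth_ripple <- function(scale_cpo, rate_hz, duration_ms = 1000, rate = 16000,
                         n_carriers = 64, f_range = c(250, 6000),
                         depth = 0.9, seed = 1) {
  with_seed(hash_seed("ripple", scale_cpo, rate_hz, seed = seed), {
    n <- round(duration_ms / 1000 * rate)
    t <- (seq_len(n) - 1) / rate
    fc <- 2^seq(log2(f_range[1]), log2(f_range[2]), length.out = n_carriers)
    x_oct <- log2(fc / f_range[1])
    phases <- stats::runif(n_carriers, 0, 2 * pi)
    out <- numeric(n)
    for (j in seq_len(n_carriers)) {
      am <- 1 + depth * sin(2 * pi * (rate_hz * t + scale_cpo * x_oct[j]))
      out <- out + am * sin(2 * pi * fc[j] * t + phases[j]) / sqrt(n_carriers)
    }
    audio_waveform(out / rms(out) * 0.05, rate, word_id = "ripple")
  })
}
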