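#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## Internal numerical helpers shared across modules.

#' Root-mean-square of a numeric vector
#' @param x numeric vector.
#' @return scalar RMS.
#' @export
rms <- function(x) sqrt(mean(x^2))

# Evaluate expr with a temporarily-seeded RNG, restoring global state after.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic 31-bit integer from a string + integer seed (FNV-style mix).
# Used to derive per-word / per-stage seeds below 2^31.
hash_seed <- function(..., seed = 0L) {
  s <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
             collapse = "|")
  h <- 5381
  for (ch in utf8ToInt(s)) {
    h <- (h * 33 + ch) %% 2147483629
  }
  as.integer(h) + 1L
}

# Frequency (Hz) of each DFT bin for a length-n transform at rate fs,
# folded so bin k and its conjugate share |f|.
fft_bin_freqs <- function(n, fs) {
  f <- (seq_len(n) - 1) * fs / n
  pmin(f, fs - f)
}

# Zero-phase Butterworth-magnitude filtering applied in the frequency domain.
# The effective amplitude response is |H|^2 with H the order-`order`
# Butterworth magnitude (the response a forward-backward IIR pass would have),
# so filtered output is exactly zero-phase. `lo`/`hi` give the band edges in
# Hz; omit one for pure high-/low-pass. Input is zero-padded to avoid
# wrap-around.
fft_filter <- function(x, fs, lo = NULL, hi = NULL, order = 4) {
  stopifnot(is.numeric(x), fs > 0)
  n <- length(x)
  if (n < 2) return(x)
  if (!is.null(hi) && hi >= fs / 2) {
    stop("upper cutoff (", hi, " Hz) must be below the Nyquist frequency (",
         fs / 2, " Hz)")
  }
  nfft <- stats::nextn(2L * n, 2)
  f <- fft_bin_freqs(nfft, fs)
  H <- rep(1, nfft)
  if (!is.null(hi)) H <- H / sqrt(1 + (f / hi)^(2 * order))
  if (!is.null(lo)) {
    hp <- ifelse(f > 0, 1 / sqrt(1 + (lo / f)^(2 * order)), 0)
    H <- H * hp
  }
  X <- stats::fft(c(x, rep(0, nfft - n)))
  Re(stats::fft(X * H^2, inverse = TRUE))[seq_len(n)] / nfft
}

# Band-limit then linearly interpolate a series onto an exact fs_out grid.
# Anti-alias lowpass at 0.45 * fs_out when downsampling.
resample_to <- function(x, fs_in, fs_out) {
  stopifnot(fs_in > 0, fs_out > 0)
  if (fs_in == fs_out) return(x)
  n <- length(x)
  if (fs_out < fs_in) x <- fft_filter(x, fs_in, hi = 0.45 * fs_out, order = 8)
  n_out <- max(1L, round(n * fs_out / fs_in))
  t_in <- (seq_len(n) - 1) / fs_in
  t_out <- (seq_len(n_out) - 1) / fs_out
  stats::approx(t_in, x, xout = t_out, rule = 2)$y
}

# Analytic-signal magnitude (Hilbert envelope) via the FFT.
analytic_envelope <- function(x) {
  n <- length(x)
  if (n < 2) return(abs(x))
  X <- stats::fft(x)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Column-wise z-score; constant columns are left at zero and flagged.
zscore_cols <- function(m) {
  m <- as.matrix(m)
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  flat <- sdv < .Machine$double.eps^0.5
  out <- sweep(m, 2, mu)
  out[, !flat] <- sweep(out[, !flat, drop = FALSE], 2, sdv[!flat], "/")
  out[, flat] <- 0
  attr(out, "constant_columns") <- which(flat)
  out
}

ms_to_samples <- function(ms, rate) {
  s <- ms * rate / 1000
  if (any(abs(s - round(s)) > 1e-6)) {
    stop("lag/padding of ", paste(ms[abs(s - round(s)) > 1e-6], collapse = ", "),
         " ms is not a whole number of samples at ", rate, " Hz")
  }
  as.integer(round(s))
}
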