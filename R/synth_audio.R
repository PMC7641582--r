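## Parametric synthesis of monosyllabic word-like audio. Words are built as a
## pitched harmonic source shaped by time-varying formant resonances
## (short-time spectral shaping with overlap-add), with consonant segments
## realised as shaped noise (fricatives), burst + gap (plosives) or a
## low-passed murmur (nasals). This gives controllable spectrotemporal
## content for the vocoder and modulation filterbank while remaining fully
## deterministic given (word_id, seed).

# Formant targets (F1, F2, F3 in Hz) for the monophthong vowels we synthesise.
vowel_formants <- list(
  iy = c(270, 2290, 3010), ih = c(390, 1990, 2550), eh = c(530, 1840, 2480),
  ae = c(660, 1720, 2410), aa = c(730, 1090, 2440), ah = c(640, 1190, 2390),
  ao = c(570, 840, 2410), uh = c(440, 1020, 2240), uw = c(300, 870, 2240)
)

onset_consonants <- c("t", "k", "p", "s", "sh", "f", "m", "n", "l", "d", "b", "g")
coda_consonants <- c("t", "k", "n", "s", "l", "d", "m", "p", "z", "f")

#' Synthesize a monosyllabic word-like waveform
#'
#' Generates a single-syllable (consonant-vowel-consonant) sound: a pitched
#' harmonic source shaped by three time-varying formant resonances, an onset
#' consonant (noise burst, fricative noise, or nasal murmur), and a syllable
#' amplitude envelope. The phoneme identity and formant trajectory are drawn
#' deterministically from `word_id` and `seed`, so the same word is always
#' the same waveform and different words differ.
#'
#' @param word_id word identifier (any string).
#' @param duration_ms total duration; if `NULL`, drawn from the configured
#'   range (default 372-903 ms, mean 591, SD 78).
#' @param rate sampling rate in Hz (>= 8000; default 44100).
#' @param seed integer seed shared across the word set.
#' @param duration_range admissible duration range in ms.
#' @return An `audio_waveform`: list with `samples`, `rate`, `word_id`, and a
#'   `segments` tibble (`phoneme`, `onset_ms`) describing the synthetic
#'   phoneme segmentation.
#' @examples
#' w <- synth_word_audio("w001", seed = 1)
#' w$segments
#' @export
synth_word_audio <- function(word_id, duration_ms = NULL, rate = 44100,
                             seed = 1, duration_range = c(372, 903)) {
  if (rate < 8000) {
    stop("rate must be at least 8000 Hz to cover the 5 kHz vocoder band")
  }
  with_seed(hash_seed("audio", word_id, seed = seed), {
    if (is.null(duration_ms)) {
      repeat {
        duration_ms <- stats::rnorm(1, 591, 78)
        if (duration_ms >= duration_range[1] && duration_ms <= duration_range[2])
          break
      }
    }
    if (duration_ms < duration_range[1] || duration_ms > duration_range[2]) {
      stop("duration_ms outside the configured range [",
           duration_range[1], ", ", duration_range[2], "] ms")
    }
    n <- round(duration_ms * rate / 1000)
    t <- (seq_len(n) - 1) / rate

    onset <- sample(onset_consonants, 1)
    vowel <- sample(names(vowel_formants), 1)
    coda <- sample(coda_consonants, 1)

    # Segment boundaries: onset consonant ~18%, vowel ~57%, coda ~25%.
    b1 <- round(n * stats::runif(1, 0.14, 0.22))
    b2 <- round(n * stats::runif(1, 0.68, 0.80))

    # Voiced source: harmonics of a declining f0 with slight vibrato.
    f0 <- stats::runif(1, 105, 135) * exp(-0.15 * t / max(t)) *
      (1 + 0.01 * sin(2 * pi * 5 * t))
    phase <- 2 * pi * cumsum(f0) / rate
    nharm <- floor(5000 / max(f0))
    src <- rowSums(vapply(seq_len(nharm),
                          function(h) sin(h * phase) / h, numeric(n)))

    # Formant tracks: glide from a consonant locus into the vowel target and
    # out toward the coda locus.
    vf <- vowel_formants[[vowel]]
    locus_on <- vf * stats::runif(3, 0.75, 1.25)
    locus_off <- vf * stats::runif(3, 0.8, 1.2)
    tracks <- sapply(1:3, function(j) {
      stats::approx(x = c(1, b1, round((b1 + b2) / 2), b2, n),
                    y = c(locus_on[j], (locus_on[j] + vf[j]) / 2, vf[j],
                          vf[j], (vf[j] + locus_off[j]) / 2),
                    xout = seq_len(n))$y
    })
    voiced <- formant_shape(src, rate, tracks)

    out <- voiced
    out[seq_len(b1)] <- 0.15 * voiced[seq_len(b1)]
    out <- mix_consonant(out, seq_len(b1), onset, rate, edge = "onset")
    out <- mix_consonant(out, seq(b2, n), coda, rate, edge = "coda")

    # Syllable envelope: raised-cosine attack and release.
    env <- rep(1, n)
    na <- min(n, round(0.025 * rate))
    nr <- min(n, round(0.060 * rate))
    env[seq_len(na)] <- 0.5 * (1 - cos(pi * seq_len(na) / na))
    env[(n - nr + 1):n] <- 0.5 * (1 + cos(pi * seq_len(nr) / nr))
    out <- out * env
    out <- out / rms(out) * 0.05

    seg <- tibble::tibble(
      phoneme = c(onset, vowel, coda),
      onset_ms = c(0, b1, b2) / rate * 1000
    )
    audio_waveform(out, rate, word_id = word_id, segments = seg)
  })
}

# Short-time spectral shaping by Lorentzian formant resonances whose centre
# frequencies vary over time (overlap-add with a Hann window).
formant_shape <- function(x, rate, tracks, bw = c(90, 120, 160)) {
  n <- length(x)
  win <- 2048L
  if (n < win) win <- 2^floor(log2(n))
  hop <- win %/% 2L
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(win) / win)
  f <- fft_bin_freqs(win, rate)
  out <- numeric(n + win)
  starts <- seq(1L, n, by = hop)
  for (s in starts) {
    idx <- s:min(s + win - 1L, n)
    frame <- numeric(win)
    frame[seq_along(idx)] <- x[idx] * w[seq_along(idx)]
    mid <- idx[ceiling(length(idx) / 2)]
    gain <- 0.03
    for (j in 1:3) {
      gain <- gain + 1 / (1 + ((f - tracks[mid, j]) / bw[j])^2)
    }
    shaped <- Re(stats::fft(stats::fft(frame) * gain, inverse = TRUE)) / win
    out[s:(s + win - 1L)] <- out[s:(s + win - 1L)] + shaped
  }
  out[seq_len(n)]
}

# Overlay a consonant realisation on a span of the waveform.
mix_consonant <- function(x, idx, phoneme, rate, edge) {
  n <- length(idx)
  if (n < 8) return(x)
  noise <- stats::rnorm(n)
  shaped <- switch(phoneme,
    s = , z = fft_filter(noise, rate, lo = 3200, hi = min(7800, rate / 2 - 1)),
    sh = fft_filter(noise, rate, lo = 1800, hi = 4800),
    f = fft_filter(noise, rate, lo = 1200, hi = min(7000, rate / 2 - 1)),
    t = , d = burst(noise, rate, n, lo = 2500, hi = 4800),
    k = , g = burst(noise, rate, n, lo = 1200, hi = 2600),
    p = , b = burst(noise, rate, n, lo = 400, hi = 1500),
    m = , n = , ng = NULL,
    NULL
  )
  if (is.null(shaped)) {
    # Nasals/liquids: keep the voiced path, low-passed murmur.
    x[idx] <- fft_filter(x[idx], rate, hi = 900) * 1.6
    return(x)
  }
  ramp <- if (edge == "onset") seq(1, 0.1, length.out = n) else
    seq(0.1, 1, length.out = n)
  x[idx] <- x[idx] * 0.25 + shaped / max(rms(shaped), 1e-12) *
    0.035 * ramp
  x
}

# Plosive-like burst: silence (closure) then a short band-limited noise burst.
burst <- function(noise, rate, n, lo, hi) {
  out <- numeric(n)
  nb <- max(8L, min(n, round(0.015 * rate)))
  start <- max(1L, n - round(n * 0.45))
  seg <- fft_filter(noise[seq_len(nb)], rate, lo = lo, hi = min(hi, rate / 2 - 1))
  out[start:min(n, start + nb - 1L)] <- seg[seq_len(min(nb, n - start + 1L))]
  out
}

#' Synthesize a ripple-bearing word-like stimulus
#'
#' A word-length stimulus whose spectral detail is concentrated at
#' intermediate spectrotemporal modulations: a flat bank of tone carriers
#' modulated by a drifting ripple with a (jittered) spectral modulation of
#' 1-2 cycles/octave and temporal modulation of 2-4 Hz, with an onset/offset
#' taper. Because a 24-channel Greenwood bank can represent these spectral
#' modulations while a 1-channel vocoder cannot, this stimulus set isolates
#' the vocoder-limited spectral detail of speech.
#'
#' @param word_id identifier (also seeds the carrier phases).
#' @param scale_cpo,rate_hz ripple modulation (defaults 1.4 cycles/octave and
#'   3 Hz -- intermediate cells of the 5 x 5 modulation grid).
#' @param jitter relative jitter applied to `scale_cpo`/`rate_hz` per word
#'   (default 0: every word carries the same ripple, so paired contrasts
#'   across the set are maximally sensitive).
#' @param duration_ms duration (default 600).
#' @param rate sampling rate in Hz.
#' @param seed integer seed shared across the set.
#' @return an `audio_waveform`.
#' @export
synth_ripple_word <- function(word_id, scale_cpo = 1.4, rate_hz = 3,
                              jitter = 0, duration_ms = 600, rate = 44100,
                              seed = 1) {
  with_seed(hash_seed("rippleword", word_id, seed = seed), {
    if (jitter > 0) {
      scale_cpo <- scale_cpo * stats::runif(1, 1 - jitter, 1 + jitter)
      rate_hz <- rate_hz * stats::runif(1, 1 - jitter, 1 + jitter)
    }
    rip <- synth_ripple(scale_cpo, rate_hz, duration_ms = duration_ms,
                        rate = rate, f_range = c(100, 5000),
                        seed = stats::runif(1, 1, 1e6))
    n <- length(rip$samples)
    env <- rep(1, n)
    na <- min(n %/% 3, round(0.05 * rate))
    env[seq_len(na)] <- seq(0, 1, length.out = na)
    env[(n - na + 1):n] <- seq(1, 0, length.out = na)
    audio_waveform(rip$samples * env, rate, word_id = word_id)
  })
}

#' Construct an audio waveform object
#' @param samples numeric vector of samples (arbitrary units).
#' @param rate sampling rate in Hz.
#' @param word_id optional identifier.
#' @param segments optional tibble of (phoneme, onset_ms).
#' @return An object of class `audio_waveform`.
#' @export
audio_waveform <- function(samples, rate, word_id = NULL, segments = NULL) {
  stopifnot(all(is.finite(samples)), rate > 0)
  structure(list(samples = as.numeric(samples), rate = rate,
                 word_id = word_id, segments = segments),
            class = "audio_waveform")
}

#' @export
print.audio_waveform <- function(x, ...) {
  cat(sprintf("<audio_waveform%s: %.1f ms @ %g Hz, RMS %.4g>\n",
              if (is.null(x$word_id)) "" else paste0(" ", x$word_id),
              duration_ms(x), x$rate, rms(x$samples)))
  invisible(x)
}

#' Duration of a waveform in milliseconds
#' @param audio an `audio_waveform`.
#' @export
duration_ms <- function(audio) length(audio$samples) / audio$rate * 1000

#' Synthesize the word set for a design
#'
#' @param design tibble from [make_design()].
#' @param rate sampling rate in Hz.
#' @param seed integer seed.
#' @return Named list of `audio_waveform`s, one per unique `word_id`.
#' @export
synth_word_set <- function(design, rate = 44100, seed = 1) {
  ids <- unique(design$word_id)
  out <- lapply(ids, synth_word_audio, rate = rate, seed = seed)
  names(out) <- ids
  out
}
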