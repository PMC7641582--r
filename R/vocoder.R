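## Noise-vocoding: channel envelopes of speech are superimposed on
## band-limited white-noise carriers, removing spectral detail while
## preserving slow temporal structure. Channel boundaries are equally spaced
## on the Greenwood cochlear-position axis between 70 and 5000 Hz.

greenwood_defaults <- list(A = 165.4, a = 2.1, k = 0.88)

# Greenwood map between proportional cochlear position x in [0, 1] and
# characteristic frequency f: f = A (10^(a x) - k).
greenwood_freq <- function(x, p = greenwood_defaults) p$A * (10^(p$a * x) - p$k)
greenwood_pos <- function(f, p = greenwood_defaults) log10(f / p$A + p$k) / p$a

#' Greenwood-spaced vocoder channel bank
#'
#' Channel boundaries are equally spaced on the Greenwood cochlear-position
#' axis between `lo` and `hi`; channel centres sit at the midpoint position
#' of each channel (override with `centers_override` to impose a published
#' centre list).
#'
#' @param n_channels number of channels (>= 1).
#' @param lo,hi outer band edges in Hz (defaults 70 and 5000).
#' @param params Greenwood parameters (list with `A`, `a`, `k`); defaults to
#'   the standard human fit A = 165.4, a = 2.1, k = 0.88.
#' @param centers_override optional explicit centre frequencies.
#' @return A `channel_bank`: list with `n_channels`, `edges` (length n+1),
#'   `centers`, `lo`, `hi`.
#' @examples
#' greenwood_bank(3)$edges
#' @export
greenwood_bank <- function(n_channels, lo = 70, hi = 5000,
                           params = greenwood_defaults,
                           centers_override = NULL) {
  stopifnot(n_channels >= 1, lo < hi, lo > 0)
  x <- seq(greenwood_pos(lo, params), greenwood_pos(hi, params),
           length.out = n_channels + 1)
  edges <- greenwood_freq(x, params)
  edges[1] <- lo; edges[n_channels + 1] <- hi
  centers <- greenwood_freq((x[-1] + x[-(n_channels + 1)]) / 2, params)
  if (!is.null(centers_override)) {
    stopifnot(length(centers_override) == n_channels)
    centers <- centers_override
  }
  structure(list(n_channels = as.integer(n_channels), edges = edges,
                 centers = centers, lo = lo, hi = hi),
            class = "channel_bank")
}

#' Extract a channel's amplitude envelope
#'
#' Half-wave rectification followed by a second-order zero-phase low-pass
#' filter (default cut-off 30 Hz).
#'
#' @param band_signal numeric vector (a band-limited signal) or an
#'   `audio_waveform`.
#' @param rate sampling rate in Hz (ignored when `band_signal` is an
#'   `audio_waveform`).
#' @param cutoff low-pass cut-off in Hz.
#' @return numeric envelope, same length as the input.
#' @export
extract_envelope <- function(band_signal, rate = NULL, cutoff = 30) {
  if (inherits(band_signal, "audio_waveform")) {
    rate <- band_signal$rate
    band_signal <- band_signal$samples
  }
  stopifnot(!is.null(rate), all(is.finite(band_signal)))
  if (cutoff >= rate / 2) stop("cutoff must be below the Nyquist frequency")
  fft_filter(pmax(band_signal, 0), rate, hi = cutoff, order = 2)
}

#' Noise-vocode a waveform
#'
#' For each channel of a Greenwood-spaced bank: band-pass the input, extract
#' its envelope, modulate band-passed white noise with the envelope,
#' re-band-pass, and sum across channels. The output is scaled to a reference
#' RMS (by default the input RMS). The carrier noise is drawn once per
#' channel from `seed`, so the same seed reproduces the output exactly while
#' different seeds change only the carrier, not the channel envelopes.
#'
#' @param audio an `audio_waveform` with `rate >= 2 * hi`.
#' @param n_channels number of vocoder channels (1 or more).
#' @param seed integer seed for the noise carriers.
#' @param bank optional `channel_bank` (defaults to `greenwood_bank(n_channels)`).
#' @param ref_rms reference output RMS; default = input RMS.
#' @return An `audio_waveform` of the same duration.
#' @export
vocode <- function(audio, n_channels, seed = 1, bank = NULL, ref_rms = NULL) {
  stopifnot(inherits(audio, "audio_waveform"))
  if (n_channels < 1) stop("n_channels must be at least 1")
  if (is.null(bank)) bank <- greenwood_bank(n_channels)
  if (audio$rate < 2 * bank$hi) {
    stop("audio rate must be at least twice the top band edge (",
         2 * bank$hi, " Hz)")
  }
  x <- audio$samples
  n <- length(x)
  if (is.null(ref_rms)) ref_rms <- rms(x)
  out <- with_seed(hash_seed("vocode", audio$word_id, n_channels, seed = seed), {
    acc <- numeric(n)
    for (ch in seq_len(bank$n_channels)) {
      lo <- bank$edges[ch]; hi <- bank$edges[ch + 1]
      band <- fft_filter(x, audio$rate, lo = lo, hi = hi, order = 4)
      env <- extract_envelope(band, audio$rate)
      carrier <- fft_filter(stats::rnorm(n), audio$rate, lo = lo, hi = hi,
                            order = 4)
      acc <- acc + fft_filter(carrier * env, audio$rate, lo = lo, hi = hi,
                              order = 4)
    }
    acc
  })
  out <- out / max(rms(out), 1e-15) * ref_rms
  audio_waveform(out, audio$rate, word_id = audio$word_id,
                 segments = audio$segments)
}

#' Equalize RMS across a set of waveforms
#'
#' Scales every waveform to a common target RMS, as is standard when
#' preparing a stimulus set.
#'
#' @param audios list of `audio_waveform`s.
#' @param target target RMS; default is the mean RMS of the inputs.
#' @return list of rescaled `audio_waveform`s.
#' @export
rms_equalize <- function(audios, target = NULL) {
  r <- vapply(audios, function(a) rms(a$samples), numeric(1))
  if (any(r < .Machine$double.eps)) {
    stop("cannot RMS-equalize a silent waveform")
  }
  if (is.null(target)) target <- mean(r)
  lapply(audios, function(a) {
    audio_waveform(a$samples / rms(a$samples) * target, a$rate,
                   word_id = a$word_id, segments = a$segments)
  })
}
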