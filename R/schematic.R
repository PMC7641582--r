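## Schematic simulation of the two coding schemes. Written words are coarse
## binary pixel glyphs; sensory detail is manipulated by local mean
## filtering; representations are either the sharpened (input x prediction)
## pattern or the prediction-error (input - prediction) pattern, and their
## fidelity is the squared correlation with a clean rendering of the heard
## word.

# 7 x 5 binary glyphs for the letters used by the built-in word fixtures.
glyphs <- list(
  a = c("01110","10001","10001","11111","10001","10001","10001"),
  c = c("01110","10001","10000","10000","10000","10001","01110"),
  f = c("11111","10000","10000","11110","10000","10000","10000"),
  l = c("10000","10000","10000","10000","10000","10001","11111"),
  s = c("01111","10000","10000","01110","00001","00001","11110"),
  t = c("11111","00100","00100","00100","00100","00100","00100"),
  y = c("10001","10001","01010","00100","00100","00100","00100")
)

#' Rasterize a word as a binary pixel pattern
#'
#' @param word a string using the letters of the built-in glyph set
#'   (`a c f l s t y`, covering the "clay"/"fast" fixture), or a ready binary
#'   matrix (returned unchanged).
#' @param scale rendering resolution: each glyph cell becomes a `scale` x
#'   `scale` pixel block (default 3, so the local-mean degradation kernels
#'   blur within letter strokes rather than across whole letters).
#' @return binary matrix (`7 * scale` rows).
#' @export
word_pattern <- function(word, scale = 3) {
  if (is.matrix(word)) {
    stopifnot(all(word %in% c(0, 1)))
    return(word)
  }
  letters_in <- strsplit(word, "")[[1]]
  unknown <- setdiff(letters_in, names(glyphs))
  if (length(unknown)) stop("no glyph for letter(s): ",
                            paste(unknown, collapse = ", "))
  cols <- lapply(letters_in, function(ch) {
    g <- glyphs[[ch]]
    m <- t(vapply(g, function(row) as.numeric(strsplit(row, "")[[1]]),
                  numeric(5)))
    cbind(m, 0)
  })
  out <- do.call(cbind, cols)
  out <- out[, -ncol(out), drop = FALSE]
  kronecker(out, matrix(1, scale, scale))
}

# Local mean filter with a given kernel, periodic boundary handling (keeps
# the total sum exactly preserved).
mean_filter <- function(m, kernel) {
  kernel <- kernel / sum(kernel)
  nr <- nrow(m); nc <- ncol(m)
  kr <- nrow(kernel); kc <- ncol(kernel)
  out <- matrix(0, nr, nc)
  off_r <- seq_len(kr) - (kr + 1) %/% 2
  off_c <- seq_len(kc) - (kc + 1) %/% 2
  for (i in seq_len(kr)) for (j in seq_len(kc)) {
    if (kernel[i, j] == 0) next
    shifted <- m[(seq_len(nr) - 1 + off_r[i]) %% nr + 1,
                 (seq_len(nc) - 1 + off_c[j]) %% nc + 1, drop = FALSE]
    out <- out + kernel[i, j] * shifted
  }
  out
}

#' Degrade a pixel pattern to a sensory-detail level
#'
#' `"low"` averages over the eight surrounding pixels (3 x 3 neighbourhood
#' excluding the centre), `"medium"` over four local pixels (2 x 2 kernel),
#' `"high"` leaves the pattern unfiltered.
#'
#' @param pattern 2D numeric matrix.
#' @param level `"low"`, `"medium"` or `"high"`.
#' @return filtered matrix of the same size.
#' @export
degrade <- function(pattern, level = c("high", "medium", "low")) {
  level <- match.arg(level)
  stopifnot(is.matrix(pattern))
  switch(level,
         high = pattern,
         medium = mean_filter(pattern, matrix(1, 2, 2)),
         low = mean_filter(pattern, matrix(c(1, 1, 1, 1, 0, 1, 1, 1, 1), 3)))
}

#' Add uniform noise and normalize to unit sum
#'
#' Uniform noise with mean 0 and the requested standard deviation (support
#' `+/- sd * sqrt(3)`) is added, then the pattern is rescaled to sum to one.
#' If the post-noise sum is not positive the noise is resampled (count kept
#' in the `"resampled"` attribute).
#'
#' @param pattern 2D numeric matrix.
#' @param noise_sd noise standard deviation (default 0.5).
#' @param seed integer seed.
#' @return normalized matrix summing to 1.
#' @export
noise_and_normalize <- function(pattern, noise_sd = 0.5, seed = 1) {
  stopifnot(is.matrix(pattern), noise_sd >= 0)
  half <- noise_sd * sqrt(3)
  with_seed(hash_seed("noisepat", seed = seed), {
    tries <- 0
    repeat {
      noisy <- pattern + matrix(stats::runif(length(pattern), -half, half),
                                nrow(pattern))
      s <- sum(noisy)
      if (s > 0) break
      tries <- tries + 1
      if (tries > 1000) stop("post-noise sum not positive after 1000 resamples")
    }
    out <- noisy / s
    attr(out, "resampled") <- tries
    out
  })
}

#' Sharpened-signal representation
#'
#' Elementwise product of input and prediction, renormalized to sum to one.
#' @param input,prediction matrices of the same shape.
#' @return normalized matrix.
#' @export
sharpened <- function(input, prediction) {
  stopifnot(identical(dim(input), dim(prediction)))
  prod <- input * prediction
  s <- sum(prod)
  if (abs(s) < .Machine$double.eps) stop("degenerate product pattern (sum 0)")
  prod / s
}

#' Prediction-error representation
#'
#' Input minus prediction, unnormalized.
#' @inheritParams sharpened
#' @return difference matrix.
#' @export
prediction_error <- function(input, prediction) {
  stopifnot(identical(dim(input), dim(prediction)))
  input - prediction
}

#' Representational fidelity (squared Pearson correlation)
#'
#' @param representation matrix.
#' @param clean_target clean (noise-free) pattern of the heard word.
#' @return R-squared over pixels.
#' @export
fidelity <- function(representation, clean_target) {
  stopifnot(identical(dim(representation), dim(clean_target)))
  stats::cor(as.vector(representation), as.vector(clean_target))^2
}

#' Total prediction-error magnitude
#'
#' Sum of absolute prediction error over pixels.
#' @param pe_pattern prediction-error matrix.
#' @return non-negative scalar.
#' @export
pe_magnitude <- function(pe_pattern) sum(abs(pe_pattern))

#' Run the full schematic simulation grid
#'
#' Crosses prior (Match: prediction = the heard word; Mismatch: prediction =
#' the other word) with sensory-detail level and coding scheme over `n_reps`
#' noise draws. Fidelity is always computed against a clean rendering of the
#' heard word; total |prediction error| is recorded for the PE scheme.
#'
#' @param heard,other the heard and the mismatching word (strings or binary
#'   matrices; defaults `"clay"` and `"fast"`).
#' @param levels detail levels to simulate.
#' @param n_reps repetitions (noise draws) per cell.
#' @param noise_sd uniform noise SD.
#' @param seed integer seed.
#' @return tibble with `rep`, `prior`, `level`, `scheme`, `fidelity`,
#'   `pe_abs` (NA for the sharpened scheme).
#' @export
run_schematic_grid <- function(heard = "clay", other = "fast",
                               levels = c("low", "medium", "high"),
                               n_reps = 100, noise_sd = 0.5, seed = 1) {
  stopifnot(n_reps >= 1)
  clean <- word_pattern(heard)
  pats <- list(Match = word_pattern(heard), Mismatch = word_pattern(other))
  rows <- vector("list", 0)
  k <- 0
  for (rep_i in seq_len(n_reps)) {
    for (prior in c("Match", "Mismatch")) {
      pred <- noise_and_normalize(pats[[prior]], noise_sd,
                                  seed = hash_seed("pred", rep_i, prior,
                                                   seed = seed))
      for (level in levels) {
        inp <- noise_and_normalize(degrade(clean, level), noise_sd,
                                   seed = hash_seed("inp", rep_i, prior, level,
                                                    seed = seed))
        pe <- prediction_error(inp, pred)
        k <- k + 1
        rows[[k]] <- tibble::tibble(
          rep = rep_i, prior = prior, level = level,
          scheme = c("sharpened", "prediction_error"),
          fidelity = c(fidelity(sharpened(inp, pred), clean),
                       fidelity(pe, clean)),
          pe_abs = c(NA_real_, pe_magnitude(pe)))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$level <- factor(out$level, levels = c("low", "medium", "high"))
  out
}
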