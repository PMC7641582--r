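## Stimulus acoustics: spectrotemporal modulation content of the word set,
## its dependence on the number of vocoder channels, and between-word
## distances per modulation cell.

grid_template <- function(axes = modulation_axes()) {
  matrix(0, 5, 5, dimnames = list(paste0(axes$spectral_mods, "cpo"),
                                  paste0(axes$temporal_mods, "Hz")))
}

# 25-column STM feature matrix -> 5 x 5 grid of time-means.
stm_time_mean_grid <- function(stm_values, axes = modulation_axes()) {
  g <- grid_template(axes)
  for (si in 1:5) for (ti in 1:5) {
    g[si, ti] <- mean(stm_values[, stm_cell_index(si, ti)])
  }
  g
}

#' Spectrotemporal modulation magnitude grids for a word set
#'
#' Vocode each word with `n_channels` (or leave clear when `NULL`), compute
#' its spectrotemporal modulation feature space, and take the time-mean of
#' the (non-z-scored) magnitude per modulation cell.
#'
#' @param words list of clear `audio_waveform`s.
#' @param n_channels vocoder channels, or `NULL` for clear speech.
#' @param seed seed for the vocoder noise carriers.
#' @param axes modulation axes.
#' @return words x 5 x 5 array (word, spectral modulation, temporal
#'   modulation).
#' @export
modulation_magnitude <- function(words, n_channels = NULL, seed = 1,
                                 axes = modulation_axes()) {
  grids <- lapply(words, function(w) {
    a <- if (is.null(n_channels)) w else vocode(w, n_channels, seed = seed)
    stm_time_mean_grid(stm_feature(a, axes = axes)$values, axes)
  })
  out <- array(0, c(length(words), 5, 5),
               dimnames = c(list(names(words)), dimnames(grid_template(axes))))
  for (i in seq_along(grids)) out[i, , ] <- grids[[i]]
  out
}

#' Mean between-word Euclidean distance per modulation cell
#'
#' For each modulation cell, the Euclidean distance between the two words'
#' cell time series (zero-padded to the longest word) is computed for every
#' word pair and averaged over the `N(N-1)/2` pairs.
#'
#' @param words list of clear `audio_waveform`s (at least 2).
#' @param n_channels vocoder channels, or `NULL` for clear speech.
#' @param seed vocoder seed.
#' @param axes modulation axes.
#' @return 5 x 5 matrix of mean distances.
#' @export
between_word_distance <- function(words, n_channels = NULL, seed = 1,
                                  axes = modulation_axes()) {
  if (length(words) < 2) stop("need at least 2 words")
  stms <- lapply(words, function(w) {
    a <- if (is.null(n_channels)) w else vocode(w, n_channels, seed = seed)
    stm_feature(a, axes = axes)$values
  })
  n_max <- max(vapply(stms, nrow, 1L))
  stms <- lapply(stms, function(v) rbind(v, matrix(0, n_max - nrow(v), ncol(v))))
  g <- grid_template(axes)
  pairs <- utils::combn(length(words), 2)
  for (si in 1:5) for (ti in 1:5) {
    k <- stm_cell_index(si, ti)
    d <- apply(pairs, 2, function(pr)
      sqrt(sum((stms[[pr[1]]][, k] - stms[[pr[2]]][, k])^2)))
    g[si, ti] <- mean(d)
  }
  g
}

#' Per-cell contrast of modulation magnitude between two vocoding conditions
#'
#' Paired t-test over words per modulation cell (e.g. 24 channels versus 1
#' channel), with Benjamini-Hochberg FDR across the 25 cells.
#'
#' @param grids_a,grids_b words x 5 x 5 arrays from [modulation_magnitude()]
#'   for the same word set under two conditions.
#' @param q FDR level.
#' @return list of 5 x 5 matrices `t`, `p`, `reject` plus `mean_diff`.
#' @export
channel_contrast <- function(grids_a, grids_b, q = 0.05) {
  stopifnot(identical(dim(grids_a), dim(grids_b)), dim(grids_a)[1] >= 2)
  tg <- grid_template(); pg <- grid_template(); md <- grid_template()
  for (si in 1:5) for (ti in 1:5) {
    a <- grids_a[, si, ti]; b <- grids_b[, si, ti]
    md[si, ti] <- mean(a - b)
    if (stats::sd(a - b) < .Machine$double.eps) {
      tg[si, ti] <- 0; pg[si, ti] <- 1
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
      tg[si, ti] <- unname(tt$statistic)
      pg[si, ti] <- tt$p.value
    }
  }
  adj <- fdr_bh(as.vector(pg), q)
  reject <- matrix(adj$reject, 5, 5, dimnames = dimnames(tg))
  list(t = tg, p = pg, p_fdr = matrix(adj$p_adj, 5, 5, dimnames = dimnames(tg)),
       reject = reject, mean_diff = md)
}

#' Write a 5 x 5 modulation grid as labelled CSV
#' @param grid 5 x 5 matrix.
#' @param path output path.
#' @export
write_grid <- function(grid, path) {
  df <- data.frame(spectral_mod = rownames(grid), grid, check.names = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}
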