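## Articulatory phonetic feature space: 13 binary features (voicing, place,
## manner, vowel backness) held between successive phoneme onsets. Diphthongs
## and affricates carry the mean of their component phonemes' feature
## vectors. The phoneme-to-feature map ships as an editable CSV.

PHONETIC_FEATURES <- c("voiced", "unvoiced", "bilabial", "labiodental_dental",
                       "alveolar", "velar", "plosive", "nasal", "fricative",
                       "liquid", "front", "central", "back")

#' Load the phoneme-to-feature map
#'
#' @param path CSV path; defaults to the map shipped with the package.
#'   Columns: `phoneme`, `components` (space-separated component phonemes for
#'   diphthongs/affricates, empty otherwise), then the 13 feature columns.
#' @return named list mapping each phoneme to its length-13 feature vector
#'   (component phonemes averaged).
#' @export
read_phoneme_map <- function(path = system.file("extdata",
                                                "phoneme_features.csv",
                                                package = "stmtrf")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(PHONETIC_FEATURES %in% names(raw)))
  base <- raw[is.na(raw$components) | raw$components == "", ]
  map <- stats::setNames(
    lapply(seq_len(nrow(base)), function(i) {
      stats::setNames(as.numeric(base[i, PHONETIC_FEATURES]), PHONETIC_FEATURES)
    }),
    base$phoneme)
  compound <- raw[!(is.na(raw$components) | raw$components == ""), ]
  for (i in seq_len(nrow(compound))) {
    parts <- strsplit(compound$components[i], " +")[[1]]
    missing <- setdiff(parts, names(map))
    if (length(missing)) {
      stop("component phoneme(s) not in map: ", paste(missing, collapse = ", "))
    }
    map[[compound$phoneme[i]]] <- Reduce(`+`, map[parts]) / length(parts)
  }
  map
}

#' Phonetic feature space (13 features)
#'
#' Between each phoneme onset and the next (or the word offset), the
#' phoneme's feature values fill the corresponding rows; all other features
#' are zero. Phonetic features are categorical and are not z-scored by
#' [prepare()].
#'
#' @param segmentation tibble/data.frame with columns `phoneme` and
#'   `onset_ms` (strictly increasing, within the word).
#' @param word_duration_ms word duration in ms.
#' @param rate_out sampling rate (default 80 Hz).
#' @param map phoneme-to-feature map from [read_phoneme_map()].
#' @return `feature_space` with 13 columns, `acoustic = FALSE`.
#' @export
phonetic_feature <- function(segmentation, word_duration_ms,
                             rate_out = NEURAL_RATE,
                             map = read_phoneme_map()) {
  seg <- as.data.frame(segmentation)
  stopifnot(all(c("phoneme", "onset_ms") %in% names(seg)))
  if (is.unsorted(seg$onset_ms, strictly = TRUE)) {
    stop("phoneme onsets must be strictly increasing")
  }
  if (any(seg$onset_ms < 0) || any(seg$onset_ms >= word_duration_ms)) {
    stop("phoneme onsets must lie within the word duration")
  }
  unknown <- setdiff(seg$phoneme, names(map))
  if (length(unknown)) {
    stop("unknown phoneme label(s): ", paste(unique(unknown), collapse = ", "))
  }
  n <- max(1L, round(word_duration_ms / 1000 * rate_out))
  t_ms <- (seq_len(n) - 1) / rate_out * 1000
  v <- matrix(0, n, length(PHONETIC_FEATURES),
              dimnames = list(NULL, PHONETIC_FEATURES))
  bounds <- c(seg$onset_ms, word_duration_ms)
  for (i in seq_len(nrow(seg))) {
    rows <- t_ms >= bounds[i] & t_ms < bounds[i + 1]
    v[rows, ] <- matrix(map[[seg$phoneme[i]]], sum(rows),
                        length(PHONETIC_FEATURES), byrow = TRUE)
  }
  feature_space(v, rate_out, "phonetic", feature_labels = PHONETIC_FEATURES,
                acoustic = FALSE)
}

#' Read phoneme segmentations from a tab-separated file
#'
#' Expected columns: `word_id`, `phoneme`, `onset_ms`.
#' @param path TSV path.
#' @return named list of per-word segmentation tibbles.
#' @export
read_segmentations <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("word_id", "phoneme", "onset_ms") %in% names(d)))
  lapply(split(d[, c("phoneme", "onset_ms")], d$word_id), tibble::as_tibble)
}
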