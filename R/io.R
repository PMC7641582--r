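## File formats: 16-bit PCM WAV audio and the plain-text epoch container (a
## directory bundle holding the trials x sensors x samples array, sensor
## table, per-trial feature stores and attributes, mirroring an HDF5-style
## layout with /data, /sensors and /features/<space_id> datasets).

#' Write a waveform as 16-bit PCM mono WAV
#'
#' Samples are scaled by `scale` (default: peak-normalized to 0.999) before
#' quantization.
#'
#' @param audio an `audio_waveform`.
#' @param path output path.
#' @param scale scaling applied before quantization, or `NULL` to
#'   peak-normalize.
#' @export
write_wav <- function(audio, path, scale = NULL) {
  stopifnot(inherits(audio, "audio_waveform"))
  x <- audio$samples
  if (is.null(scale)) scale <- 0.999 / max(abs(x), 1e-12)
  pcm <- as.integer(round(pmax(pmin(x * scale, 0.999969), -1) * 32768))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # PCM
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(audio$rate), con, size = 4, endian = "little")
  writeBin(as.integer(audio$rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")              # block align
  writeBin(16L, con, size = 2, endian = "little")             # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path WAV path.
#' @return an `audio_waveform` with samples in [-1, 1).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (riff != "RIFF") stop("not a RIFF/WAVE file")
  invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (wave != "WAVE") stop("not a RIFF/WAVE file")
  rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (!length(id) || nchar(id) < 4) stop("no data chunk found")
    sz <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), 2, size = 2, endian = "little")
      if (fmt[1] != 1 || fmt[2] != 1) stop("only 16-bit PCM mono supported")
      rate <- readBin(con, integer(), 1, size = 4, endian = "little")
      invisible(readBin(con, "raw", sz - 8))
    } else if (id == "data") {
      pcm <- readBin(con, integer(), sz / 2, size = 2, endian = "little",
                     signed = TRUE)
      return(audio_waveform(pcm / 32768, rate))
    } else {
      invisible(readBin(con, "raw", sz))
    }
  }
}

#' Write an epoched-neural bundle to a directory
#'
#' Layout: `attrs.json` (rate, t0_ms, dims, n_valid), `sensors.csv`,
#' `data.csv` (one row per trial x sensor, samples in columns), and
#' optionally `features/<space_id>.csv` stores written by
#' [write_feature_store()].
#'
#' @param epochs an `epoched_neural`.
#' @param dir output directory (created).
#' @export
write_epochs <- function(epochs, dir) {
  stopifnot(inherits(epochs, "epoched_neural"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(epochs$data)
  jsonlite::write_json(
    list(rate = epochs$rate, t0_ms = epochs$t0_ms, dims = d,
         n_valid = attr(epochs, "n_valid")),
    file.path(dir, "attrs.json"), auto_unbox = TRUE, digits = NA)
  data.table::fwrite(epochs$sensors, file.path(dir, "sensors.csv"))
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), ncol = d[3], byrow = TRUE)
  idx <- expand.grid(sensor = seq_len(d[2]), trial = seq_len(d[1]))
  out <- data.table::data.table(trial = idx$trial, sensor = idx$sensor)
  data.table::fwrite(cbind(out, data.table::as.data.table(flat)),
                     file.path(dir, "data.csv"))
  invisible(dir)
}

#' Read an epoched-neural bundle
#'
#' @param dir directory written by [write_epochs()].
#' @return an `epoched_neural`.
#' @export
read_epochs <- function(dir) {
  attrs <- jsonlite::read_json(file.path(dir, "attrs.json"),
                               simplifyVector = TRUE)
  sensors <- tibble::as_tibble(data.table::fread(file.path(dir, "sensors.csv"),
                                                 data.table = FALSE))
  flat <- data.table::fread(file.path(dir, "data.csv"), data.table = FALSE)
  d <- attrs$dims
  data <- array(0, d)
  vals <- as.matrix(flat[, -(1:2), drop = FALSE])
  for (r in seq_len(nrow(flat))) {
    data[flat$trial[r], flat$sensor[r], ] <- vals[r, ]
  }
  out <- epoched_neural(data, sensors, rate = attrs$rate, t0_ms = attrs$t0_ms)
  if (!is.null(attrs$n_valid)) attr(out, "n_valid") <- attrs$n_valid
  out
}

#' Write per-trial feature matrices into an epoch bundle
#'
#' @param features list of per-trial `feature_space`s (same space).
#' @param dir epoch bundle directory.
#' @return the store path, invisibly.
#' @export
write_feature_store <- function(features, dir) {
  space_id <- features[[1]]$space_id
  fdir <- file.path(dir, "features")
  dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(features), function(i) {
    v <- features[[i]]$values
    data.table::data.table(trial = i, sample = seq_len(nrow(v)), v)
  })
  meta <- features[[1]][c("rate", "space_id", "feature_labels", "acoustic",
                          "pad_pre_ms", "pad_post_ms")]
  jsonlite::write_json(meta, file.path(fdir, paste0(space_id, ".json")),
                       auto_unbox = TRUE, digits = NA)
  path <- file.path(fdir, paste0(space_id, ".csv"))
  data.table::fwrite(data.table::rbindlist(rows), path)
  invisible(path)
}

#' Read a per-trial feature store
#'
#' @param dir epoch bundle directory.
#' @param space_id feature-space id to read.
#' @return list of per-trial `feature_space`s.
#' @export
read_feature_store <- function(dir, space_id) {
  fdir <- file.path(dir, "features")
  meta <- jsonlite::read_json(file.path(fdir, paste0(space_id, ".json")),
                              simplifyVector = TRUE)
  flat <- data.table::fread(file.path(fdir, paste0(space_id, ".csv")),
                            data.table = FALSE)
  lapply(split(flat, flat$trial), function(df) {
    v <- as.matrix(df[order(df$sample), -(1:2), drop = FALSE])
    fs <- feature_space(v, meta$rate, meta$space_id,
                        feature_labels = meta$feature_labels,
                        acoustic = meta$acoustic)
    fs$pad_pre_ms <- meta$pad_pre_ms
    fs$pad_post_ms <- meta$pad_post_ms
    fs
  })
}
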