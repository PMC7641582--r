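#' Generate the factorial trial design
#'
#' Builds the 3 (sensory detail: 3/6/12 vocoder channels) x 2 (prior
#' knowledge: Match/Mismatch) design. Every spoken word occurs exactly once;
#' written words on Mismatch trials are a fixed-point-free permutation of the
#' Mismatch trials' spoken words, so every mismatching written word is heard
#' as a spoken word on another trial. Trials are distributed over presentation
#' blocks (cells spread as evenly as possible) and randomly ordered within
#' each block.
#'
#' @param n_per_cell trials per design cell (the original study used 78).
#' @param n_blocks number of presentation blocks (default 3).
#' @param seed integer seed; the table is reproducible given the seed.
#' @return A tibble with columns `trial_id`, `word_id`, `detail` (3/6/12),
#'   `prior` (`"Match"`/`"Mismatch"`), `block`, and `written_id` (the text
#'   shown before the spoken word).
#' @examples
#' d <- make_design(n_per_cell = 2, seed = 1)
#' table(d$detail, d$prior)
#' @export
make_design <- function(n_per_cell, n_blocks = 3, seed = 1) {
  if (!is.numeric(n_per_cell) || length(n_per_cell) != 1 || n_per_cell < 1) {
    stop("n_per_cell must be a positive integer")
  }
  n_per_cell <- as.integer(n_per_cell)
  n_blocks <- as.integer(n_blocks)
  n_trials <- 6L * n_per_cell
  with_seed(seed, {
    words <- sprintf("w%03d", seq_len(n_trials))
    cells <- expand.grid(detail = c(3L, 6L, 12L),
                         prior = c("Match", "Mismatch"),
                         stringsAsFactors = FALSE)
    df <- cells[rep(seq_len(6), each = n_per_cell), ]
    df$word_id <- sample(words)

    # Written text: Match trials repeat the spoken word; Mismatch trials get a
    # derangement of the Mismatch spoken words (no written word equals its own
    # spoken word).
    df$written_id <- df$word_id
    mm <- which(df$prior == "Mismatch")
    if (length(mm) >= 2) {
      df$written_id[mm] <- derangement_of(df$word_id[mm])
    }

    # Spread each cell's trials over blocks, then shuffle within block.
    blk <- integer(nrow(df))
    for (cell in split(seq_len(nrow(df)), paste(df$detail, df$prior))) {
      blk[cell] <- sample(rep_len(seq_len(n_blocks), length(cell)))
    }
    df$block <- blk
    ord <- order(df$block, sample(nrow(df)))
    df <- df[ord, ]
    df$trial_id <- seq_len(nrow(df))
    tibble::as_tibble(df[, c("trial_id", "word_id", "detail", "prior",
                             "block", "written_id")])
  })
}

# Fixed-point-free permutation by rejection sampling (expected ~e tries).
derangement_of <- function(x) {
  for (i in 1:1000) {
    p <- sample(x)
    if (all(p != x)) return(p)
  }
  stop("failed to find a derangement")
}

#' Write/read a design table as CSV
#' @param design tibble from [make_design()].
#' @param path file path.
#' @return `read_design` returns the design tibble.
#' @export
write_design <- function(design, path) {
  data.table::fwrite(design, path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- data.table::fread(path, data.table = FALSE)
  tibble::as_tibble(d)
}

# Canonical key for a design cell, used by condition-gain maps.
cell_key <- function(prior, detail) paste(prior, detail, sep = ":")
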