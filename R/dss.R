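## Denoising source separation: linear spatial components ordered by their
## consistency over trials, obtained from the generalized eigendecomposition
## of the trial-average covariance against the total covariance (with
## whitening and rank control).

#' Fit a DSS decomposition
#'
#' The biased covariance is that of the trial average; the baseline is the
#' sum of single-trial covariances (covariances are summed over whatever the
#' "sample" axis holds -- time points, or lag-by-feature weights when
#' denoising TRFs -- and over conditions if trials span conditions). The
#' total covariance is whitened with eigenvalue rank control, the averaged
#' covariance is diagonalized in the whitened space, and components are
#' ordered by the resulting consistency score.
#'
#' @param trials list of samples x sensors matrices (>= 2), or a trials x
#'   sensors x samples array / `epoched_neural`.
#' @param rank_tol relative eigenvalue threshold for whitening (default
#'   1e-10).
#' @return a `dss_decomposition`: `filters` (sensors x components),
#'   `patterns` (components x sensors), `scores` (descending consistency
#'   ratios).
#' @export
dss_fit <- function(trials, rank_tol = 1e-10) {
  trials <- as_trial_list(trials)
  n_tr <- length(trials)
  if (n_tr < 2) stop("DSS needs at least 2 trials")
  dims <- vapply(trials, dim, integer(2))
  stopifnot(all(dims[2, ] == dims[2, 1]), all(dims[1, ] == dims[1, 1]))

  center <- function(m) sweep(m, 2, colMeans(m))
  c0 <- Reduce(`+`, lapply(trials, function(m) crossprod(center(m))))
  avg <- Reduce(`+`, trials) / n_tr
  c1 <- crossprod(center(avg))

  e0 <- eigen(c0, symmetric = TRUE)
  keep <- e0$values > max(e0$values) * rank_tol
  if (!all(keep)) {
    warning("rank-deficient total covariance; reducing to ", sum(keep),
            " dimensions")
  }
  W <- e0$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e0$values[keep]), sum(keep))
  e1 <- eigen(crossprod(W, c1 %*% W), symmetric = TRUE)
  filters <- W %*% e1$vectors
  patterns <- MASS_ginv(filters)
  structure(list(filters = filters, patterns = patterns,
                 scores = e1$values, rank = sum(keep)),
            class = "dss_decomposition")
}

# Moore-Penrose pseudoinverse via SVD (avoids importing MASS for one call).
MASS_ginv <- function(m, tol = 1e-12) {
  s <- svd(m)
  keep <- s$d > max(s$d) * tol
  s$v[, keep, drop = FALSE] %*% diag(1 / s$d[keep], sum(keep)) %*%
    t(s$u[, keep, drop = FALSE])
}

as_trial_list <- function(trials) {
  if (inherits(trials, "epoched_neural")) {
    return(neural_trial_list(trials, zscore = FALSE))
  }
  if (is.array(trials) && length(dim(trials)) == 3) {
    return(lapply(seq_len(dim(trials)[1]), function(tr) t(trials[tr, , ])))
  }
  stopifnot(is.list(trials))
  lapply(trials, as.matrix)
}

#' Denoise trials by retaining the leading DSS components
#'
#' Projects each trial onto the first `n_keep` components and back into
#' sensor space.
#'
#' @param trials as in [dss_fit()].
#' @param decomposition a `dss_decomposition`.
#' @param n_keep components to retain (default 3).
#' @return list of denoised samples x sensors matrices.
#' @export
dss_denoise <- function(trials, decomposition, n_keep = 3) {
  trials <- as_trial_list(trials)
  n_keep <- min(n_keep, ncol(decomposition$filters))
  f <- decomposition$filters[, seq_len(n_keep), drop = FALSE]
  p <- decomposition$patterns[seq_len(n_keep), , drop = FALSE]
  lapply(trials, function(m) m %*% f %*% p)
}

#' RMS amplitude over a sensor subset
#'
#' @param avg samples x sensors matrix (e.g. the trial-averaged, denoised
#'   TRF).
#' @param sensors column indices or logical mask (e.g. left-hemisphere
#'   sensors); default all.
#' @return non-negative time series (length = samples).
#' @export
sensor_rms <- function(avg, sensors = seq_len(ncol(avg))) {
  avg <- as.matrix(avg)
  sub <- avg[, sensors, drop = FALSE]
  sqrt(rowMeans(sub^2))
}
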