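## Lagged linear (temporal response function) models: ridge and banded ridge
## closed-form fits, leave-one-trial-out cross-validation with per-trial
## weight averaging, lambda-mode selection.

#' Lag specification for TRF models
#'
#' @param fit_ms length-2 lag range used for fitting (default -100..300 ms).
#' @param predict_ms length-2 narrower lag range used when predicting
#'   (default 0..250 ms), to avoid edge artefacts at the extreme lags.
#' @param rate sampling rate in Hz (default 80).
#' @return a `lag_spec`: lag ranges plus the integer sample lags they imply.
#' @export
lag_spec <- function(fit_ms = c(-100, 300), predict_ms = c(0, 250),
                     rate = NEURAL_RATE) {
  stopifnot(fit_ms[1] <= predict_ms[1], fit_ms[2] >= predict_ms[2])
  fit <- ms_to_samples(fit_ms[1], rate):ms_to_samples(fit_ms[2], rate)
  pred <- ms_to_samples(predict_ms[1], rate):ms_to_samples(predict_ms[2], rate)
  structure(list(fit_ms = fit_ms, predict_ms = predict_ms, rate = rate,
                 fit_lags = fit, predict_lags = pred),
            class = "lag_spec")
}

#' Default ridge regularization grid
#'
#' 17 log2-equispaced values spanning 2^0 to 2^20.
#' @return numeric vector of length 17.
#' @export
default_lambda_grid <- function() 2^seq(0, 20, length.out = 17)

#' Build a lagged design matrix
#'
#' Column ordering is feature-major: all lags of feature 1, then all lags of
#' feature 2, and so on; within a feature, lags ascend. The column for lag
#' `l` holds `x[t - l]`; out-of-range samples are zero.
#'
#' @param x time x feature matrix (or a `feature_space`).
#' @param lags integer sample lags (or a `lag_spec`, whose `fit_lags` are
#'   used).
#' @return time x (features * n_lags) matrix.
#' @export
lag_matrix <- function(x, lags) {
  if (inherits(x, "feature_space")) x <- x$values
  if (inherits(lags, "lag_spec")) lags <- lags$fit_lags
  if (any(lags != round(lags))) stop("lags must be whole sample shifts")
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x); nl <- length(lags)
  out <- matrix(0, n, p * nl)
  for (j in seq_len(p)) {
    for (li in seq_len(nl)) {
      l <- lags[li]
      col <- (j - 1L) * nl + li
      if (l >= 0) {
        if (l < n) out[(l + 1):n, col] <- x[1:(n - l), j]
      } else {
        if (-l < n) out[1:(n + l), col] <- x[(1 - l):n, j]
      }
    }
  }
  out
}

#' Ridge regression (closed form)
#'
#' Minimizes `||y - Xw||^2 + lambda ||w||^2`. An intercept is included by
#' default and left unpenalized (fitting on centred data and restoring the
#' mean).
#'
#' @param X design matrix (n x p).
#' @param y response vector or matrix (n x m).
#' @param lambda non-negative ridge penalty.
#' @param intercept include an unpenalized intercept? (default TRUE)
#' @param penalty optional per-column penalty multipliers (length p), used by
#'   banded ridge.
#' @return list with `coef` (p x m) and `intercept` (length m).
#' @export
fit_ridge <- function(X, y, lambda, intercept = TRUE, penalty = NULL) {
  if (lambda < 0) stop("lambda must be non-negative")
  X <- as.matrix(X); y <- as.matrix(y)
  stopifnot(nrow(X) == nrow(y), all(is.finite(X)), all(is.finite(y)))
  p <- ncol(X)
  pen <- if (is.null(penalty)) rep(lambda, p) else lambda * penalty
  if (intercept) {
    xbar <- colMeans(X); ybar <- colMeans(y)
    Xc <- sweep(X, 2, xbar); yc <- sweep(y, 2, ybar)
  } else {
    Xc <- X; yc <- y
  }
  A <- crossprod(Xc)
  diag(A) <- diag(A) + pen
  w <- solve(A, crossprod(Xc, yc))
  b <- if (intercept) as.numeric(ybar - crossprod(w, xbar)) else numeric(ncol(y))
  list(coef = w, intercept = b)
}

#' Banded ridge regression
#'
#' A separate penalty per column band (feature-space block): band `b`'s
#' columns are penalized by `lambdas[b]`. With equal per-band lambdas this
#' reduces exactly to [fit_ridge()].
#'
#' @param X design matrix.
#' @param y response.
#' @param bands named list of column index vectors partitioning `1:ncol(X)`.
#' @param lambdas per-band penalties, same length/order as `bands`.
#' @param intercept include an unpenalized intercept?
#' @return list with `coef` and `intercept`.
#' @export
fit_banded <- function(X, y, bands, lambdas, intercept = TRUE) {
  stopifnot(length(bands) == length(lambdas))
  cols <- sort(as.integer(unlist(bands)))
  if (!identical(cols, seq_len(ncol(X)))) {
    stop("bands must partition the columns of X")
  }
  pen <- numeric(ncol(X))
  for (b in seq_along(bands)) pen[bands[[b]]] <- lambdas[b]
  fit_ridge(X, y, lambda = 1, intercept = intercept, penalty = pen)
}

#' Per-band lambda search grid
#'
#' Cartesian product of the grid over bands (17 x 17 = 289 combinations for
#' two bands with the default grid).
#' @param n_bands number of bands.
#' @param grid per-band lambda grid.
#' @return data.frame with one column per band, one row per combination.
#' @export
banded_grid <- function(n_bands, grid = default_lambda_grid()) {
  expand.grid(rep(list(grid), n_bands))
}

# Eigen-precomputation for solving one trial's ridge path over many lambdas.
ridge_path <- function(X, y, lambdas) {
  xbar <- colMeans(X); ybar <- colMeans(y)
  Xc <- sweep(X, 2, xbar); yc <- sweep(y, 2, ybar)
  E <- eigen(crossprod(Xc), symmetric = TRUE)
  vt_xty <- crossprod(E$vectors, crossprod(Xc, yc))
  lapply(lambdas, function(l) {
    w <- E$vectors %*% (vt_xty / (pmax(E$values, 0) + l))
    list(coef = w, intercept = as.numeric(ybar - crossprod(w, xbar)))
  })
}

safe_cor <- function(a, b) {
  if (stats::sd(a) < 1e-14 || stats::sd(b) < 1e-14) return(0)
  stats::cor(a, b)
}

#' Leave-one-trial-out cross-validated TRF fitting
#'
#' For every held-out trial, weights fitted on each training trial separately
#' are averaged and used to predict the held-out trial over the narrower
#' predict-lag range; accuracy is the Pearson correlation between predicted
#' and observed series, per output unit. The procedure runs over the whole
#' lambda grid at once. Trials shorter than the longest lag are excluded
#' with a warning.
#'
#' @param x_list list of per-trial predictor matrices (time x feature); for
#'   encoding these are prepared stimulus features, for decoding the reduced
#'   neural components.
#' @param y_list list of per-trial response matrices (time x output).
#' @param lspec a [lag_spec()].
#' @param lambda_grid ridge penalties to evaluate.
#' @param direction `"encoding"` or `"decoding"` (decoding reverses the sign
#'   of the lags so positive lags read the neural response after the
#'   stimulus).
#' @param space_id identity string stored in the returned model.
#' @return a `trf_cv` object: list with `accuracy` (trial x output x lambda
#'   array), `weights` (p x output x lambda array of trial-averaged weights,
#'   feature-major rows), `lambda_grid`, `lspec`, `direction`, `n_features`.
#' @export
trf_loto <- function(x_list, y_list, lspec = lag_spec(),
                     lambda_grid = default_lambda_grid(),
                     direction = c("encoding", "decoding"),
                     space_id = "features") {
  direction <- match.arg(direction)
  n_tr <- length(x_list)
  if (n_tr < 3) stop("leave-one-trial-out needs at least 3 trials")
  stopifnot(length(y_list) == n_tr)
  x_list <- lapply(x_list, function(x)
    if (inherits(x, "feature_space")) x$values else as.matrix(x))
  y_list <- lapply(y_list, as.matrix)

  lags <- lspec$fit_lags
  if (direction == "decoding") lags <- -rev(lags)
  max_lag <- max(abs(lags))
  ok <- vapply(x_list, nrow, 1L) > max_lag
  if (!all(ok)) {
    warning(sum(!ok), " trial(s) shorter than the longest lag excluded")
    x_list <- x_list[ok]; y_list <- y_list[ok]
    n_tr <- length(x_list)
    if (n_tr < 3) stop("fewer than 3 usable trials")
  }

  n_feat <- ncol(x_list[[1]])
  nl <- length(lags)
  p <- n_feat * nl
  m <- ncol(y_list[[1]])
  L <- length(lambda_grid)

  # Columns used at prediction time (lags restricted to the predict window).
  pl <- lspec$predict_lags
  if (direction == "decoding") pl <- -rev(pl)
  keep_l <- lags %in% pl
  keep_cols <- rep(keep_l, n_feat)

  Xl <- lapply(x_list, lag_matrix, lags = lags)
  coefs <- array(0, c(p, m, L, n_tr))
  icpts <- array(0, c(m, L, n_tr))
  for (tr in seq_len(n_tr)) {
    path <- ridge_path(Xl[[tr]], y_list[[tr]], lambda_grid)
    for (li in seq_len(L)) {
      coefs[, , li, tr] <- path[[li]]$coef
      icpts[, li, tr] <- path[[li]]$intercept
    }
  }
  coef_sum <- rowSums(coefs, dims = 3)
  icpt_sum <- rowSums(icpts, dims = 2)

  acc <- array(NA_real_, c(n_tr, m, L))
  for (tr in seq_len(n_tr)) {
    Xp <- Xl[[tr]][, keep_cols, drop = FALSE]
    for (li in seq_len(L)) {
      w <- (coef_sum[, , li, drop = FALSE][, , 1] - coefs[, , li, tr]) / (n_tr - 1)
      w <- matrix(w, p, m)
      b <- (icpt_sum[, li] - icpts[, li, tr]) / (n_tr - 1)
      pred <- Xp %*% w[keep_cols, , drop = FALSE]
      pred <- sweep(pred, 2, b, "+")
      acc[tr, , li] <- vapply(seq_len(m), function(u)
        safe_cor(pred[, u], y_list[[tr]][, u]), numeric(1))
    }
  }
  weights <- coef_sum / n_tr
  dimnames(acc) <- list(NULL, colnames(y_list[[1]]), NULL)
  structure(list(accuracy = acc, weights = weights,
                 per_trial_coefs = coefs,
                 lambda_grid = lambda_grid, lspec = lspec,
                 direction = direction, n_features = n_feat,
                 lags = lags, space_id = space_id),
            class = "trf_cv")
}

#' Accuracy table from a cross-validated TRF fit
#'
#' @param fit a `trf_cv` object.
#' @param lambda optional single lambda (must be in the grid); default all.
#' @return tibble with columns `trial`, `output`, `lambda`, `r`.
#' @export
accuracy_table <- function(fit, lambda = NULL) {
  li <- if (is.null(lambda)) seq_along(fit$lambda_grid) else {
    w <- which(fit$lambda_grid == lambda)
    if (!length(w)) stop("lambda not in the fitted grid")
    w
  }
  out <- expand.grid(trial = seq_len(dim(fit$accuracy)[1]),
                     output = seq_len(dim(fit$accuracy)[2]),
                     lambda = fit$lambda_grid[li])
  out$r <- as.vector(fit$accuracy[, , li])
  tibble::as_tibble(out)
}

#' Extract the TRF weight array at one lambda
#'
#' @param fit a `trf_cv` object.
#' @param lambda penalty at which to extract (default: smallest in grid).
#' @return a `trf_model`: list with `weights` (lags x features x outputs),
#'   `lag_ms`, `lambda`, `direction`, `space_id`.
#' @export
trf_model <- function(fit, lambda = fit$lambda_grid[1]) {
  li <- which(fit$lambda_grid == lambda)
  if (!length(li)) stop("lambda not in the fitted grid")
  nl <- length(fit$lags)
  m <- dim(fit$weights)[2]
  w_flat <- matrix(fit$weights[, , li], ncol = m)
  arr <- array(0, c(nl, fit$n_features, m))
  for (j in seq_len(fit$n_features)) {
    arr[, j, ] <- w_flat[((j - 1) * nl + 1):(j * nl), ]
  }
  structure(list(weights = arr,
                 lag_ms = fit$lags / fit$lspec$rate * 1000,
                 lambda = lambda, direction = fit$direction,
                 space_id = fit$space_id, lspec = fit$lspec),
            class = "trf_model")
}

#' TRF peak latency
#'
#' Lag (ms) at which the RMS of the weights over features and outputs peaks.
#' @param model a `trf_model`.
#' @param lag_range_ms restrict the search (default the predict window).
#' @return latency in ms.
#' @export
trf_peak_latency <- function(model, lag_range_ms = model$lspec$predict_ms) {
  prof <- apply(model$weights, 1, function(s) sqrt(mean(s^2)))
  sel <- model$lag_ms >= lag_range_ms[1] & model$lag_ms <= lag_range_ms[2]
  model$lag_ms[sel][which.max(prof[sel])]
}

#' Select the regularization strength as the modal argmax
#'
#' For each (participant, condition) cell, accuracies (already averaged over
#' trials and output units) are maximized over the grid; the returned lambda
#' is the most frequent argmax across cells. Ties -- both within a cell's
#' argmax and in the mode -- are broken toward the smaller lambda.
#'
#' @param acc tibble with columns `participant`, `condition`, `lambda`,
#'   `accuracy`.
#' @return the selected lambda (scalar).
#' @export
select_lambda <- function(acc) {
  if (!nrow(acc)) stop("empty accuracy table")
  stopifnot(all(c("participant", "condition", "lambda", "accuracy") %in%
                  names(acc)))
  cells <- split(acc, list(acc$participant, acc$condition), drop = TRUE)
  picks <- vapply(cells, function(cell) {
    cell <- cell[order(cell$lambda), ]
    cell$lambda[which.max(cell$accuracy)]   # which.max: first (smallest) on tie
  }, numeric(1))
  tab <- table(picks)
  best <- as.numeric(names(tab)[tab == max(tab)])
  min(best)
}
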