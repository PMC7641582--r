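## Condition-level inference on model accuracies: top-sensor selection,
## two-way repeated-measures ANOVA (with Greenhouse-Geisser correction for
## the 3-level factor), paired t-tests with Cohen's dz, permutation null
## distributions (feature shuffling within trials, word shuffling across
## trials), z-scoring against nulls, Benjamini-Hochberg FDR, and the
## detail-by-prior interaction contrast.

#' Select the best sensors per hemisphere
#'
#' Picks the `k` sensors with the highest mean accuracy in each hemisphere
#' (independently per participant when a `participant` column is present).
#'
#' @param acc tibble with columns `sensor`, `hemisphere`, `accuracy` and
#'   optionally `participant`.
#' @param k sensors per hemisphere (default 20). If a hemisphere has fewer
#'   than `k` sensors, all are taken with a warning.
#' @return tibble of selected rows (`participant` if present, `hemisphere`,
#'   `sensor`, mean `accuracy`).
#' @export
select_top_sensors <- function(acc, k = 20) {
  stopifnot(all(c("sensor", "hemisphere", "accuracy") %in% names(acc)))
  grp <- intersect(c("participant", "hemisphere", "sensor"), names(acc))
  means <- dplyr::summarise(
    dplyr::group_by(acc, dplyr::across(dplyr::all_of(grp))),
    accuracy = mean(.data$accuracy), .groups = "drop")
  by_hemi <- intersect(c("participant", "hemisphere"), names(means))
  short <- 0L
  out <- dplyr::group_modify(
    dplyr::group_by(means, dplyr::across(dplyr::all_of(by_hemi))),
    function(df, key) {
      if (nrow(df) < k) short <<- short + 1L
      df[order(-df$accuracy), ][seq_len(min(k, nrow(df))), ]
    })
  if (short > 0) {
    warning(short, " hemisphere group(s) have only ", k - 1,
            " or fewer sensors; taking all of them")
  }
  dplyr::ungroup(out)
}

# Orthonormal polynomial contrast matrix for k levels ((k-1) x k).
contrast_mat <- function(k) t(stats::contr.poly(k))

gg_epsilon <- function(scores, C) {
  # scores: subjects x levels matrix of cell values; C: contrasts.
  S <- C %*% stats::cov(scores) %*% t(C)
  d <- nrow(S)
  sum(diag(S))^2 / (d * sum(S^2))
}

#' Two-way repeated-measures ANOVA (prior x detail)
#'
#' Standard within-subject sum-of-squares decomposition for the 2 (prior) x 3
#' (detail) design: main effects, interaction (each tested against its
#' subject-by-effect error term), plus simple effects of detail within each
#' prior level. Partial eta squared = SS_effect / (SS_effect + SS_error).
#' Greenhouse-Geisser corrected p-values are reported for effects involving
#' the 3-level factor.
#'
#' @param data tibble with columns `participant`, `prior`, `detail`, `value`
#'   (one value per participant per cell).
#' @return tibble with `effect`, `df1`, `df2`, `F`, `pes`, `p`, `p_gg`.
#' @export
rm_anova_2x3 <- function(data) {
  stopifnot(all(c("participant", "prior", "detail", "value") %in% names(data)))
  pr <- sort(unique(as.character(data$prior)))
  dt <- sort(unique(as.numeric(as.character(data$detail))))
  subj <- sort(unique(data$participant))
  a <- length(pr); b <- length(dt); n <- length(subj)
  Y <- array(NA_real_, c(n, a, b))
  for (r in seq_len(nrow(data))) {
    Y[match(data$participant[r], subj),
      match(as.character(data$prior[r]), pr),
      match(as.numeric(as.character(data$detail[r])), dt)] <- data$value[r]
  }
  if (anyNA(Y)) stop("incomplete design: every participant needs all ",
                     a * b, " cells")

  G <- mean(Y)
  Ms <- apply(Y, 1, mean); Mi <- apply(Y, 2, mean); Mj <- apply(Y, 3, mean)
  Mij <- apply(Y, c(2, 3), mean); Msi <- apply(Y, c(1, 2), mean)
  Msj <- apply(Y, c(1, 3), mean)

  ss_a <- n * b * sum((Mi - G)^2)
  ss_b <- n * a * sum((Mj - G)^2)
  ss_ab <- n * sum((Mij - outer(Mi - G, Mj - G, "+") - G)^2)
  ss_as <- b * sum((Msi - outer(Ms - G, Mi - G, "+") - G)^2)
  ss_bs <- a * sum((Msj - outer(Ms - G, Mj - G, "+") - G)^2)
  resid <- Y
  for (s in seq_len(n)) for (i in seq_len(a)) for (j in seq_len(b)) {
    resid[s, i, j] <- Y[s, i, j] - Mij[i, j] - Msi[s, i] - Msj[s, j] +
      Mi[i] + Mj[j] + Ms[s] - G
  }
  ss_abs <- sum(resid^2)

  eff <- function(name, ss, ss_err, df1, df2, eps = NA_real_) {
    Fv <- (ss / df1) / (ss_err / df2)
    p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
    p_gg <- if (is.na(eps)) NA_real_ else
      stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
    tibble::tibble(effect = name, df1 = df1, df2 = df2, F = Fv,
                   pes = ss / (ss + ss_err), p = p, p_gg = p_gg)
  }

  eps_b <- gg_epsilon(apply(Y, c(1, 3), mean), contrast_mat(b))
  ab_scores <- matrix(aperm(Y, c(1, 2, 3)), n, a * b)
  eps_ab <- gg_epsilon(ab_scores, kronecker(contrast_mat(a), contrast_mat(b)))

  out <- dplyr::bind_rows(
    eff("prior", ss_a, ss_as, a - 1, (a - 1) * (n - 1)),
    eff("detail", ss_b, ss_bs, b - 1, (b - 1) * (n - 1), eps_b),
    eff("prior:detail", ss_ab, ss_abs, (a - 1) * (b - 1),
        (a - 1) * (b - 1) * (n - 1), eps_ab)
  )
  # Simple effects of detail at each prior level (one-way RM ANOVA).
  for (i in seq_len(a)) {
    Z <- Y[, i, ]                       # subjects x detail
    Gz <- mean(Z)
    ss_d <- n * sum((colMeans(Z) - Gz)^2)
    ss_e <- sum((Z - outer(rowMeans(Z) - Gz, colMeans(Z) - Gz, "+") - Gz)^2)
    epsz <- gg_epsilon(Z, contrast_mat(b))
    out <- dplyr::bind_rows(out, eff(paste0("detail@", pr[i]), ss_d, ss_e,
                                     b - 1, (b - 1) * (n - 1), epsz))
  }
  out
}

#' Paired t-test with Cohen's dz
#'
#' @param x,y paired numeric vectors.
#' @return tibble with `t`, `df`, `dz`, `p` (two-sided).
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  if (stats::sd(d) < .Machine$double.eps) {
    stop("zero variance of paired differences; t undefined")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 dz = mean(d) / stats::sd(d), p = tt$p.value)
}

#' Shuffle a feature representation within a trial
#'
#' One joint random permutation of all (feature, time) entries of the trial's
#' feature matrix, destroying both the temporal and the channel structure
#' while preserving the multiset of values.
#'
#' @param space a `feature_space`.
#' @param seed integer seed.
#' @return the shuffled `feature_space`.
#' @export
shuffle_within_trial <- function(space, seed = 1) {
  stopifnot(inherits(space, "feature_space"))
  with_seed(hash_seed("shuffle_within", seed = seed), {
    v <- space$values
    space$values <- matrix(sample(as.vector(v)), nrow(v), ncol(v),
                           dimnames = dimnames(v))
    space
  })
}

#' Shuffle feature representations across trials
#'
#' Permutes the word-to-trial assignment (keeping every feature matrix
#' intact) within each permutation scope -- by default within each design
#' cell, preserving the condition structure. The identity permutation is
#' excluded whenever an alternative exists.
#'
#' @param features list of per-trial `feature_space`s.
#' @param design design tibble (same order).
#' @param seed integer seed.
#' @param scope `"condition"` (within each prior x detail cell) or `"all"`.
#' @return reordered feature list.
#' @export
shuffle_across_trials <- function(features, design, seed = 1,
                                  scope = c("condition", "all")) {
  scope <- match.arg(scope)
  stopifnot(length(features) >= 2, length(features) == nrow(design))
  with_seed(hash_seed("shuffle_across", seed = seed), {
    idx <- seq_along(features)
    groups <- if (scope == "condition") {
      split(idx, cell_key(design$prior, design$detail))
    } else list(idx)
    perm <- idx
    repeat {
      for (g in groups) perm[g] <- if (length(g) > 1) sample(g) else g
      if (!identical(perm, idx) || all(lengths(groups) <= 1)) break
    }
    features[perm]
  })
}

#' Permutation null distribution of encoding accuracies
#'
#' Re-runs the leave-one-trial-out encoding accuracy pipeline with shuffled
#' feature representations, at the lambda already optimized for the
#' unshuffled data, once per permutation; accuracies are averaged over trials
#' and output units within each condition.
#'
#' @param features list of per-trial prepared `feature_space`s.
#' @param neural an `epoched_neural` (or a list of per-trial matrices).
#' @param design design tibble.
#' @param lambda the fixed ridge penalty.
#' @param lspec a [lag_spec()].
#' @param scheme `"within_trial"` (joint feature/time-bin shuffling) or
#'   `"across_trial"` (word shuffling within condition).
#' @param n_perm number of permutations (default 100).
#' @param seed integer seed.
#' @return a `null_distribution`: tibble with `permutation`, `condition`,
#'   `accuracy`; attributes `scheme`, `n_perm`, `seed`.
#' @export
null_distribution <- function(features, neural, design, lambda,
                              lspec = lag_spec(),
                              scheme = c("within_trial", "across_trial"),
                              n_perm = 100, seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(n_perm >= 1)
  y_list <- if (inherits(neural, "epoched_neural")) {
    neural_trial_list(neural)
  } else neural
  n_samp <- nrow(y_list[[1]])
  cells <- cell_key(design$prior, design$detail)
  out <- vector("list", n_perm)
  for (perm in seq_len(n_perm)) {
    pseed <- hash_seed("perm", perm, seed = seed)
    shuffled <- if (scheme == "within_trial") {
      lapply(seq_along(features), function(i)
        shuffle_within_trial(features[[i]], seed = pseed + i))
    } else {
      shuffle_across_trials(features, design, seed = pseed)
    }
    x_list <- lapply(shuffled, function(f) pad_to_length(f, n_samp)$values)
    fit <- trf_loto(x_list, y_list, lspec = lspec, lambda_grid = lambda,
                    direction = "encoding")
    per_trial <- rowMeans(fit$accuracy[, , 1, drop = FALSE], dims = 1)
    out[[perm]] <- tibble::tibble(
      permutation = perm,
      condition = names(tapply(per_trial, cells, mean)),
      accuracy = as.numeric(tapply(per_trial, cells, mean)))
  }
  res <- dplyr::bind_rows(out)
  attr(res, "scheme") <- scheme
  attr(res, "n_perm") <- n_perm
  attr(res, "seed") <- seed
  class(res) <- c("null_distribution", class(res))
  res
}

#' z-score observed accuracies against a null distribution
#'
#' Subtracts the per-condition null mean and divides by the per-condition
#' null standard deviation.
#'
#' @param observed tibble with `condition` and `accuracy` (and optionally
#'   other id columns, preserved).
#' @param null a [null_distribution()] tibble.
#' @return `observed` with an added `z` column.
#' @export
zscore_vs_null <- function(observed, null) {
  stats_tbl <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(null),
                                                .data$condition),
                                null_mean = mean(.data$accuracy),
                                null_sd = stats::sd(.data$accuracy),
                                .groups = "drop")
  if (any(stats_tbl$null_sd < .Machine$double.eps)) {
    stop("null distribution has zero standard deviation")
  }
  out <- dplyr::left_join(observed, stats_tbl, by = "condition")
  out$z <- (out$accuracy - out$null_mean) / out$null_sd
  out$null_mean <- NULL; out$null_sd <- NULL
  out
}

#' Benjamini-Hochberg FDR control
#'
#' @param p vector of p-values.
#' @param q target false-discovery rate (default 0.05).
#' @return list with `p_adj` (BH-adjusted p-values) and `reject` (logical).
#' @export
fdr_bh <- function(p, q = 0.05) {
  p_adj <- stats::p.adjust(p, method = "BH")
  list(p_adj = p_adj, reject = p_adj < q)
}

#' Sensory-detail by prior-knowledge interaction contrast
#'
#' Per output unit (modulation cell or lag), computes
#' `(A[12, Mismatch] - A[3, Mismatch]) - (A[12, Match] - A[3, Match])` for
#' each participant, tests it against zero with a paired-style one-sample t,
#' and controls FDR across units.
#'
#' @param acc tibble with columns `participant`, `prior`, `detail`, `unit`,
#'   `value` (accuracy per cell).
#' @param q FDR level (default 0.05).
#' @param high,low the detail levels contrasted (defaults 12 and 3).
#' @return tibble with `unit`, `contrast` (mean), `t`, `df`, `p`, `p_fdr`,
#'   `significant`.
#' @export
interaction_contrast <- function(acc, q = 0.05, high = 12, low = 3) {
  stopifnot(all(c("participant", "prior", "detail", "unit", "value") %in%
                  names(acc)))
  get_cell <- function(df, pr, de) {
    v <- df$value[df$prior == pr & df$detail == de]
    if (length(v) != 1) stop("need exactly one value per (prior, detail) cell")
    v
  }
  per_unit <- lapply(split(acc, acc$unit), function(u) {
    cons <- vapply(split(u, u$participant), function(s) {
      (get_cell(s, "Mismatch", high) - get_cell(s, "Mismatch", low)) -
        (get_cell(s, "Match", high) - get_cell(s, "Match", low))
    }, numeric(1))
    if (length(cons) > 1 && stats::sd(cons) > .Machine$double.eps) {
      tt <- stats::t.test(cons)
      tibble::tibble(unit = u$unit[1], contrast = mean(cons),
                     t = unname(tt$statistic), df = unname(tt$parameter),
                     p = tt$p.value)
    } else {
      tibble::tibble(unit = u$unit[1], contrast = mean(cons),
                     t = NA_real_, df = NA_real_,
                     p = if (all(cons == 0)) 1 else NA_real_)
    }
  })
  out <- dplyr::bind_rows(per_unit)
  adj <- fdr_bh(out$p, q)
  out$p_fdr <- adj$p_adj
  out$significant <- adj$reject
  out
}
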