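# Group-level inference: cross-validated model comparison on Fisher-z
# transformed prediction correlations, and mass-univariate tests on STRFs
# with max-statistic permutation correction.

#' Per-subject model fit
#'
#' Holds one subject's per-channel cross-validated prediction correlations
#' for one model, with their Fisher z transform `z = atanh(r)`.
#'
#' @param subject Subject identifier.
#' @param model_name Model label.
#' @param r Numeric vector of per-channel prediction correlations.
#' @return An object of class `model_fit`.
#' @export
model_fit <- function(subject, model_name, r) {
  stopifnot(is.numeric(r), all(r >= -1 & r <= 1))
  structure(list(subject = subject, model_name = model_name,
                 r = r, z = atanh(r)),
            class = "model_fit")
}

group_test <- function(statistic, p, null_max, stat_max, p_min,
                       n_permutations, tail, df) {
  structure(list(statistic = statistic, p = p, null_max = null_max,
                 t_max = stat_max, p_min = p_min,
                 n_permutations = n_permutations, tail = tail, df = df),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("<group_test> %d tests, df = %d, %s; p_min = %.4g, t_max = %s\n",
              length(x$statistic), x$df, x$tail, x$p_min,
              if (is.na(x$t_max)) "none significant" else
                sprintf("%.3f", x$t_max)))
  invisible(x)
}

# paired t statistics per column of a difference matrix (subjects x tests);
# all-zero columns give t = 0, zero-variance nonzero columns give +/-Inf
col_t <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  v <- (colMeans(D^2) * n - n * m^2) / (n - 1)
  v[v < 0] <- 0
  se <- sqrt(v / n)
  t <- ifelse(se == 0, ifelse(m == 0, 0, sign(m) * Inf), m / se)
  list(t = t, mean = m, se = se)
}

# sign-flip permutation max statistics for a difference matrix.
# signs: B x n matrix of +/-1. Uses the fact that sign flips leave the
# per-column mean square unchanged, so only permuted means are needed.
signflip_max <- function(D, signs, tail) {
  n <- nrow(D)
  msq <- colMeans(D^2)
  mp <- (signs %*% D) / n
  vp <- sweep(-mp^2 * n, 2, msq * n, "+") / (n - 1)
  vp[vp < 0] <- 0
  tp <- mp / sqrt(vp / n)
  tp[is.nan(tp)] <- 0
  tp[is.infinite(tp)] <- sign(tp[is.infinite(tp)]) * .Machine$double.xmax
  if (tail == "greater") apply(tp, 1, max) else apply(abs(tp), 1, max)
}

all_sign_patterns <- function(n) {
  if (n > 20) stop("exact enumeration limited to 20 subjects")
  as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
}

perm_p <- function(stat, null_max, exact) {
  if (exact)
    vapply(stat, function(s) mean(null_max >= s - 1e-12), numeric(1))
  else
    vapply(stat, function(s) (1 + sum(null_max >= s - 1e-12)) /
             (length(null_max) + 1), numeric(1))
}

#' Compare full and null encoding models across subjects
#'
#' Tests whether a full model predicts held-out responses better than a
#' null model from which one or more predictors were removed. Per channel,
#' a related-measures t test is computed on the per-subject differences of
#' Fisher-z transformed prediction correlations; family-wise error across
#' channels is controlled with the permutation distribution of the maximum
#' statistic under random sign flips of the subject difference maps. The
#' test is one-tailed (full > null) by default, since removing a predictor
#' can only remove explanatory structure.
#'
#' @param full,null Lists of [model_fit()] objects, same subjects in the
#'   same order, same channels.
#' @param n_permutations Number of random sign-flip permutations (ignored
#'   for `permutations = "exact"`).
#' @param seed Optional seed for the permutation draw.
#' @param alpha Significance level used to report `t_max`, the largest t in
#'   the significant area (`NA` if no channel is significant).
#' @param tail `"greater"` (one-tailed, default) or `"two"`.
#' @param permutations `"random"` or `"exact"` (all `2^n` sign patterns).
#' @return A `group_test` with the t map, corrected p map, max-statistic
#'   null distribution, `t_max` and `p_min`.
#' @export
compare_models <- function(full, null, n_permutations = 10000, seed = NULL,
                           alpha = 0.05, tail = c("greater", "two"),
                           permutations = c("random", "exact")) {
  tail <- match.arg(tail)
  permutations <- match.arg(permutations)
  stopifnot(length(full) == length(null), length(full) >= 2)
  sf <- vapply(full, function(m) as.character(m$subject), character(1))
  sn <- vapply(null, function(m) as.character(m$subject), character(1))
  if (!identical(sf, sn)) stop("full and null fits have different subjects")
  nc <- length(full[[1]]$r)
  D <- matrix(unlist(lapply(seq_along(full), function(i) {
    if (length(null[[i]]$r) != nc || length(full[[i]]$r) != nc)
      stop("channel count mismatch")
    full[[i]]$z - null[[i]]$z
  })), nrow = length(full), ncol = nc, byrow = TRUE)
  obs <- col_t(D)
  if (permutations == "exact") {
    signs <- all_sign_patterns(nrow(D))
  } else {
    if (!is.null(seed)) set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n_permutations * nrow(D), replace = TRUE),
                    n_permutations, nrow(D))
  }
  null_max <- signflip_max(D, signs, tail)
  p <- perm_p(if (tail == "greater") obs$t else abs(obs$t), null_max,
              exact = permutations == "exact")
  sig <- p <= alpha
  group_test(obs$t, p, null_max,
             stat_max = if (any(sig)) max(obs$t[sig]) else NA_real_,
             p_min = min(p), n_permutations = nrow(signs), tail = tail,
             df = nrow(D) - 1L)
}

#' Mass-univariate tests on STRF arrays
#'
#' Point-wise related-measures tests over (time, band) arrays with
#' family-wise error correction from the permutation distribution of the
#' maximum statistic.
#'
#' For `design = "paired"`, `arrays` is a list of two subjects-by-time-by-
#' band arrays (or subjects-by-points matrices); a two-tailed paired t test
#' is computed point-wise and corrected with sign-flip permutations of the
#' difference maps (max |t|).
#'
#' For `design = "anova_2x2"`, `arrays` is a list of four arrays in the
#' order attended-overt, attended-masked, ignored-overt, ignored-masked;
#' the repeated-measures stream-by-masking interaction F is computed
#' point-wise and corrected by permuting the four condition labels within
#' each subject (max F).
#'
#' @param arrays List of condition arrays, identical dimensions, subjects
#'   in the first dimension.
#' @param design `"paired"` or `"anova_2x2"`.
#' @param lags_ms Optional lag axis (ms) of the time dimension; when given,
#'   the test is restricted to `time_window`.
#' @param time_window Half-open analysis window in ms, default `[0, 450)`.
#' @param n_permutations Number of permutations.
#' @param seed Optional seed.
#' @param alpha Level for the `t_max` summary.
#' @param permutations `"random"` or (paired only) `"exact"`.
#' @return A `group_test`; statistic and p maps have one entry per tested
#'   point.
#' @export
mass_univariate_test <- function(arrays, design = c("paired", "anova_2x2"),
                                 lags_ms = NULL, time_window = c(0, 450),
                                 n_permutations = 10000, seed = NULL,
                                 alpha = 0.05,
                                 permutations = c("random", "exact")) {
  design <- match.arg(design)
  permutations <- match.arg(permutations)
  dims <- lapply(arrays, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("condition arrays must have identical dimensions (balanced design)")
  flat <- lapply(arrays, function(a) {
    if (length(dim(a)) == 3L) {
      if (!is.null(lags_ms)) {
        keep <- lags_ms >= time_window[1] & lags_ms < time_window[2]
        a <- a[, keep, , drop = FALSE]
      }
      matrix(a, nrow = dim(a)[1])
    } else as.matrix(a)
  })
  n <- nrow(flat[[1]])
  if (n < 2) stop("need at least 2 subjects")
  if (!is.null(seed)) set.seed(seed)

  if (design == "paired") {
    if (length(flat) != 2L) stop("paired design needs exactly 2 conditions")
    D <- flat[[1]] - flat[[2]]
    obs <- col_t(D)
    signs <- if (permutations == "exact") all_sign_patterns(n) else
      matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
             n_permutations, n)
    null_max <- signflip_max(D, signs, tail = "two")
    p <- perm_p(abs(obs$t), null_max, exact = permutations == "exact")
    sig <- p <= alpha
    return(group_test(obs$t, p, null_max,
                      stat_max = if (any(sig)) max(abs(obs$t)[sig]) else NA_real_,
                      p_min = min(p), n_permutations = nrow(signs),
                      tail = "two", df = n - 1L))
  }

  # 2x2 repeated-measures interaction: per-subject contrast
  # (att_overt - att_masked) - (ign_overt - ign_masked); F = t^2
  if (length(flat) != 4L) stop("anova_2x2 design needs exactly 4 conditions")
  if (permutations == "exact")
    stop("exact enumeration is implemented for the paired design only")
  w <- c(1, -1, -1, 1)
  contrast <- function(idx) {
    # idx: n x 4 matrix giving, per subject, which condition sits in each slot
    C <- matrix(0, n, ncol(flat[[1]]))
    for (j in 1:4)
      for (i in seq_len(n))
        C[i, ] <- C[i, ] + w[j] * flat[[idx[i, j]]][i, ]
    C
  }
  idx0 <- matrix(rep(1:4, each = n), n, 4)
  obs <- col_t(contrast(idx0))
  F_obs <- obs$t^2
  null_max <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    idx <- t(vapply(seq_len(n), function(i) sample(4L), integer(4)))
    tb <- col_t(contrast(idx))$t
    tb[is.infinite(tb)] <- sign(tb[is.infinite(tb)]) * .Machine$double.xmax
    null_max[b] <- max(tb^2)
  }
  p <- perm_p(F_obs, null_max, exact = FALSE)
  sig <- p <= alpha
  group_test(F_obs, p, null_max,
             stat_max = if (any(sig)) max(F_obs[sig]) else NA_real_,
             p_min = min(p), n_permutations = n_permutations,
             tail = "two", df = n - 1L)
}
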