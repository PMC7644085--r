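# Multi-predictor STRF estimation by L1 boosting over a Hamming-window
# basis, with nested cross-validation for held-out prediction.

#' TRF basis configuration
#'
#' Lag range and basis for STRF estimation. Model comparisons use lags
#' `[0, 500)` ms; STRF waveform analysis refits with `[-100, 500)` ms so
#' that pre-stimulus baseline activity is estimated too.
#'
#' @param tmin,tmax Lag range in ms, half-open `[tmin, tmax)`.
#' @param basis_width Width of the Hamming-window basis elements in ms.
#' @param rate Sampling rate of predictors and response in Hz.
#' @return An object of class `trf_basis_config`.
#' @export
trf_basis_config <- function(tmin = 0, tmax = 500, basis_width = 50,
                             rate = 100) {
  if (tmin >= tmax) stop("tmin must be < tmax")
  if (basis_width <= 0) stop("basis_width must be positive")
  lag0 <- round(tmin * rate / 1000)
  lag1 <- round(tmax * rate / 1000)
  bs <- max(1L, round(basis_width * rate / 1000))
  if (bs %% 2L == 0L) bs <- bs + 1L          # odd length, centered window
  structure(list(tmin = tmin, tmax = tmax, basis_width = basis_width,
                 rate = rate, lag0 = lag0, n_lags = lag1 - lag0,
                 basis_samples = bs),
            class = "trf_basis_config")
}

basis_window <- function(bs) {
  if (bs == 1L) return(1)
  k <- seq_len(bs) - 1L
  0.54 - 0.46 * cos(2 * pi * k / (bs - 1))
}

conv_same <- function(x, h) {
  if (length(h) == 1L) return(as.numeric(x * h))
  half <- (length(h) - 1L) %/% 2L
  full <- stats::convolve(c(rep(0, half), x, rep(0, half)), rev(h),
                          type = "filter")
  as.numeric(full)
}

#' Spectrotemporal response function
#'
#' Container for per-predictor kernels over lags and frequency bands.
#'
#' @param kernels Named list of lag-by-band matrices, one per predictor,
#'   sharing the lag axis.
#' @param lags_ms Lag axis in ms (left edge of each sample).
#' @param rate Sampling rate in Hz.
#' @return An object of class `strf`.
#' @export
strf <- function(kernels, lags_ms, rate) {
  stopifnot(is.list(kernels), length(kernels) >= 1L, !is.null(names(kernels)))
  for (k in kernels) {
    if (!is.matrix(k) || nrow(k) != length(lags_ms) || !all(is.finite(k)))
      stop("each kernel must be a finite lag x band matrix on the lag axis")
  }
  structure(list(kernels = kernels, lags_ms = lags_ms, rate = rate),
            class = "strf")
}

#' @export
print.strf <- function(x, ...) {
  cat(sprintf("<strf> %d predictors, lags [%g, %g] ms @ %g Hz\n",
              length(x$kernels), min(x$lags_ms), max(x$lags_ms), x$rate))
  invisible(x)
}

#' Average STRFs
#'
#' Element-wise mean of kernels across a list of `strf` objects sharing
#' axes and predictor names.
#'
#' @param strfs List of `strf` objects.
#' @return A single `strf`.
#' @export
strf_mean <- function(strfs) {
  stopifnot(length(strfs) >= 1L)
  out <- strfs[[1]]
  for (nm in names(out$kernels)) {
    acc <- out$kernels[[nm]]
    for (i in seq_along(strfs)[-1]) acc <- acc + strfs[[i]]$kernels[[nm]]
    out$kernels[[nm]] <- acc / length(strfs)
  }
  out
}

# flatten a predictor_set into a time x series matrix plus bookkeeping
flatten_predictors <- function(ps) {
  mats <- lapply(ps$predictors, function(p) p$values)
  X <- do.call(cbind, mats)
  n_bands <- vapply(ps$predictors, function(p) ncol(p$values), integer(1))
  list(X = X, names = names(ps$predictors), n_bands = n_bands,
       pred_of_series = rep(seq_along(n_bands), n_bands))
}

kernel_to_strf <- function(K, flat, cfg) {
  lags_ms <- (cfg$lag0 + seq_len(cfg$n_lags) - 1L) * 1000 / cfg$rate
  kernels <- list()
  off <- 0L
  for (i in seq_along(flat$names)) {
    nb <- flat$n_bands[i]
    kernels[[flat$names[i]]] <- t(K[off + seq_len(nb), , drop = FALSE])
    off <- off + nb
  }
  strf(kernels, lags_ms, cfg$rate)
}

#' Predict a response from an STRF
#'
#' Evaluates the forward model: the predicted response is the sum over
#' predictors and lags of the kernel times the lagged predictor,
#' `yhat(t) = sum_n sum_tau h(n, tau) x(n, t - tau)`. Negative lags shift
#' the predictor leftward; samples outside the trial are treated as zero.
#'
#' @param object An `strf`.
#' @param ps A `predictor_set` for one trial, with matching rate and
#'   predictor names.
#' @param ... Unused.
#' @return Numeric vector with one sample per predictor time sample.
#' @export
predict.strf <- function(object, ps, ...) {
  stopifnot(inherits(ps, "predictor_set"))
  if (!isTRUE(all.equal(object$rate, ps$rate)))
    stop("predictor rate does not match STRF rate")
  if (!all(names(object$kernels) %in% names(ps$predictors)))
    stop("predictor set lacks predictors named in the STRF")
  n <- nrow(ps$predictors[[1]]$values)
  lags <- round(object$lags_ms * object$rate / 1000)
  y <- numeric(n)
  for (nm in names(object$kernels)) {
    K <- object$kernels[[nm]]
    X <- ps$predictors[[nm]]$values
    for (j in seq_along(lags)) {
      kj <- K[j, ]
      if (all(kj == 0)) next
      lag <- lags[j]
      if (lag >= 0) {
        if (lag < n)
          y[(lag + 1):n] <- y[(lag + 1):n] + X[1:(n - lag), , drop = FALSE] %*% kj
      } else {
        if (-lag < n)
          y[1:(n + lag)] <- y[1:(n + lag)] + X[(1 - lag):n, , drop = FALSE] %*% kj
      }
    }
  }
  y
}

# build the boosting design for a set of trials: basis-smoothed, scaled
# series concatenated across trials with segment boundaries
boost_design <- function(resp_trials, ps_trials, trials, cfg, h) {
  Xs <- list(); ys <- list()
  for (tr in trials) {
    flat <- flatten_predictors(ps_trials[[tr]])
    Xs[[length(Xs) + 1L]] <- apply(flat$X, 2, conv_same, h = h)
    ys[[length(ys) + 1L]] <- resp_trials[[tr]]
  }
  lens <- vapply(ys, length, integer(1))
  list(X = do.call(rbind, Xs), y = unlist(ys),
       seg = c(0L, cumsum(lens)))
}

#' Estimate one channel's STRF by boosting
#'
#' Greedy coordinate descent on the training L1 error: kernels are sums of
#' signed, fixed-size steps of 50-ms Hamming-window basis elements; at each
#' iteration the (predictor, band, lag, sign) update giving the steepest
#' training error reduction is applied, and a frequency bin (or whole
#' predictor, with `freeze = "predictor"`) is frozen as soon as its chosen
#' update would strictly increase the error on the validation set.
#' Estimation stops when every bin is frozen.
#'
#' The step size is scale-free: 0.005 in units of the training response's
#' mean absolute value per unit of each (basis-smoothed) predictor band's
#' mean absolute value, making the estimator equivariant to rescaling of
#' either the response or any predictor band.
#'
#' @param response List with one numeric response vector per trial
#'   (a single channel).
#' @param ps_trials List with one `predictor_set` per trial.
#' @param cfg A [trf_basis_config()].
#' @param train_trials,validation_trials Disjoint trial index vectors.
#' @param freeze `"band"` (default) freezes individual frequency bins;
#'   `"predictor"` freezes all bands of a predictor together.
#' @param delta Relative step size.
#' @param max_iter Safety cap on boosting iterations.
#' @return An `strf` with attributes `history` (training L1 error after
#'   each accepted step) and `val_err`.
#' @export
boost_channel <- function(response, ps_trials, cfg, train_trials,
                          validation_trials, freeze = c("band", "predictor"),
                          delta = 0.005, max_iter = 20000L) {
  freeze <- match.arg(freeze)
  stopifnot(length(train_trials) >= 1L, length(validation_trials) >= 1L,
            !any(train_trials %in% validation_trials))
  if (!isTRUE(all.equal(cfg$rate, ps_trials[[1]]$rate)))
    stop("predictor rate does not match the basis configuration")
  h <- basis_window(cfg$basis_samples)
  tr <- boost_design(response, ps_trials, train_trials, cfg, h)
  va <- boost_design(response, ps_trials, validation_trials, cfg, h)
  flat <- flatten_predictors(ps_trials[[train_trials[1]]])
  S <- ncol(tr$X)

  s_y <- mean(abs(tr$y))
  if (s_y == 0) {
    warning("zero-variance response; returning an all-zero STRF")
    K <- matrix(0, S, cfg$n_lags)
    out <- kernel_to_strf(K, flat, cfg)
    attr(out, "history") <- numeric(0)
    attr(out, "val_err") <- sum(abs(va$y))
    return(out)
  }
  s_x <- colMeans(abs(tr$X))
  s_x[s_x == 0] <- 1
  Xt <- sweep(tr$X, 2, s_x, "/")
  Xv <- sweep(va$X, 2, s_x, "/")
  grp <- switch(freeze, band = seq_len(S), predictor = flat$pred_of_series)

  fit <- .boost_core(Xt, tr$y / s_y, Xv, va$y / s_y,
                     as.integer(tr$seg), as.integer(va$seg),
                     as.integer(cfg$n_lags), as.integer(cfg$lag0),
                     delta, as.integer(grp - 1L), as.integer(max_iter))

  # coefficients -> kernels: convolve with the basis window along lags and
  # undo the internal scaling
  K <- t(apply(fit$coef, 1, conv_same, h = h)) * (s_y / s_x)
  if (cfg$n_lags == 1L) K <- matrix(K, ncol = 1L)
  out <- kernel_to_strf(K, flat, cfg)
  attr(out, "history") <- fit$train_err * s_y
  attr(out, "val_err") <- fit$val_err * s_y
  attr(out, "n_accepted") <- fit$n_accepted
  out
}

#' Round-robin fold assignment
#'
#' Successive trials are assigned to folds in order (1, 2, ..., k, 1, 2, ...).
#'
#' @param n_trials Number of trials.
#' @param n_folds Number of folds.
#' @return Integer vector mapping each trial to a fold.
#' @export
fold_assignment <- function(n_trials, n_folds = 4) {
  if (n_trials < n_folds) stop("fewer trials than folds")
  ((seq_len(n_trials) - 1L) %% n_folds) + 1L
}

#' Nested cross-validated STRF estimation and model scoring
#'
#' Outer loop: each fold is held out once as a test set and its responses
#' are predicted from STRFs estimated on the remaining folds. Inner loop:
#' each of the remaining folds serves once as the early-stopping validation
#' set for boosting on the other folds; the inner STRFs are averaged before
#' predicting the test fold. Held-out predictions are concatenated across
#' folds and scored per channel by the Pearson correlation with the
#' measured response.
#'
#' @param response List with one time-by-channel matrix per trial (a single
#'   channel may be given as a plain vector).
#' @param ps_trials List with one `predictor_set` per trial.
#' @param cfg A [trf_basis_config()].
#' @param n_folds Number of folds.
#' @param ... Passed to [boost_channel()].
#' @return An object of class `boosting_result`: `strfs` (per channel, the
#'   average of all inner-loop estimates), `r` (per-channel cross-validated
#'   correlation), `predicted` (per-trial predicted responses),
#'   `fold_assignment`, and `history` (per-channel boosting traces).
#' @export
nested_crossval <- function(response, ps_trials, cfg, n_folds = 4, ...) {
  response <- lapply(response, function(m) {
    if (is.null(dim(m))) matrix(m, ncol = 1L) else m
  })
  n_trials <- length(response)
  folds <- fold_assignment(n_trials, n_folds)
  n_chan <- ncol(response[[1]])
  n <- vapply(response, nrow, integer(1))
  strfs <- vector("list", n_chan)
  r <- numeric(n_chan)
  predicted <- lapply(n, numeric)
  history <- vector("list", n_chan)
  for (ch in seq_len(n_chan)) {
    resp_ch <- lapply(response, function(m) m[, ch])
    inner_strfs <- list()
    hist_ch <- list()
    pred_ch <- lapply(n, numeric)
    for (f in sort(unique(folds))) {
      test_trials <- which(folds == f)
      est_folds <- setdiff(sort(unique(folds)), f)
      fold_strfs <- lapply(est_folds, function(v) {
        boost_channel(resp_ch, ps_trials, cfg,
                      train_trials = which(folds %in% setdiff(est_folds, v)),
                      validation_trials = which(folds == v), ...)
      })
      avg <- strf_mean(fold_strfs)
      inner_strfs <- c(inner_strfs, fold_strfs)
      hist_ch <- c(hist_ch, lapply(fold_strfs, attr, "history"))
      for (tt in test_trials)
        pred_ch[[tt]] <- predict(avg, ps_trials[[tt]])
    }
    strfs[[ch]] <- strf_mean(inner_strfs)
    obs <- unlist(resp_ch)
    fit <- unlist(pred_ch)
    r[ch] <- if (stats::sd(obs) > 0 && stats::sd(fit) > 0)
      stats::cor(obs, fit) else 0
    for (tt in seq_len(n_trials))
      predicted[[tt]] <- cbind(predicted[[tt]], pred_ch[[tt]])
    history[[ch]] <- hist_ch
  }
  structure(list(strfs = strfs, r = r, predicted = predicted,
                 fold_assignment = folds, history = history,
                 cfg = cfg),
            class = "boosting_result")
}

#' @export
print.boosting_result <- function(x, ...) {
  cat(sprintf("<boosting_result> %d channels, %d trials; r: %s\n",
              length(x$r), length(x$fold_assignment),
              paste(sprintf("%.3f", x$r), collapse = ", ")))
  invisible(x)
}

#' Cross-validated STRF estimates for waveform analysis
#'
#' For each fold, one STRF is estimated with that fold as the boosting
#' validation set and all remaining folds as training data; the per-fold
#' estimates are averaged. This is the estimation path used for STRF peak
#' and latency analysis (typically with `tmin = -100` ms).
#'
#' @inheritParams nested_crossval
#' @return List of per-channel `strf` objects.
#' @export
fit_strf <- function(response, ps_trials, cfg, n_folds = 4, ...) {
  response <- lapply(response, function(m) {
    if (is.null(dim(m))) matrix(m, ncol = 1L) else m
  })
  folds <- fold_assignment(length(response), n_folds)
  n_chan <- ncol(response[[1]])
  lapply(seq_len(n_chan), function(ch) {
    resp_ch <- lapply(response, function(m) m[, ch])
    ests <- lapply(sort(unique(folds)), function(v) {
      boost_channel(resp_ch, ps_trials, cfg,
                    train_trials = which(folds != v),
                    validation_trials = which(folds == v), ...)
    })
    strf_mean(ests)
  })
}
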