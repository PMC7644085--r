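# Small fixture builders shared across tests. Everything is generated in
# code under fixed seeds; no stored data.

# plain spectrogram with given values
spec_of <- function(values, rate = 100, role = "envelope",
                    centers = NULL) {
  values <- as.matrix(values)
  if (is.null(centers)) centers <- erb_centers(ncol(values), 150, 4000)
  spectrogram(values, rate, centers, role = role)
}

# random nonnegative onset-like predictor
rand_onset <- function(n, bands = 4, seed = 1, rate = 100) {
  set.seed(seed)
  v <- matrix(rexp(n * bands) * rbinom(n * bands, 1, 0.3), n, bands)
  predictor(spec_of(v, rate, role = "onset"), "o")
}

# predictor set of white-ish rectified-noise predictors for one trial
rand_predictor_set <- function(n, bands = 2, n_pred = 1, seed = 1,
                               rate = 100, names = NULL) {
  set.seed(seed)
  if (is.null(names)) names <- paste0("p", seq_len(n_pred))
  preds <- lapply(seq_len(n_pred), function(i)
    predictor(spec_of(matrix(pmax(rnorm(n * bands), 0), n, bands),
                      rate, role = "onset"), names[i]))
  predictor_set(preds, "custom")
}

# smooth two-peaked temporal kernel on a lag grid (ms)
two_peak_trf <- function(lags_ms, pos_lat = 70, neg_lat = 130,
                         pos_w = 15, neg_w = 25, neg_rel = 0.7) {
  exp(-(lags_ms - pos_lat)^2 / (2 * pos_w^2)) -
    neg_rel * exp(-(lags_ms - neg_lat)^2 / (2 * neg_w^2))
}

# align a ground-truth STRF onto an estimate's lag axis (zero padding)
gt_on_lags <- function(gt, nm, lags_ms) {
  K <- matrix(0, length(lags_ms), ncol(gt$kernels[[nm]]))
  idx <- match(round(gt$lags_ms, 6), round(lags_ms, 6))
  K[idx[!is.na(idx)], ] <- gt$kernels[[nm]][!is.na(idx), ]
  K
}

# correlation between frequency-smoothed estimated and true kernels
smoothed_kernel_cor <- function(est, gt, nm) {
  ests <- smooth_frequency(est)
  gts <- gt
  gts$kernels[[nm]] <- gt_on_lags(gt, nm, est$lags_ms)
  gts$lags_ms <- est$lags_ms
  gts <- smooth_frequency(gts)
  stats::cor(as.vector(ests$kernels[[nm]]), as.vector(gts$kernels[[nm]]))
}
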