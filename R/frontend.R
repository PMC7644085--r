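# Acoustic frontend: gammatone envelope spectrograms, auditory edge
# detection (onsets), frequency binning and rate conversion.

#' Gammatone envelope spectrogram
#'
#' Filters a waveform through a bank of 4th-order gammatone filters with
#' ERB-spaced center frequencies, takes the magnitude envelope of each
#' filter output, integrates it down to `out_rate`, and applies a
#' compressive power nonlinearity.
#'
#' @param wav A `waveform` object.
#' @param n_bands Number of gammatone bands.
#' @param fmin,fmax Lowest and highest band center frequency in Hz.
#' @param power Compressive exponent applied to the magnitude envelopes.
#' @param out_rate Output sampling rate in Hz; `wav$rate` must be an
#'   integer multiple of it.
#' @return An envelope `spectrogram` at `out_rate` with `n_bands`
#'   ERB-spaced bands.
#' @export
gammatone_spectrogram <- function(wav, n_bands = 256, fmin = 20, fmax = 5000,
                                  power = 0.6, out_rate = 1000) {
  stopifnot(inherits(wav, "waveform"))
  fs <- wav$rate
  if (fs < 2 * fmax)
    stop("waveform sampling rate (", fs, " Hz) is below the Nyquist rate ",
         "for fmax = ", fmax, " Hz")
  if (fs %% out_rate != 0)
    stop("waveform rate must be an integer multiple of out_rate")
  x <- wav$samples
  n <- length(x)
  factor <- fs %/% out_rate
  if (n < factor) stop("waveform shorter than one output sample")
  centers <- erb_centers(n_bands, fmin, fmax)

  # complex gammatone FIR kernels, applied by FFT convolution
  kern_dur <- 0.128                      # s; covers the slowest (20 Hz) band
  kl <- min(n, ceiling(fs * kern_dur))
  tt <- (seq_len(kl) - 1) / fs
  nfft <- stats::nextn(n + kl - 1, 2)
  xf <- stats::fft(c(x, rep(0, nfft - n)))
  n_out <- n %/% factor
  vals <- matrix(0, n_out, n_bands)
  for (b in seq_len(n_bands)) {
    fc <- centers[b]
    bw <- 1.019 * 24.7 * (4.37 * fc / 1000 + 1)   # ERB bandwidth scaling
    env <- tt^3 * exp(-2 * pi * bw * tt)
    g <- (2 / sum(env)) * env * exp(2i * pi * fc * tt)
    gf <- stats::fft(c(g, rep(0, nfft - kl)))
    y <- stats::fft(xf * gf, inverse = TRUE)[seq_len(n)] / nfft
    e <- Mod(y)
    # temporal integration: mean magnitude per output sample
    vals[, b] <- colMeans(matrix(e[seq_len(n_out * factor)], nrow = factor))
  }
  spectrogram(vals^power, out_rate, centers, role = "envelope")
}

#' Auditory edge detector configuration
#'
#' Parameters of the per-band onset (acoustic edge) detector: a saturating
#' nonlinearity followed by a layer of delayed copies filtered across the
#' delay axis with a derivative-of-Gaussian receptive field and half-wave
#' rectification.
#'
#' @param n_delays Number of taps in the delay layer.
#' @param tau_min,tau_max Smallest and largest delay increment in ms; tap
#'   `k` delays the signal by the cumulative sum of increments linearly
#'   spaced from `tau_min` to `tau_max`.
#' @param saturation_c Half-saturation constant of the input nonlinearity
#'   `s(x) = x * C / (x + C)`.
#' @param rf_sd Standard deviation of the Gaussian, in delay (tap index)
#'   units, whose derivative forms the receptive field.
#' @return An object of class `edge_detector_config`.
#' @export
edge_detector_config <- function(n_delays = 10, tau_min = 3, tau_max = 5,
                                 saturation_c = 30, rf_sd = 2) {
  if (n_delays < 2) stop("n_delays must be at least 2")
  if (!(tau_min > 0 && tau_min <= tau_max)) stop("need 0 < tau_min <= tau_max")
  if (saturation_c <= 0) stop("saturation_c must be positive")
  if (rf_sd <= 0) stop("rf_sd must be positive")
  structure(list(n_delays = n_delays, tau_min = tau_min, tau_max = tau_max,
                 saturation_c = saturation_c, rf_sd = rf_sd),
            class = "edge_detector_config")
}

# delays of the tap layer in ms: cumulative sums of linearly spaced increments
edge_delays_ms <- function(cfg) {
  cumsum(seq(cfg$tau_min, cfg$tau_max, length.out = cfg$n_delays))
}

# zero-sum, unit-l2 derivative-of-Gaussian receptive field over tap indices
edge_rf <- function(cfg) {
  k <- seq_len(cfg$n_delays)
  mu <- (cfg$n_delays + 1) / 2
  w <- -(k - mu) * exp(-(k - mu)^2 / (2 * cfg$rf_sd^2))
  w <- w - mean(w)                       # exact zero sum
  w / sqrt(sum(w^2))
}

#' Detect acoustic onsets (auditory edges)
#'
#' Applies the edge detector independently to each frequency band of an
#' envelope spectrogram: saturating nonlinearity, delay layer, a
#' derivative-of-Gaussian receptive field across the delay axis, and
#' half-wave rectification. Rapid energy increases produce positive onset
#' values; decreases are rectified away.
#'
#' @param spec An envelope `spectrogram`.
#' @param cfg An [edge_detector_config()].
#' @return An onset `spectrogram` with the same shape, rate and bands.
#' @export
detect_edges <- function(spec, cfg = edge_detector_config()) {
  stopifnot(inherits(spec, "spectrogram"))
  if (spec$role != "envelope")
    stop("detect_edges expects an envelope spectrogram")
  if (!inherits(cfg, "edge_detector_config"))
    stop("cfg must be an edge_detector_config")
  d <- round(edge_delays_ms(cfg) * spec$rate / 1000)
  if (any(diff(d) <= 0))
    stop("spectrogram rate too low to resolve the delay layer; ",
         "compute onsets at a higher rate")
  w <- edge_rf(cfg)
  C <- cfg$saturation_c
  s <- spec$values * C / (spec$values + C)
  n <- nrow(s)
  out <- matrix(0, n, ncol(s))
  for (k in seq_along(d)) {
    dk <- d[k]
    if (dk < n)
      out[(dk + 1):n, ] <- out[(dk + 1):n, ] + w[k] * s[1:(n - dk), , drop = FALSE]
  }
  out[out < 0] <- 0
  spectrogram(out, spec$rate, spec$band_centers, role = "onset")
}

#' Bin spectrogram bands on the ERB scale
#'
#' Drops bands with center frequencies below `fmin_bin` and partitions the
#' remaining bands into `n_bins` contiguous groups of equal width on the
#' ERB scale. Each output band is the sum of its group, so total magnitude
#' over the retained bands is preserved.
#'
#' @param spec A `spectrogram` with more than `n_bins` bands.
#' @param n_bins Number of output bands.
#' @param fmin_bin Cutoff in Hz; input bands centered below it are omitted.
#' @return A `spectrogram` with `n_bins` bands.
#' @export
bin_bands <- function(spec, n_bins = 8, fmin_bin = 100) {
  stopifnot(inherits(spec, "spectrogram"))
  keep <- spec$band_centers >= fmin_bin
  if (sum(keep) < n_bins)
    stop("fewer than ", n_bins, " bands at or above ", fmin_bin, " Hz")
  e <- hz_to_erb(spec$band_centers[keep])
  edges <- seq(e[1], e[length(e)], length.out = n_bins + 1)
  grp <- pmin(findInterval(e, edges, rightmost.closed = TRUE), n_bins)
  if (!all(seq_len(n_bins) %in% grp))
    stop("empty frequency bin; too few bands for ", n_bins, " bins")
  v <- spec$values[, keep, drop = FALSE]
  vals <- vapply(seq_len(n_bins),
                 function(g) rowSums(v[, grp == g, drop = FALSE]),
                 numeric(nrow(v)))
  centers <- erb_to_hz((edges[-1] + edges[-(n_bins + 1)]) / 2)
  spectrogram(vals, spec$rate, centers, role = spec$role)
}

#' Downsample a spectrogram
#'
#' Anti-alias filters each band with a unit-sum windowed-sinc FIR low-pass
#' (symmetric edge padding, so constant signals are preserved exactly) and
#' decimates to `out_rate`. Small negative filter overshoot is clipped to
#' zero so predictors stay nonnegative.
#'
#' @param spec A `spectrogram`.
#' @param out_rate Target rate in Hz; must divide `spec$rate`.
#' @return A `spectrogram` at `out_rate`.
#' @export
resample_series <- function(spec, out_rate = 100) {
  stopifnot(inherits(spec, "spectrogram"))
  if (out_rate > spec$rate)
    stop("resample_series only downsamples (out_rate > spectrogram rate)")
  if (isTRUE(all.equal(out_rate, spec$rate))) return(spec)
  if (spec$rate %% out_rate != 0)
    stop("out_rate must divide the spectrogram rate")
  factor <- spec$rate %/% out_rate
  half <- 5L * factor
  t <- (-half):half
  h <- sincf(t / factor) * (0.54 + 0.46 * cos(pi * t / half))
  h <- h / sum(h)
  n <- nrow(spec$values)
  idx <- seq(1L, n, by = factor)
  vals <- apply(spec$values, 2, function(x) {
    xp <- c(rep(x[1], half), x, rep(x[n], half))
    y <- stats::filter(xp, h, sides = 2)
    as.numeric(y[(half + 1):(half + n)])[idx]
  })
  vals <- as.matrix(vals)
  vals[vals < 0] <- 0
  spectrogram(vals, out_rate, spec$band_centers, role = spec$role)
}

sincf <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Band-limited upsampling of a sampled series
#'
#' Windowed-sinc (Whittaker) interpolation onto a grid `factor` times finer,
#' with edge replication and per-sample weight renormalization. Original
#' samples are reproduced exactly.
#'
#' @param x Numeric vector.
#' @param factor Integer upsampling factor.
#' @param half_width Half width of the sinc window in input samples.
#' @return Numeric vector of length `(length(x) - 1) * factor + 1`.
#' @export
upsample_sinc <- function(x, factor, half_width = 16) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1, length(x) >= 2)
  if (factor == 1L) return(as.numeric(x))
  n <- length(x)
  hw <- as.integer(half_width)
  xp <- c(rep(x[1], hw), x, rep(x[n], hw))
  u <- (seq_len((n - 1L) * factor + 1L) - 1L) / factor   # position, 0-based
  i0 <- floor(u)
  frac <- u - i0
  out <- numeric(length(u))
  wsum <- numeric(length(u))
  for (m in (-hw + 1L):hw) {
    d <- frac - m
    w <- sincf(d) * (0.54 + 0.46 * cos(pi * pmax(pmin(d / hw, 1), -1)))
    out <- out + w * xp[i0 + m + hw + 1L]
    wsum <- wsum + w
  }
  out / wsum
}
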