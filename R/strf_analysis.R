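# STRF post-processing: frequency smoothing and averaging, band-limited
# upsampling, peak latency/amplitude extraction, paired peak statistics.

#' Smooth an STRF along the frequency axis
#'
#' Convolves every lag's band vector with a unit-sum Hamming window of
#' `width_bins` bins. At the edges the kernel is renormalized over its
#' in-range support, so a constant band profile is left unchanged and
#' total mass per lag is preserved up to edge renormalization.
#'
#' @param x An `strf`.
#' @param width_bins Width of the Hamming window in bins (odd).
#' @return The smoothed `strf`.
#' @export
smooth_frequency <- function(x, width_bins = 7) {
  stopifnot(inherits(x, "strf"), width_bins >= 1)
  half <- (width_bins - 1) %/% 2
  k <- seq_len(width_bins) - 1
  w <- if (width_bins == 1) 1 else 0.54 - 0.46 * cos(2 * pi * k / (width_bins - 1))
  x$kernels <- lapply(x$kernels, function(K) {
    B <- ncol(K)
    M <- matrix(0, B, B)
    for (b in seq_len(B)) {
      j <- (b - half):(b + half)
      ok <- j >= 1 & j <= B
      M[b, j[ok]] <- w[ok] / sum(w[ok])
    }
    K %*% t(M)
  })
  x
}

# frequency-averaged temporal response function for one predictor
freq_average <- function(x, pred, smooth = TRUE, width_bins = 7) {
  stopifnot(inherits(x, "strf"))
  if (smooth) x <- smooth_frequency(x, width_bins)
  K <- x$kernels[[pred]]
  if (is.null(K)) stop("no predictor named '", pred, "' in the STRF")
  rowMeans(K)
}

#' Peak of a temporal response function
#'
#' Averages one predictor's kernel along the frequency axis (after
#' optional frequency smoothing), upsamples the resulting temporal
#' response function to `upsample_rate` by windowed-sinc interpolation,
#' and returns the location and value of the extremum inside a half-open
#' latency window `[lo, hi)`. Ties go to the earliest latency.
#'
#' @param x An `strf`.
#' @param pred Predictor name.
#' @param polarity `"positive"` (maximum) or `"negative"` (minimum).
#' @param window Half-open search window in ms, e.g. `c(20, 200)`.
#' @param upsample_rate Rate of the peak search grid in Hz; must be an
#'   integer multiple of the STRF rate.
#' @param smooth Whether to frequency-smooth before averaging.
#' @param subject Optional subject id stored in the result.
#' @return An object of class `peak_measurement` with fields `subject`,
#'   `predictor`, `polarity`, `latency` (ms), `amplitude`, `window`.
#' @export
find_peak <- function(x, pred, polarity = c("positive", "negative"),
                      window = c(20, 200), upsample_rate = 500,
                      smooth = TRUE, subject = NA) {
  polarity <- match.arg(polarity)
  trf <- freq_average(x, pred, smooth = smooth)
  step <- 1000 / x$rate
  if (window[1] < min(x$lags_ms) || window[2] > max(x$lags_ms) + step)
    stop("search window [", window[1], ", ", window[2],
         ") outside the STRF lag range")
  if (upsample_rate %% x$rate != 0)
    stop("upsample_rate must be an integer multiple of the STRF rate")
  factor <- upsample_rate %/% x$rate
  fine <- upsample_sinc(trf, factor)
  lags_fine <- min(x$lags_ms) + (seq_along(fine) - 1) * 1000 / upsample_rate
  idx <- which(lags_fine >= window[1] & lags_fine < window[2])
  if (length(idx) == 0) stop("empty search window")
  j <- if (polarity == "positive") idx[which.max(fine[idx])]
       else idx[which.min(fine[idx])]
  structure(list(subject = subject, predictor = pred, polarity = polarity,
                 latency = lags_fine[j], amplitude = fine[j],
                 window = window),
            class = "peak_measurement")
}

#' @export
print.peak_measurement <- function(x, ...) {
  cat(sprintf("<peak '%s' %s> %.1f ms, amplitude %.4g (window [%g, %g) ms)\n",
              x$predictor, x$polarity, x$latency, x$amplitude,
              x$window[1], x$window[2]))
  invisible(x)
}

peak_values <- function(peaks, measure) {
  if (is.numeric(peaks)) return(peaks)
  vapply(peaks, function(p) p[[measure]], numeric(1))
}

#' Paired test on peak measurements
#'
#' Related-measures t test (df = n - 1, two-tailed) on per-subject peak
#' latencies or amplitudes from two conditions. A zero-variance nonzero
#' difference (every subject shifted by exactly the same amount) is
#' degenerate for the t statistic and is reported with the
#' `exact_difference` flag instead of a p-value.
#'
#' @param a,b Lists of `peak_measurement` objects (same subjects, same
#'   order) or plain numeric vectors.
#' @param measure `"latency"` or `"amplitude"`.
#' @return List with `t`, `df`, `p`, `mean_diff`, `se`, `n`,
#'   `exact_difference`.
#' @export
paired_peak_test <- function(a, b, measure = c("latency", "amplitude")) {
  measure <- match.arg(measure)
  xa <- peak_values(a, measure)
  xb <- peak_values(b, measure)
  if (length(xa) != length(xb)) stop("conditions have different subjects")
  n <- length(xa)
  if (n < 2) stop("need at least 2 subjects")
  d <- xa - xb
  m <- mean(d)
  s <- stats::sd(d)
  if (s <= abs(m) * 1e-10) {               # zero variance up to rounding
    if (m == 0)
      return(list(t = 0, df = n - 1, p = 1, mean_diff = 0, se = 0, n = n,
                  exact_difference = FALSE))
    return(list(t = sign(m) * Inf, df = n - 1, p = NA_real_, mean_diff = m,
                se = 0, n = n, exact_difference = TRUE))
  }
  se <- s / sqrt(n)
  t <- m / se
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1),
       mean_diff = m, se = se, n = n, exact_difference = FALSE)
}

#' Difference of two STRFs
#'
#' Element-wise `a - b` over matching predictors and axes; the contrast is
#' recorded in the `"contrast"` attribute.
#'
#' @param a,b `strf` objects with identical predictors and lag axes.
#' @return An `strf`.
#' @export
condition_difference <- function(a, b) {
  stopifnot(inherits(a, "strf"), inherits(b, "strf"))
  if (!isTRUE(all.equal(a$lags_ms, b$lags_ms)) ||
      !identical(names(a$kernels), names(b$kernels)))
    stop("STRF axes or predictors do not match")
  for (nm in names(a$kernels)) {
    if (!identical(dim(a$kernels[[nm]]), dim(b$kernels[[nm]])))
      stop("kernel shape mismatch for predictor '", nm, "'")
    a$kernels[[nm]] <- a$kernels[[nm]] - b$kernels[[nm]]
  }
  attr(a, "contrast") <- "a - b"
  a
}
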