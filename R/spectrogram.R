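#' Equivalent rectangular bandwidth (ERB) scale
#'
#' Convert between frequency in Hz and ERB-number (Cam) using the
#' Glasberg & Moore approximation. ERB spacing approximates the spacing of
#' cochlear filters and is the frequency axis used throughout this package.
#'
#' @param f Frequency in Hz.
#' @param erb ERB-number.
#' @return `hz_to_erb()` returns ERB-numbers; `erb_to_hz()` returns Hz.
#' @export
hz_to_erb <- function(f) 21.4 * log10(0.00437 * f + 1)

#' @rdname hz_to_erb
#' @export
erb_to_hz <- function(erb) (10^(erb / 21.4) - 1) / 0.00437

#' ERB-spaced band center frequencies
#'
#' @param n Number of bands.
#' @param fmin,fmax Frequency range in Hz (inclusive endpoints).
#' @return Strictly increasing vector of `n` center frequencies in Hz,
#'   equally spaced on the ERB scale.
#' @export
erb_centers <- function(n, fmin, fmax) {
  stopifnot(n >= 1, fmin > 0, fmax > fmin)
  erb_to_hz(seq(hz_to_erb(fmin), hz_to_erb(fmax), length.out = n))
}

#' Spectrogram container
#'
#' A time-by-band matrix of nonnegative values with a sampling rate, band
#' center frequencies and a role tag. Envelope spectrograms hold band
#' magnitude envelopes; onset spectrograms hold half-wave-rectified output
#' of the auditory edge detector.
#'
#' @param values Numeric matrix, time in rows, frequency bands in columns.
#'   Must be finite and nonnegative.
#' @param rate Sampling rate in Hz.
#' @param band_centers Band center frequencies in Hz, strictly increasing,
#'   one per column.
#' @param role `"envelope"` or `"onset"`.
#' @return An object of class `spectrogram`.
#' @export
spectrogram <- function(values, rate, band_centers, role = c("envelope", "onset")) {
  role <- match.arg(role)
  values <- as.matrix(values)
  if (!is.numeric(values) || nrow(values) == 0L)
    stop("spectrogram values must be a non-empty numeric matrix")
  if (!all(is.finite(values)))
    stop("spectrogram values must be finite")
  if (any(values < 0))
    stop("spectrogram values must be nonnegative")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a positive scalar")
  band_centers <- as.numeric(band_centers)
  if (length(band_centers) != ncol(values))
    stop("band_centers must have one entry per column of values")
  if (length(band_centers) > 1L && any(diff(band_centers) <= 0))
    stop("band_centers must be strictly increasing")
  structure(
    list(values = values, rate = rate, band_centers = band_centers, role = role),
    class = "spectrogram"
  )
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf(
    "<spectrogram [%s]> %d samples x %d bands @ %g Hz, %g-%g Hz\n",
    x$role, nrow(x$values), ncol(x$values), x$rate,
    min(x$band_centers), max(x$band_centers)
  ))
  invisible(x)
}

#' @export
dim.spectrogram <- function(x) dim(x$values)

n_samples <- function(spec) nrow(spec$values)
n_bands <- function(spec) ncol(spec$values)

stop_if_axis_mismatch <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("spectrogram shape mismatch")
  if (!isTRUE(all.equal(a$rate, b$rate)))
    stop("spectrogram rate mismatch")
  if (!isTRUE(all.equal(a$band_centers, b$band_centers)))
    stop("spectrogram band mismatch")
  invisible(TRUE)
}
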