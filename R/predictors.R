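# Predictor construction: stream-based envelope/onset predictors, the
# masked/overt onset decomposition, intensity-level splits, and the l1
# normalization used by the reverse-correlation procedure.

#' Predictor time series
#'
#' A named, role-tagged spectrogram used as a model predictor. Carries the
#' per-band l1 norms once [l1_normalize()] has been applied.
#'
#' @param spec A `spectrogram` (typically 8 bands at response rate).
#' @param name Predictor label, e.g. `"o_mix"` or `"e_att"`.
#' @return An object of class `predictor` (inherits `spectrogram`).
#' @export
predictor <- function(spec, name) {
  stopifnot(inherits(spec, "spectrogram"), is.character(name), length(name) == 1L)
  structure(list(name = name, values = spec$values, rate = spec$rate,
                 band_centers = spec$band_centers, role = spec$role,
                 l1_norms = NULL, zero_bands = NULL),
            class = c("predictor", "spectrogram"))
}

#' @export
print.predictor <- function(x, ...) {
  cat(sprintf("<predictor '%s' [%s]> %d samples x %d bands @ %g Hz%s\n",
              x$name, x$role, nrow(x$values), ncol(x$values), x$rate,
              if (is.null(x$l1_norms)) "" else ", l1-normalized"))
  invisible(x)
}

#' Ordered collection of predictors for one model
#'
#' @param predictors List of `predictor` objects sharing rate and duration,
#'   with unique names.
#' @param model_name One of `"clean"`, `"stream"`, `"masked"`,
#'   `"level_control"`, or a free-form label.
#' @return An object of class `predictor_set`.
#' @export
predictor_set <- function(predictors, model_name = "custom") {
  stopifnot(is.list(predictors), length(predictors) >= 1L)
  lapply(predictors, function(p) stopifnot(inherits(p, "predictor")))
  nm <- vapply(predictors, function(p) p$name, character(1))
  if (anyDuplicated(nm)) stop("predictor names must be unique")
  rates <- vapply(predictors, function(p) p$rate, numeric(1))
  lens <- vapply(predictors, function(p) nrow(p$values), integer(1))
  if (length(unique(rates)) != 1L || length(unique(lens)) != 1L)
    stop("all predictors must share rate and duration")
  names(predictors) <- nm
  structure(list(predictors = predictors, model_name = model_name,
                 rate = unname(rates[1])),
            class = "predictor_set")
}

#' @export
print.predictor_set <- function(x, ...) {
  cat(sprintf("<predictor_set '%s'> %d predictors @ %g Hz: %s\n",
              x$model_name, length(x$predictors), x$rate,
              paste(names(x$predictors), collapse = ", ")))
  invisible(x)
}

#' Masked/overt onset decomposition
#'
#' Splits a source onset predictor into the part masked by a competing
#' mixture and the part overtly visible in it:
#' masked = `max(source - mixture, 0)`, overt = `min(source, mixture)`.
#' The two parts reconstruct the source exactly: `overt + masked == source`.
#'
#' @param o_source Onset `predictor` (or spectrogram) of one source stream.
#' @param o_mixture Onset `predictor` of the acoustic mixture, same shape.
#' @return List with elements `overt` and `masked`, named by appending
#'   `"_overt"`/`"_masked"` to the source name.
#' @export
split_masked_overt <- function(o_source, o_mixture) {
  stop_if_axis_mismatch(o_source, o_mixture)
  src <- o_source$values
  mix <- o_mixture$values
  masked <- pmax(src - mix, 0)
  overt <- src - masked                    # == pmin(src, mix)
  base <- if (inherits(o_source, "predictor")) o_source$name else "o"
  sp <- function(v, suffix) predictor(
    spectrogram(v, o_source$rate, o_source$band_centers, role = "onset"),
    paste0(base, "_", suffix))
  list(overt = sp(overt, "overt"), masked = sp(masked, "masked"))
}

#' Fraction of onset magnitude that is overt vs masked
#'
#' Pools the l1 norm of the overt and masked decompositions over all source
#' streams and frequency bands and returns the fractions of total source
#' onset magnitude assigned to each.
#'
#' @param o_sources List of source onset predictors.
#' @param o_mixture Mixture onset predictor.
#' @return List with `overt` and `masked` fractions (summing to 1) and
#'   `per_source`, the overt fraction of each source separately.
#' @export
overt_fraction <- function(o_sources, o_mixture) {
  if (inherits(o_sources, "spectrogram")) o_sources <- list(o_sources)
  tot <- 0; ov <- 0
  per_source <- numeric(length(o_sources))
  for (i in seq_along(o_sources)) {
    sp <- split_masked_overt(o_sources[[i]], o_mixture)
    s_tot <- sum(o_sources[[i]]$values)
    s_ov <- sum(sp$overt$values)
    tot <- tot + s_tot
    ov <- ov + s_ov
    per_source[i] <- if (s_tot > 0) s_ov / s_tot else NA_real_
  }
  if (tot <= 0) stop("total source onset magnitude is zero")
  list(overt = ov / tot, masked = 1 - ov / tot, per_source = per_source)
}

# per-band onset events: maximal runs of consecutive nonzero samples
band_events <- function(x) {
  r <- rle(x > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Split an onset predictor by event intensity
#'
#' Identifies discrete onset events per band (maximal runs of nonzero
#' samples), measures each event's intensity as the sum of its elements,
#' and assigns whole events to intensity levels by per-band tertiles
#' (generally, `n_levels`-tiles). The level predictors partition the input
#' exactly.
#'
#' Ties are broken deterministically by sorting events on (intensity, onset
#' time); level boundaries fall at ranks `ceiling(k * n / n_levels)`. Bands
#' with fewer events than levels assign event of rank k to level k.
#'
#' @param o An onset `predictor`.
#' @param n_levels Number of intensity levels.
#' @return A `predictor_set` of `n_levels` predictors named by appending
#'   `"_low"`, `"_mid"`, `"_high"` (or `"_l<k>"` for other level counts).
#' @export
split_intensity_levels <- function(o, n_levels = 3) {
  stopifnot(inherits(o, "spectrogram"))
  if (o$role != "onset") stop("split_intensity_levels expects an onset predictor")
  v <- o$values
  outs <- replicate(n_levels, matrix(0, nrow(v), ncol(v)), simplify = FALSE)
  for (b in seq_len(ncol(v))) {
    ev <- band_events(v[, b])
    n <- nrow(ev)
    if (n == 0L) next
    ev$intensity <- vapply(seq_len(n),
                           function(i) sum(v[ev$start[i]:ev$end[i], b]),
                           numeric(1))
    ord <- order(ev$intensity, ev$start)
    bounds <- ceiling(seq_len(n_levels) * n / n_levels)
    for (r in seq_len(n)) {
      i <- ord[r]
      lvl <- if (n < n_levels) r else findInterval(r, bounds, left.open = TRUE) + 1L
      rng <- ev$start[i]:ev$end[i]
      outs[[lvl]][rng, b] <- v[rng, b]
    }
  }
  suffix <- if (n_levels == 3) c("low", "mid", "high")
            else paste0("l", seq_len(n_levels))
  base <- if (inherits(o, "predictor")) o$name else "o"
  preds <- lapply(seq_len(n_levels), function(k) predictor(
    spectrogram(outs[[k]], o$rate, o$band_centers, role = "onset"),
    paste0(base, "_", suffix[k])))
  predictor_set(preds, model_name = "intensity_levels")
}

#' Assemble the predictor roster of a named model
#'
#' Builds the predictor sets of the four model specifications used for
#' model comparison, in a fixed order:
#' \describe{
#'   \item{clean}{`o + e` (single-talker speech).}
#'   \item{stream}{`o_mix + o_att + o_ign + e_mix + e_att + e_ign`.}
#'   \item{masked}{`o_mix + o_att_overt + o_att_masked + o_ign_overt +
#'     o_ign_masked + e_mix + e_att + e_ign`.}
#'   \item{level_control}{`o_mix_low + o_mix_mid + o_mix_high + o_att_overt +
#'     o_att_masked + e_mix + e_att + e_ign` — the mixture onset replaced by
#'     its three intensity levels, ignored-stream overt/masked dropped, same
#'     predictor count as `masked`.}
#' }
#'
#' @param envelopes Named list of envelope spectrograms; requires `att` for
#'   `clean` and `att`, `ign`, `mix` otherwise.
#' @param onsets Named list of onset spectrograms, same streams.
#' @param model_name Model to assemble.
#' @return A `predictor_set`.
#' @export
build_model_set <- function(envelopes, onsets,
                            model_name = c("clean", "stream", "masked",
                                           "level_control")) {
  model_name <- match.arg(model_name)
  need <- if (model_name == "clean") "att" else c("att", "ign", "mix")
  for (s in need) {
    if (is.null(envelopes[[s]]) || is.null(onsets[[s]]))
      stop("missing stream '", s, "' for model '", model_name, "'")
  }
  P <- function(spec, nm) {
    if (inherits(spec, "predictor")) {
      p <- spec; p$name <- nm; p
    } else predictor(spec, nm)
  }
  preds <- switch(model_name,
    clean = list(P(onsets$att, "o"), P(envelopes$att, "e")),
    stream = list(P(onsets$mix, "o_mix"), P(onsets$att, "o_att"),
                  P(onsets$ign, "o_ign"), P(envelopes$mix, "e_mix"),
                  P(envelopes$att, "e_att"), P(envelopes$ign, "e_ign")),
    masked = {
      att <- split_masked_overt(P(onsets$att, "o_att"), P(onsets$mix, "o_mix"))
      ign <- split_masked_overt(P(onsets$ign, "o_ign"), P(onsets$mix, "o_mix"))
      list(P(onsets$mix, "o_mix"), att$overt, att$masked, ign$overt,
           ign$masked, P(envelopes$mix, "e_mix"), P(envelopes$att, "e_att"),
           P(envelopes$ign, "e_ign"))
    },
    level_control = {
      att <- split_masked_overt(P(onsets$att, "o_att"), P(onsets$mix, "o_mix"))
      lv <- split_intensity_levels(P(onsets$mix, "o_mix"))$predictors
      c(unname(lv),
        list(att$overt, att$masked, P(envelopes$mix, "e_mix"),
             P(envelopes$att, "e_att"), P(envelopes$ign, "e_ign")))
    })
  predictor_set(preds, model_name = model_name)
}

#' Scale each predictor band by its l1 norm over time
#'
#' Divides every frequency band of every predictor by its l1 norm over
#' time, recording the norms. All-zero bands are left unchanged and
#' flagged. Applied to a whole `predictor_set` or a single `predictor`.
#'
#' @param ps A `predictor_set` or `predictor`.
#' @return The same type of object with unit-l1 bands and `l1_norms` set.
#' @export
l1_normalize <- function(ps) {
  if (inherits(ps, "predictor")) {
    norms <- colSums(abs(ps$values))
    zero <- norms == 0
    scale <- ifelse(zero, 1, norms)
    ps$values <- sweep(ps$values, 2, scale, "/")
    ps$l1_norms <- norms
    ps$zero_bands <- zero
    return(ps)
  }
  stopifnot(inherits(ps, "predictor_set"))
  ps$predictors <- lapply(ps$predictors, l1_normalize)
  ps
}
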