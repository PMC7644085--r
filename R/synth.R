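# Seeded synthetic two-talker scenes, ground-truth kernels and cohort
# responses. The generator works at the spectrogram level: sources are
# random band-limited event trains shaped like speech envelopes, mixed
# additively in linear power before compression, so that every later
# pipeline stage (onset detection, masked/overt decomposition, boosting,
# inference) can be validated against known ground truth.

#' Scene configuration for the synthetic generator
#'
#' @param n_trials Number of trials.
#' @param trial_duration Trial duration in seconds (excluding lead-in).
#' @param rate Response/predictor rate in Hz.
#' @param gen_rate Internal generation rate in Hz for envelopes and onset
#'   detection (must be an integer multiple of `rate`).
#' @param lead_in Seconds at the start of each trial during which only the
#'   attended source is active; discarded before analysis.
#' @param event_rate Onset events per second per band.
#' @param comodulation Probability that a source event spans all bands
#'   rather than a single band.
#' @param pause_range Pause durations in seconds, drawn uniformly;
#'   maximum 0.3 s.
#' @param utterance_mean Mean utterance duration in seconds between pauses.
#' @param swell_rate Rate (per second) of slow-rise amplitude swells, the
#'   envelope structure the edge detector is largely blind to.
#' @param swell_weight Weight of the swell component relative to the
#'   event-driven envelope.
#' @param pedestal_weight Weight of the sustained per-utterance pedestal.
#' @param mod_depth Depth of the slow multiplicative envelope modulation.
#' @param amp_spread SD (log scale) of event amplitudes.
#' @param seed Master seed; mandatory for any stochastic call.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(n_trials = 4, trial_duration = 60, rate = 100,
                         gen_rate = 500, lead_in = 1, event_rate = 3,
                         comodulation = 0.7, pause_range = c(0.25, 0.30),
                         utterance_mean = 3, swell_rate = 1.5,
                         swell_weight = 2, pedestal_weight = 0,
                         mod_depth = 0.3, amp_spread = 0.5, seed = NULL) {
  stopifnot(n_trials >= 1, trial_duration > 0, rate > 0, gen_rate >= rate,
            gen_rate %% rate == 0, lead_in >= 0, event_rate > 0,
            comodulation >= 0, comodulation <= 1,
            pause_range[1] > 0, pause_range[2] <= 0.3,
            pause_range[1] <= pause_range[2], utterance_mean > 0,
            swell_rate >= 0, swell_weight >= 0, pedestal_weight >= 0,
            mod_depth >= 0, amp_spread > 0)
  structure(list(n_trials = n_trials, trial_duration = trial_duration,
                 rate = rate, gen_rate = gen_rate, lead_in = lead_in,
                 event_rate = event_rate, comodulation = comodulation,
                 pause_range = pause_range, utterance_mean = utterance_mean,
                 swell_rate = swell_rate, swell_weight = swell_weight,
                 pedestal_weight = pedestal_weight, mod_depth = mod_depth,
                 amp_spread = amp_spread, seed = seed),
            class = "scene_config")
}

need_seed <- function(cfg) {
  if (is.null(cfg$seed)) stop("scene_config seed is mandatory for stochastic calls")
  invisible(cfg$seed)
}

# alternating utterance/pause timeline over [0, dur]; returns a 0/1 mask
speech_mask <- function(dur, fs, cfg) {
  n <- round(dur * fs)
  mask <- numeric(n)
  t <- 0
  repeat {
    utt <- min(max(stats::rexp(1, 1 / cfg$utterance_mean), 0.8), 3 * cfg$utterance_mean)
    i0 <- floor(t * fs) + 1
    i1 <- min(n, floor((t + utt) * fs))
    if (i0 <= n) mask[i0:i1] <- 1
    t <- t + utt + stats::runif(1, cfg$pause_range[1], cfg$pause_range[2])
    if (t * fs >= n) break
  }
  mask
}

# slow positive modulation: low-pass filtered Gaussian noise through exp
slow_modulation <- function(n, fs, cutoff_hz = 1.5, depth = 0.5) {
  taps <- round(fs / cutoff_hz)
  x <- stats::filter(stats::rnorm(n + taps), rep(1 / taps, taps), sides = 1)
  x <- as.numeric(x[(taps + 1):(taps + n)])
  exp(depth * x / stats::sd(x))
}

# one source stream: 8-band linear-power envelope from comodulated event
# trains with speech-like rise/decay, a sustained per-utterance pedestal,
# and slow multiplicative modulation; silenced during pauses. The pedestal
# and slow modulation give the envelope structure that the onset detector
# is largely blind to, as in natural speech.
synth_stream <- function(dur, cfg, n_bands = 8) {
  fs <- cfg$gen_rate
  n <- round(dur * fs)
  mask <- speech_mask(dur, fs, cfg)
  speech_frac <- mean(mask)
  # per-band target event rate during speech; a comodulated event counts in
  # every band, a solitary one in a single band
  master_rate <- cfg$event_rate /
    (cfg$comodulation + (1 - cfg$comodulation) / n_bands) /
    max(speech_frac, 0.1)
  n_events <- stats::rpois(1, master_rate * dur)
  times <- sort(stats::runif(n_events, 0, dur))
  imp <- matrix(0, n, n_bands)
  band_profile <- 0.5 + 0.5 * exp(-(seq_len(n_bands) - 4.5)^2 / (2 * 2.5^2))
  for (ev in seq_len(n_events)) {
    i <- floor(times[ev] * fs) + 1
    if (i > n || mask[i] == 0) next
    amp <- stats::rlnorm(1, 0, cfg$amp_spread)
    if (stats::runif(1) < cfg$comodulation) {
      imp[i, ] <- imp[i, ] + amp * band_profile * stats::rlnorm(n_bands, 0, 0.2)
    } else {
      b <- sample.int(n_bands, 1)
      imp[i, b] <- imp[i, b] + amp
    }
  }
  # event envelope: ~10 ms rise, ~60 ms decay
  tt <- seq(0, 0.3, by = 1 / fs)
  shape <- (tt / 0.012) * exp(-tt / 0.05)
  shape <- shape / max(shape)
  env <- apply(imp, 2, function(x)
    stats::convolve(c(x, numeric(length(shape))), rev(shape),
                    type = "open")[seq_len(n)])
  env[env < 0] <- 0      # FFT convolution round-off
  # slow-rise "swells": amplitude surges too gradual for the edge detector
  # to register, giving the envelope fast structure of its own
  tt2 <- seq(0, 0.8, by = 1 / fs)
  swell_shape <- (1 - exp(-tt2 / 0.15)) * exp(-tt2 / 0.3)
  swell_shape <- swell_shape / max(swell_shape)
  n_swell <- stats::rpois(1, cfg$swell_rate * dur)
  swell <- matrix(0, n, n_bands)
  for (ev in seq_len(n_swell)) {
    i <- floor(stats::runif(1, 0, dur) * fs) + 1
    if (i > n || mask[i] == 0) next
    swell[i, ] <- swell[i, ] + stats::rlnorm(1, 0, 0.5) *
      band_profile * stats::rlnorm(n_bands, 0, 0.2)
  }
  swell <- apply(swell, 2, function(x)
    stats::convolve(c(x, numeric(length(swell_shape))), rev(swell_shape),
                    type = "open")[seq_len(n)])
  swell[swell < 0] <- 0
  # sustained pedestal during speech plus slow multiplicative modulation
  level <- mean(env[env > 0])
  if (!is.finite(level)) level <- 1
  mod <- if (cfg$mod_depth > 0)
    vapply(seq_len(n_bands), function(b)
      slow_modulation(n, fs, depth = cfg$mod_depth), numeric(n))
  else matrix(1, n, n_bands)
  env <- (env + cfg$swell_weight * swell +
          cfg$pedestal_weight * level * mask * band_profile[col(env)]) * mod
  env <- env * mask      # no energy during pauses
  out <- spectrogram(env, fs, erb_centers(n_bands, 150, 4000),
                     role = "envelope")
  attr(out, "events_per_band") <- colSums(imp > 0)
  out
}

#' Generate a pair of independent source envelope spectrograms
#'
#' Builds attended and ignored source streams for one trial (lead-in plus
#' trial duration). During the lead-in only the attended source is active.
#' Envelopes are on a linear power scale; apply [compress_spectrogram()]
#' after mixing.
#'
#' @param cfg A [scene_config()] with a seed.
#' @return List with envelope spectrograms `att` and `ign` and the number
#'   of lead-in samples at `cfg$gen_rate` (attribute `lead_in_samples`).
#' @export
synth_sources <- function(cfg) {
  set.seed(need_seed(cfg))
  dur <- cfg$trial_duration + cfg$lead_in
  att <- synth_stream(dur, cfg)
  ign <- synth_stream(dur, cfg)
  n_lead <- round(cfg$lead_in * cfg$gen_rate)
  if (n_lead > 0) ign$values[seq_len(n_lead), ] <- 0
  out <- list(att = att, ign = ign)
  attr(out, "lead_in_samples") <- n_lead
  out
}

#' Mix two source envelope spectrograms
#'
#' Element-wise sum on the linear power scale. The mixture dominates each
#' source element-wise; compression applied afterwards makes the
#' compressed envelopes combine approximately, but not exactly, additively.
#'
#' @param att,ign Envelope spectrograms with matching axes.
#' @return The mixture envelope spectrogram.
#' @export
mix_scene <- function(att, ign) {
  stop_if_axis_mismatch(att, ign)
  spectrogram(att$values + ign$values, att$rate, att$band_centers,
              role = "envelope")
}

#' Compressive amplitude scaling
#'
#' Raises spectrogram values to a power, emulating the compressive
#' exponent of the auditory frontend.
#'
#' @param spec A `spectrogram`.
#' @param power Exponent.
#' @return A `spectrogram`.
#' @export
compress_spectrogram <- function(spec, power = 0.6) {
  spectrogram(spec$values^power, spec$rate, spec$band_centers, role = spec$role)
}

# full scene for all trials: per-trial envelope and onset spectrograms for
# att / ign / mix at response rate, lead-in trimmed
synth_scene <- function(cfg, edge_cfg = edge_detector_config()) {
  set.seed(need_seed(cfg))
  trial_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_trials)
  n_lead <- round(cfg$lead_in * cfg$rate)
  trials <- lapply(seq_len(cfg$n_trials), function(tr) {
    cfg_tr <- cfg
    cfg_tr$seed <- trial_seeds[tr]
    src <- synth_sources(cfg_tr)
    mix <- mix_scene(src$att, src$ign)
    streams <- list(att = src$att, ign = src$ign, mix = mix)
    env <- lapply(streams, compress_spectrogram)
    ons <- lapply(env, detect_edges, cfg = edge_cfg)
    trim <- function(s) {
      s <- resample_series(s, cfg$rate)
      if (n_lead > 0) s$values <- s$values[-seq_len(n_lead), , drop = FALSE]
      s
    }
    list(envelopes = lapply(env, trim), onsets = lapply(ons, trim))
  })
  trials
}

#' Build per-trial predictor sets for a named model
#'
#' Assembles the model roster for every trial of a synthetic (or real)
#' scene and l1-normalizes each predictor band by its norm over the
#' concatenated trials, so that the same scaling applies to every trial.
#'
#' @param scene List of per-trial `list(envelopes, onsets)` stream lists,
#'   as returned by the scene generator.
#' @param model_name Model roster to build (see [build_model_set()]).
#' @return List with one l1-normalized `predictor_set` per trial.
#' @export
build_model_sets <- function(scene, model_name = "stream") {
  ps_trials <- lapply(scene, function(tr)
    build_model_set(tr$envelopes, tr$onsets, model_name))
  normalize_trials(ps_trials)
}

# l1 normalization pooled over trials: each band divided by its l1 norm
# over the concatenated trials
normalize_trials <- function(ps_trials) {
  nms <- names(ps_trials[[1]]$predictors)
  norms <- lapply(nms, function(nm)
    Reduce(`+`, lapply(ps_trials, function(ps)
      colSums(abs(ps$predictors[[nm]]$values)))))
  names(norms) <- nms
  lapply(ps_trials, function(ps) {
    for (nm in nms) {
      nrm <- norms[[nm]]
      zero <- nrm == 0
      ps$predictors[[nm]]$values <-
        sweep(ps$predictors[[nm]]$values, 2, ifelse(zero, 1, nrm), "/")
      ps$predictors[[nm]]$l1_norms <- nrm
      ps$predictors[[nm]]$zero_bands <- zero
    }
    ps
  })
}

#' Ground-truth kernel template
#'
#' Parametric per-predictor kernel templates: each kernel is a two-peaked
#' temporal response (positive peak followed by a negative peak) times a
#' smooth frequency profile. Latency shifts and amplitudes are set per
#' predictor, so condition contrasts (e.g. a masked-vs-overt latency
#' delay) can be injected exactly; per-subject variation is a global
#' latency shift and gain around the template.
#'
#' @param pred_names Predictor names to assign kernels to.
#' @param pos_lat,neg_lat Template peak latencies in ms.
#' @param pos_width,neg_width Gaussian peak widths (SD, ms).
#' @param neg_rel Amplitude of the negative peak relative to the positive.
#' @param amp Named vector of per-predictor amplitudes (default 1; 0
#'   removes a predictor's contribution).
#' @param latency_shift Named vector of per-predictor latency shifts in ms
#'   added to both peaks (default 0).
#' @return Data frame of per-predictor kernel parameters, class
#'   `gt_template`.
#' @export
gt_template <- function(pred_names, pos_lat = 70, neg_lat = 130,
                        pos_width = 15, neg_width = 25, neg_rel = 0.7,
                        amp = NULL, latency_shift = NULL) {
  a <- rep(1, length(pred_names)); names(a) <- pred_names
  if (!is.null(amp)) a[names(amp)] <- amp
  sh <- rep(0, length(pred_names)); names(sh) <- pred_names
  if (!is.null(latency_shift)) sh[names(latency_shift)] <- latency_shift
  structure(data.frame(
    pred = pred_names, amp = unname(a), shift = unname(sh),
    pos_lat = pos_lat, neg_lat = neg_lat,
    pos_width = pos_width, neg_width = neg_width, neg_rel = neg_rel,
    band_center = 2.5 + 1.2 * (seq_along(pred_names) %% 4),
    stringsAsFactors = FALSE), class = c("gt_template", "data.frame"))
}

#' Materialize ground-truth kernels on a lag grid
#'
#' @param template A [gt_template()].
#' @param rate Sampling rate in Hz.
#' @param tmin,tmax Kernel lag range in ms.
#' @param n_bands Number of frequency bands.
#' @param latency_shift_global Subject-level latency shift in ms added to
#'   every predictor.
#' @param gain Subject-level multiplicative gain.
#' @return An `strf` holding the true kernels.
#' @export
gt_realize <- function(template, rate = 100, tmin = 0, tmax = 250,
                       n_bands = 8, latency_shift_global = 0, gain = 1) {
  lags_ms <- seq(tmin, tmax - 1000 / rate, by = 1000 / rate)
  kernels <- list()
  for (i in seq_len(nrow(template))) {
    p <- template[i, ]
    lat_p <- p$pos_lat + p$shift + latency_shift_global
    lat_n <- p$neg_lat + p$shift + latency_shift_global
    trf <- exp(-(lags_ms - lat_p)^2 / (2 * p$pos_width^2)) -
      p$neg_rel * exp(-(lags_ms - lat_n)^2 / (2 * p$neg_width^2))
    prof <- 0.4 + 0.6 * exp(-(seq_len(n_bands) - p$band_center)^2 / (2 * 2.5^2))
    kernels[[p$pred]] <- gain * p$amp * outer(trf, prof)
  }
  strf(kernels, lags_ms, rate)
}

#' Simulate multichannel responses from predictors and ground truth
#'
#' Channel responses are a channel weight times the sum of the predictors
#' convolved with the true kernels, plus noise scaled to a configured SNR.
#' Noise power is calibrated per channel against the signal power of that
#' channel, with the noise sample standardized so the realized SNR matches
#' the configured value exactly.
#'
#' @param ps_trials List of per-trial `predictor_set`s.
#' @param gt An `strf` of true kernels (see [gt_realize()]).
#' @param n_channels Number of response channels.
#' @param snr_db Signal-to-noise ratio in dB (`Inf` for a noiseless
#'   response).
#' @param noise `"pink"` (1/f, the default, matching neural background
#'   spectra) or `"white"`.
#' @param seed Seed for the noise draw.
#' @return List with one time-by-channel response matrix per trial.
#' @export
synth_response <- function(ps_trials, gt, n_channels = 1, snr_db = 0,
                           noise = c("pink", "white"), seed = NULL) {
  noise <- match.arg(noise)
  if (is.na(snr_db) || snr_db == -Inf)
    stop("snr_db must be a finite value or Inf (noiseless)")
  if (!is.null(seed)) set.seed(seed)
  weights <- seq(1, 0.6, length.out = n_channels)
  lapply(ps_trials, function(ps) {
    y0 <- predict(gt, ps)
    p_sig <- mean(y0^2)
    if (p_sig == 0) stop("cannot set an SNR for an all-zero signal")
    vapply(seq_len(n_channels), function(ch) {
      sig <- weights[ch] * y0
      if (is.infinite(snr_db)) return(sig)
      nz <- if (noise == "white") stats::rnorm(length(y0)) else
        pink_noise(length(y0))
      nz <- nz / stats::sd(nz) * sqrt(mean(sig^2)) * 10^(-snr_db / 20)
      sig + nz
    }, numeric(length(y0)))
  })
}

# 1/f amplitude-shaped Gaussian noise via FFT
pink_noise <- function(n) {
  nf <- stats::nextn(n, 2)
  half <- nf %/% 2
  amp <- c(0, (1 / sqrt(seq_len(half))))
  ph <- stats::runif(half, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = c(0, ph))
  full <- c(spec, Conj(rev(spec[2:half])))
  x <- Re(stats::fft(full, inverse = TRUE))
  x[seq_len(n)]
}

#' Generate a synthetic cohort with known ground truth
#'
#' All subjects hear the same stimuli (one scene per cohort); per-subject
#' ground truths are the template jittered by a global latency shift
#' (SD `variability$latency_sd` ms) and a global gain
#' (SD `variability$amp_sd`). Per-subject responses are generated at the
#' configured SNR. Every random draw descends from the master seed in
#' `cfg$seed`, and the manifest records everything needed to regenerate
#' the cohort bit-exactly.
#'
#' @param n_subjects Number of subjects.
#' @param cfg A [scene_config()] with a seed.
#' @param template A [gt_template()] for the model's predictors.
#' @param variability List with `latency_sd` (ms) and `amp_sd`
#'   (multiplicative, as SD of a normal gain around 1).
#' @param n_channels Response channels per subject.
#' @param snr_db SNR in dB.
#' @param model_name Predictor roster used both to generate and (by
#'   default) to analyze.
#' @param noise Noise color.
#' @param gt_tmin,gt_tmax Lag range of the true kernels in ms.
#' @return A list of class `synth_cohort` with `ps_trials` (shared,
#'   l1-normalized predictors), `subjects` (each with `response`, `gt`,
#'   `latency_shift`, `gain`), and `manifest`.
#' @export
synth_cohort <- function(n_subjects, cfg, template,
                         variability = list(latency_sd = 5, amp_sd = 0.1),
                         n_channels = 1, snr_db = 0, model_name = "stream",
                         noise = "pink", gt_tmin = 0, gt_tmax = 250) {
  template_in <- template
  set.seed(need_seed(cfg))
  scene_seed <- sample.int(.Machine$integer.max - 1L, 1)
  subj_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  shifts <- stats::rnorm(n_subjects, 0, variability$latency_sd)
  gains <- pmax(1 + stats::rnorm(n_subjects, 0, variability$amp_sd), 0.2)

  cfg_scene <- cfg
  cfg_scene$seed <- scene_seed
  scene <- synth_scene(cfg_scene)
  ps_trials <- build_model_sets(scene, model_name)

  # Express template amplitudes in units of response contribution: scale
  # each predictor's kernel so that, for this cohort's stimuli, the
  # standard deviation of its contribution to the noiseless response is
  # proportional to the template amplitude. Without this, predictors with
  # sparse (onset) versus dense (envelope) time courses would contribute
  # wildly different response power for the same kernel gain.
  gt0 <- gt_realize(template, rate = cfg$rate, tmin = gt_tmin, tmax = gt_tmax,
                    n_bands = ncol(ps_trials[[1]]$predictors[[1]]$values))
  contrib_sd <- vapply(template$pred, function(nm) {
    g1 <- gt0
    g1$kernels <- gt0$kernels[nm]
    stats::sd(unlist(lapply(ps_trials, function(ps) predict(g1, ps))))
  }, numeric(1))
  scale <- ifelse(contrib_sd > 0, 1 / contrib_sd, 0)
  scale <- scale / max(scale * (template$amp != 0), na.rm = TRUE)
  template$amp <- template$amp * scale

  subjects <- lapply(seq_len(n_subjects), function(i) {
    gt <- gt_realize(template, rate = cfg$rate, tmin = gt_tmin,
                     tmax = gt_tmax,
                     n_bands = ncol(ps_trials[[1]]$predictors[[1]]$values),
                     latency_shift_global = shifts[i], gain = gains[i])
    resp <- synth_response(ps_trials, gt, n_channels = n_channels,
                           snr_db = snr_db, noise = noise,
                           seed = subj_seeds[i])
    list(id = i, response = resp, gt = gt, latency_shift = shifts[i],
         gain = gains[i], seed = subj_seeds[i])
  })
  manifest <- list(n_subjects = n_subjects, cfg = unclass(cfg),
                   template = as.data.frame(template_in),
                   variability = variability, n_channels = n_channels,
                   snr_db = snr_db, model_name = model_name, noise = noise,
                   gt_tmin = gt_tmin, gt_tmax = gt_tmax,
                   scene_seed = scene_seed, subject_seeds = subj_seeds,
                   latency_shifts = shifts, gains = gains)
  structure(list(ps_trials = ps_trials, subjects = subjects,
                 template_realized = template, manifest = manifest,
                 cfg = cfg),
            class = "synth_cohort")
}

#' Regenerate a cohort from its manifest
#'
#' @param manifest The `manifest` element of a [synth_cohort()].
#' @return A `synth_cohort` identical to the original.
#' @export
synth_cohort_from_manifest <- function(manifest) {
  cfg <- do.call(scene_config, manifest$cfg)
  template <- structure(manifest$template, class = c("gt_template", "data.frame"))
  synth_cohort(manifest$n_subjects, cfg, template,
               variability = manifest$variability,
               n_channels = manifest$n_channels, snr_db = manifest$snr_db,
               model_name = manifest$model_name, noise = manifest$noise,
               gt_tmin = manifest$gt_tmin, gt_tmax = manifest$gt_tmax)
}
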