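---
title: "Encoding models of two-talker speech responses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding models of two-talker speech responses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

When a listener attends to one of two concurrent talkers, auditory cortex
responds not only to the acoustic mixture that reaches the ears but also to
features of the individual speech streams — including acoustic onsets of one
talker that are energetically masked by the other and therefore absent from
the mixture. `strfboost` implements the full modelling chain needed to study
this with forward (encoding) models: auditory predictor construction,
spectrotemporal response function (STRF) estimation by sparse boosting,
cross-validated model comparison across subjects with permutation inference,
and STRF peak analysis. A seeded synthetic-cohort generator with known
ground-truth kernels closes the loop, so that every stage can be validated
by parameter recovery rather than by eyeballing.

# The forward model

The response of a channel at time $t$ is modelled as a sum of $N$ predictor
time series $x_n$ convolved with per-predictor kernels $h_n$ over lags
$\tau$:

$$\hat y_t = \sum_n^N \sum_\tau^T h_{n,\tau}\, x_{n,t-\tau}.$$

Each predictor is an 8-band spectrogram-like array, so each $h_n$ is a
lag-by-band kernel (an STRF). Model comparisons use lags $[0, 500)$ ms;
STRF waveform analyses refit with $[-100, 500)$ ms so that the baseline is
estimated, and display/statistics windows avoid the range ends where
occasional edge artifacts occur (display $[-50, 450)$, statistics
$[0, 450)$ ms).

# Predictors

*Envelopes.* Audio is passed through a bank of 256 4th-order gammatone
filters with center frequencies spaced on the ERB scale from 20 to
5000 Hz; magnitude envelopes are integrated to 1 kHz and compressed with
exponent 0.6. The gammatone filters are implemented as complex FIR kernels
applied by FFT convolution; the envelope is the modulus of the complex
output.

*Onsets.* An auditory edge detector is applied to each band independently:
a saturating nonlinearity $s(x) = xC/(x+C)$ with $C = 30$ (Naka–Rushton
form, half-saturation at $C$; the saturation form is not uniquely
determined by its usual one-line description, and this bounded, monotone
choice applied *before* the delay layer keeps the detector's response to
ongoing speech from saturating), then a layer of 10 delayed copies, a
derivative-of-Gaussian receptive field (SD = 2 delay units) across the
delay axis, and half-wave rectification. The 10 delays are the cumulative
sums of increments linearly spaced from 3 to 5 ms (total span 40 ms),
giving the onset detector an integration window of a few tens of
milliseconds; the receptive field is shifted to exact zero sum and scaled
to unit $\ell_2$ norm, which guarantees — not just approximately but to
machine precision — that constant inputs produce no onsets.

*Masked and overt onsets.* For a source stream competing inside a mixture,
$o_{masked} = \max(o_{source} - o_{mixture}, 0)$ and
$o_{overt} = o_{source} - o_{masked} \equiv \min(o_{source}, o_{mixture})$.
The decomposition is conservative by construction: overt + masked
reconstructs the source exactly, element-wise.

*Binning and normalization.* Envelope and onset spectrograms are binned
into 8 bands equally spaced in ERB units, omitting bands below 100 Hz, by
*summation* (not averaging) within each group, so that total onset
magnitude — and with it the overt/masked $\ell_1$ bookkeeping — is
conserved. Predictors are resampled to the response rate (100 Hz) with a
unit-sum windowed-sinc FIR and negative filter overshoot clipped to zero.
Each band of each predictor is finally scaled by its $\ell_1$ norm over
time; in the synthetic pipeline the norm is computed over the concatenated
trials so that a single scaling applies to every trial (per-trial norms
would make the effective kernel vary across trials).

*Intensity levels.* For the level-dependent control model, onset events
(maximal runs of consecutive nonzero samples, per band) are assigned whole
to low/mid/high predictors by per-band intensity tertiles. Ties are broken
by sorting events on (intensity, onset time) with boundaries at ranks
$\lceil kn/3\rceil$; bands with fewer than 3 events assign the event of
rank $k$ to level $k$. Tertile boundaries are computed over the
concatenated trials, which gives stabler boundaries than per-trial ones.

# Boosting

Kernels are estimated by greedy coordinate descent on the training
$\ell_1$ error. The kernel of each predictor band is a sum of signed,
fixed-size steps of 50-ms Hamming-window basis elements centered at any
sample of the lag axis. At each iteration the (band, lag, sign) update
that most reduces the training error is applied; whenever the chosen
update for a band would strictly increase the error on a held-out
validation fold, that band is frozen, and estimation ends when all bands
are frozen. A switch (`freeze = "predictor"`) freezes all bands of a
predictor together instead; per-band freezing is the default because the
band is the unit that the validation signal actually disambiguates.

Implementation notes that matter for correctness and speed:

* Adding a Hamming-window bump at lag $l$ of predictor $x$ is equivalent to
  adding an impulse at lag $l$ against the basis-smoothed predictor
  $\tilde x = x * H$. The core therefore boosts impulses against smoothed
  predictors and convolves the coefficients with the basis window at the
  end.
* For a small step $d$, the $\ell_1$ error change of a candidate update is
  $-d \sum_t \mathrm{sign}(r_t)\, \tilde x_{t-l}$ to first order. The core
  maintains this sign-correlation for every coordinate incrementally: an
  accepted step changes $\mathrm{sign}(r_t)$ only where the residual
  crosses zero, so the update costs (sign flips) × (coordinates) rather
  than (coordinates) × (samples). Accept/freeze decisions always use
  exact error changes; the training error is asserted non-increasing
  across accepted steps. On test problems the linearized selection and a
  brute-force exact-selection implementation converge to the same
  solutions.
* The step is scale-free: 0.005 in units of (training response mean
  absolute value) per unit of (basis-smoothed predictor band mean absolute
  value). Normalizing the step by the predictor scale as well as the
  response scale is required for the fixed-step rule to be meaningful when
  predictor bands are $\ell_1$-normalized (their mean absolute values are
  then tiny and heterogeneous); it also makes the estimator exactly
  equivariant to rescaling of the response or of any predictor band.
* Convolution never crosses trial boundaries; out-of-range samples are
  zero.
* Ties in the selection are broken deterministically: lowest predictor,
  then band, then lag, which together with the fixed predictor ordering of
  the model rosters makes every fit bit-reproducible.

*Cross-validation.* Trials are assigned round-robin to 4 folds
(1, 2, 3, 4, 1, …). For model scoring, an outer loop holds out each fold;
the inner loop trains one STRF per remaining fold (that fold serving as
the validation set) and averages the three estimates to predict the
held-out fold. Held-out predictions are concatenated and scored per
channel by Pearson correlation with the measured response. For STRF
waveform analysis, four estimates are computed (each fold once as
validation set, the rest training) and averaged.

# Inference

Model comparison works on Fisher-z transformed per-channel correlations.
Per channel, a related-measures $t$ statistic is computed on the
per-subject $z$ differences between a full model and a null model with a
predictor removed; family-wise error across channels is controlled with
the permutation distribution of the maximum statistic under random sign
flips of subject difference maps. These comparisons are one-tailed
(full > null) because removing a predictor can only remove explanatory
structure. STRF contrasts use two-tailed point-wise paired $t$ tests
(sign-flip permutations, max $|t|$), and the stream-by-masking design uses
the repeated-measures interaction $F$ (equal to the squared one-sample $t$
of the per-subject double difference in a 2×2 design) with within-subject
permutation of the four condition labels. With $B$ random permutations,
$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(B+1)$, so $p \ge 1/(B+1)$;
with exhaustive sign enumeration the permutation $p$ equals the exact
test. `t_max` reports the largest statistic inside the significant
($p \le 0.05$) area and is absent — not zero — when nothing is
significant.

# STRF analysis

For group analysis, STRFs are smoothed along the frequency axis with a
unit-sum Hamming window of 7 bins (edge-renormalized over the in-range
support). Peak measurement averages a predictor's (smoothed, by default)
kernel over frequency, upsamples the resulting temporal response function
to 500 Hz by windowed-sinc interpolation — which preserves the positions
of well-separated extrema to within one 500-Hz sample, unlike linear
interpolation — and takes the extremum inside a half-open window
$[lo, hi)$: $[20, 200)$ ms for single-talker and stream analyses,
$[20, 250)$ ms for masked-onset analyses. Ties go to the earliest
latency. Peak latencies and amplitudes are compared across conditions
with paired $t$ tests; an exactly constant shift (zero-variance
difference) is reported as an exact-difference flag rather than an
infinite $t$.

# The synthetic cohort generator

The generator works at the spectrogram level: it emulates the *structure*
of two-talker speech that the analysis depends on, not speech audio
itself. Waveform synthesis would add no testable structure here because
all predictors are functions of band envelopes; the frontend's audio path
is exercised separately on tones and noise.

Each source stream is an 8-band envelope built from:

* *events* — Poisson onset events (3 per second per band during speech)
  with lognormal amplitudes, comodulated across bands with probability
  0.7, convolved with a fast-rise (≈10 ms) / ≈60 ms-decay shape;
* *swells* — slow-rise (≈150 ms) amplitude surges, 1.5 per second, which
  the edge detector is largely blind to;
* *slow modulation* — a multiplicative, low-pass (≈1.5 Hz) gain; and
* an utterance/pause timeline: utterances of mean 3 s separated by pauses
  drawn uniformly from 250–300 ms, with envelopes silenced in pauses. A
  1-s lead-in during which only the attended source is active is generated
  and then discarded, like the first second of the real trials.

The swell and modulation components are essential for identifiability, not
decoration: without them the envelope is a linear function of the event
train (envelope ≈ onsets convolved with a fixed shape), the envelope and
onset predictors span the same space, and no estimator could attribute
kernels between them. Natural speech envelopes likewise carry sustained
and slowly modulated energy that produces no acoustic edges. A sustained
per-utterance pedestal is available (`pedestal_weight`) but defaults to
zero because its near-DC content degrades kernel identifiability while
adding little realism at the 100-Hz analysis rate.

Mixtures are formed by adding the two sources' *linear-power* envelopes
and compressing all three streams with the same exponent 0.6 as the audio
frontend; compression after summation makes compressed envelopes combine
approximately — but deliberately not exactly — additively, as in real
audio. Onset spectrograms are computed by running the edge detector on
each compressed stream independently (onsets do not add; a source onset
can be masked in the mixture). Generation runs at 500 Hz, which resolves
the edge detector's delay layer, and is then resampled to the 100-Hz
analysis rate.

Ground-truth kernels are parametric: a positive peak (70 ms, SD 15 ms)
followed by a negative peak (130 ms, SD 25 ms), times a smooth frequency
profile, with per-predictor amplitudes and latency shifts (used to inject,
e.g., a masked-vs-overt delay exactly). Per-subject variability is a
global latency shift (SD 5 ms) and gain (SD 10%) around the template —
modelling between-subject differences as overall response timing/strength
differences, so injected condition contrasts are preserved within subject.
Kernels are realized from the continuous parameters on the lag grid, so
injected latencies are not quantized to response samples. Template
amplitudes are expressed in units of *response contribution*: each
predictor's kernel is scaled so the standard deviation of its contribution
to the noiseless response matches the template amplitude for the cohort's
actual stimuli. Without this, a dense envelope predictor and a sparse
onset predictor with equal kernel gain would contribute incomparably
different response power, and "all predictors drive the response" would be
false in practice.

Responses are channel weights times the summed kernel convolutions plus
noise — pink (1/f) by default, matching neural background spectra — with
the noise draw standardized so the realized SNR equals the configured
value exactly. All randomness descends from one master seed through
per-scene and per-subject subseeds; the cohort manifest records everything
needed to regenerate a cohort bit-exactly. All subjects hear the same
stimuli, as in the experimental design being emulated.

# What recovery tests do and do not show

At the validation scale used in the tests (cohorts of 4–12 subjects, four
1-minute trials at 100 Hz, SNR 0 dB, one channel), the pipeline recovers
onset-family kernels with grand-average frequency-smoothed correlations of
roughly 0.8–0.9 against ground truth and positive peak latencies within
about 2 ms; the model-comparison permutation test is calibrated (type-I
error at the nominal level) with essentially full power for a truly
contributing predictor; and when responses are generated from the mixture
predictors only, the source predictors' cross-validated model gain is
correctly non-significant.

Three quantities are recovered *imperfectly*, in a consistent and
instructive way, and the validation reports them honestly rather than
hiding them:

* *Onset-kernel negative peaks* (and, much more strongly, all envelope
  peaks) are biased late or early by the same mechanism that limits
  envelope kernels below: positive peak latencies come back within about
  2 ms, negative ones within about 15 ms.
* *Envelope-family kernels* reach correlations of only about 0.5. This is
  not a data-identifiability limit — an ordinary least-squares
  deconvolution on the same data recovers the envelope kernels essentially
  perfectly — but a property of the estimator class: with strongly
  autocorrelated, mutually correlated predictors (an envelope and the
  onsets derived from it; a mixture envelope and its two sources),
  early-stopped greedy boosting distributes shared variance along a ridge
  of near-equivalent solutions and stops wherever the validation rule
  freezes the path. Smaller steps, the alternative freezing granularity,
  and more data move the result very little (all three were checked).
* *Injected masked-vs-overt latency shifts* are recovered monotonically
  but shrunk by roughly 20% (an injected 20 ms reads out near 16 ms):
  the element-wise masked/overt decomposition splits single events into
  both predictors, the two time series share variance, and the greedy fit
  pulls the two kernels' peaks toward each other.
* *Kernel mass in a contamination scenario* (response driven by mixture
  predictors only) is split between the near-collinear mixture and source
  predictors instead of concentrating on the mixture, even though the
  *prediction gain* of the source predictors is correctly null. Mass
  allocation between predictors whose sum is nearly another predictor is
  simply not identified, and the greedy path divides it.

These biases are shared by the estimator as used in practice on real
recordings; recovery numbers for correlated predictors characterize the
method, not a bug in the generator or the fit. Synthetic scenes also
simplify reality in ways that matter for interpretation: envelopes are
stationary mixtures of three components rather than speech, noise is
additive and stationary, and there is no head geometry, so passing these
tests demonstrates algorithmic correctness and calibration, not
neuroscientific validity on real MEG data.

# Problem sizes and numerical choices

The validation suite uses cohorts of 12 subjects for stream-model kernel
recovery, 4–5 subjects for the masked-model latency-shift and
contamination analyses, four 1-minute trials per subject, one response
channel, and
reduced permutation counts (500–2000) for Monte-Carlo calibration checks;
inference calibration (type-I error and power of the model-comparison
test) is measured on forward-model fits with known kernels, which isolates
the test's operating characteristics from estimator variance. These sizes
were chosen so the whole validation runs comfortably on a laptop-class
machine while leaving the statistical conclusions unambiguous.

Degenerate inputs are handled explicitly: zero-variance responses return
zero STRFs with a warning; all-zero predictor bands are flagged and left
unscaled by the $\ell_1$ normalization; bands with fewer events than
intensity levels assign events by rank; zero-variance peak differences
are flagged as exact; and the edge detector refuses spectrogram rates too
low to resolve its delay layer rather than silently collapsing taps.
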