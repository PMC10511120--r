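---
title: "Methods: psychoacoustic features and Bayesian models of chord stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: psychoacoustic features and Bayesian models of chord stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

In cross-cultural studies of consonance and dissonance, a useful
operationalization of a chord's *stability* is "finishedness": in each
trial a listener hears an ordered pair of chords, then the same pair in
reverse order, and chooses which of the two pairs sounds finished. The
probability of choosing the second pair can then be modelled from
psychoacoustic properties of the sounds — properties that exist in the
audio signal itself, independent of any music-theoretic labelling. This
package implements that full chain: symbolic chord construction, audio
rendering, feature extraction, response screening, and the Bayesian
models that turn screened responses into directional hypothesis tests
and latent chord-type scalings, together with a synthetic-data
generator with known ground truth so every stage can be validated
without access to field data.

## Stimuli

Chords are written as semitone pitch numbers (69 = 440 Hz, 12-tone
equal temperament). Dyads are described by their *width* (semitones
between the two tones); triads by Tn-type — the octave-reduced set of
offsets above a root, which ignores transposition, timbre and octave
placement. Seven triad types are built in (`tn_types()`): major, minor,
augmented, the semitone cluster, a dominant-seventh subset (root,
third, seventh), a half-diminished subset (root, fifth, seventh), and a
seventh chord without its third.

`enumerate_dyad_pairs()` enumerates ordered pairs of dyad widths 0–15
whose widths differ by at most 3 semitones and whose mean pitches
differ by at most 0.5 semitones. The enumeration interpretation is a
genuine design choice: we enumerate ordered width pairs (including
equal widths) and realize each dyad at a common mean pitch, which
satisfies the mean-pitch constraint by construction. Under this
interpretation the enumeration yields 100 ordered pairs; the count is
reported by message rather than asserted, because published
descriptions of comparable stimulus sets are ambiguous about which
realizations count as distinct, and no analysis in this package depends
on the exact count. Triad-type pairs are realized with the second
triad's root shifted so the two mean pitches agree as closely as
integer roots allow. Open voicing raises the middle tone of a closed
triad by one octave — the most common textbook open-position
realization. `build_stimulus_sets()` assembles counterbalanced
versions (60 dyad pairs split over two 30-trial blocks, 42 triad
pairs in one block, two timbres alternating across versions, seeded
uniform transpositions within one octave).

## Synthesis

`render_chord()` uses additive synthesis: each chord tone contributes
harmonics *h·f0* (*h* = 1, 2, …) with amplitudes from a timbre preset,
partials at or above Nyquist dropped, the sum peak-normalized with
10 ms raised-cosine fades. The `"idealized"` preset is 36 harmonics
with amplitude 1/*h* — the conventional idealized harmonic complex
tone. Two further presets (`"vocal"`, a 1/*h* spectrum shaped by two
broad formant bumps; `"string"`, 1/*h* with a mild high-frequency
boost) provide spectrally plausible timbre variation for testing
feature robustness; they emulate no specific instrument, and no claim
is made that features computed from them match those of any particular
recorded stimulus set — roughness in particular depends on the exact
level of every partial. Defaults: 44.1 kHz, 1 s. WAV I/O is 16-bit PCM
mono (stereo accepted on read, averaged down).

## Psychoacoustic features

Four predictors are computed per chord, the first three from the
signal, the last from notation:

* **Roughness** — rapid beating between unresolved partials. Computed
  on the extracted partial spectrum as a sum over unordered pairs of
  partials of an amplitude-product-weighted Plomp–Levelt dissonance
  kernel in the Sethares parameterization
  $g(\Delta f) = a_1 a_2\,(e^{-3.51 s \Delta f} - e^{-5.75 s \Delta f})$
  with $s = 0.24/(0.0207 f_{\min} + 18.96)$. The kernel is zero at
  unison, peaks near a quarter of the critical bandwidth, and decays
  for wide separations. The constants are the published Sethares
  values; the implementation is pinned by a brute-force oracle test to
  10⁻⁹. Amplitude-product weighting means doubling all amplitudes
  quadruples roughness.
* **Harmonicity** — similarity of the spectrum to a single harmonic
  complex tone, given the inaccuracy of pitch perception. The partial
  spectrum is projected on a 1-cent log-frequency grid, each partial
  smoothed into a Gaussian of 6 cents SD (area = amplitude); the
  feature is the maximum over fundamental positions of the cosine
  similarity with an equally smoothed 12-harmonic template with
  amplitude roll-off *h*^−0.75. Anchoring the grid at the first
  partial makes the measure *exactly* invariant to transposition and
  amplitude scaling. Smoothing SD and template shape are configurable
  constants in the range used by published spectral-pitch-similarity
  models; they are pinned by invariance and ordinal tests (octave more
  harmonic than tritone, detuned partials score lower) rather than by
  constants no public source states.
* **Spectral entropy** — Shannon entropy (nats) of the same smoothed
  weight vector normalized to a distribution: 0 for a single bin,
  ln *N* for a uniform spectrum. The log base is a convention only,
  since the predictor is standardized downstream.
* **Mean pitch** — arithmetic mean of the notated semitone pitches.

Partial extraction takes Hann-windowed FFT peaks above a −60 dB floor
relative to the strongest peak, with quadratic interpolation of log
magnitude for sub-bin frequency refinement.

Each trial's predictors are the feature changes from the penultimate
(third) to the final (fourth) chord; because the second pair reverses
the first, these are the negatives of the first-to-second changes, so
one delta per feature identifies the trial. Roughness, harmonicity and
entropy deltas are z-scored over the trial set; the mean-pitch delta
stays in semitones for interpretability. The scaling is persisted so
new data can be standardized identically.

Features can also be computed on the idealized notation-based spectrum
(`source = "idealized"`): this path is faster and fully deterministic,
and is labelled as such in the output. Audio-based and idealized
features differ — that divergence is part of the motivation for
computing features from signals at all.

## Screening

Blocks in which a participant always answered "one", always "two", or
strictly alternated over the whole block indicate the task was not
performed; `screen_blocks()` removes such blocks wholesale (a single
break in alternation retains the block; a length-one block counts as
constant). Screening is blockwise — a participant can lose one block
and keep another — and idempotent. Whether the two 30-trial dyad
blocks screen as one unit or two is decided by how the caller labels
`block`; the pipeline default treats them as two.

## The stability model

Responses (1 = first pair, 2 = second pair) are Bernoulli with a logit
link on an indicator of choosing the second pair. For every exposure
group *g* independently:

$$\mathrm{logit}\, P(y_i = 2) = \beta_{0,g} + \sum_k \beta_{k,g} x_{ik}
  + \gamma_g t_i + \sum_k \delta_{k,g} x_{ik} t_i
  + u_{0,p(i)} + \sum_k u_{k,p(i)} x_{ik}$$

with *t* the sum-coded trial type (dyads +1, triads −1, so each
feature's main effect is its coefficient at *t* = 0) and *u* the
participant effects. Coefficients are fully group-indexed rather than
parameterized as reference-group-plus-contrast, because per-group
effects are the quantities of interest and no information may pool
across groups. Population effects have Student-t(3, 0, 1) priors —
weakly informative, regularizing weakly identified effects towards
zero. Participant effects are partially pooled within (and only
within) each group.

Two deliberate design choices where the design was open:

* **Random-effect structure.** Participant intercept and all included
  feature slopes vary by participant, with *independent* (diagonal)
  random effects and half-Normal(1) priors on the SDs. A correlated
  (LKJ-prior) structure is conceptually attractive, but the Gibbs
  engine used here (JAGS) has no native LKJ distribution and
  equicorrelated substitutes mix poorly; with dozens of participants
  per group and ~100 trials each, slope–intercept correlations are
  weakly identified and their omission does not bias the population
  coefficients, which is what the analysis reports. The synthetic-data
  generator *can* generate correlated effects, so the robustness of
  the diagonal fit to that misspecification is testable.
* **Main effects** are reported as the coefficient at trial-type 0,
  not as an average over trial types. These coincide for balanced
  data under sum coding; the coefficient version is well-defined for
  unbalanced data too.

Sampling is Gibbs/slice via JAGS, default 4 chains × (500 adapt + 500
warmup + 1000 draws); fixed seeds reproduce draws exactly. Split-R̂
(each chain halved) and effective sample sizes are attached; any
split-R̂ above 1.01 triggers a warning naming the coefficient.

## Hypothesis summaries

For each directional hypothesis (roughness, entropy < 0; harmonicity,
mean pitch > 0) the summary reports the posterior mean, the 90%
equal-tailed interval, the posterior probability of the hypothesized
sign, the evidence ratio *p*/(1−*p*) (19 ↔ *p* = 0.95 is the
conventional "strong evidence" threshold for a directional test; 39
for a bidirectional one), and the posterior mass inside the region of
practical equivalence [−0.036, 0.036]. When every draw falls on one
side, the evidence ratio exceeds the resolution of the posterior
sample and is reported as the bound "> (draws − 1)" — e.g. ">19999.00"
at 20 000 draws. Bayes factors are deliberately not computed; the ROPE
approach is far less prior-sensitive.

## Model comparison

`compare_predictor_subsets()` fits all (or a configured list of)
non-empty predictor subsets and compares them by PSIS-LOO: per
observation, importance ratios are reciprocal likelihoods over the
posterior draws; the largest 20% of each observation's log ratios are
smoothed against a generalized Pareto distribution fitted by the
Zhang–Stephens posterior-mean estimator (with the standard
small-sample shape regularization); weights are truncated at the raw
maximum; Pareto *k* above 0.7 is flagged. The ELPD difference to the
best model is reported with the paired standard error computed from
pointwise ELPD differences.

## The Thurstone chord-type model

For description by chord type rather than by features, a multilevel
Thurstone paired-comparison model places each Tn-type on a normally
distributed latent scale per group: the probability of choosing the
second pair is Φ of the latent difference between the two pairs' final
chord types plus a participant effect (pooled within group). The
reference type (unison for dyads, semitone cluster for triads) is
pinned at exactly 0; free latents have Normal(0, 2) priors, wide
relative to the plausible ±2 SD range of latent differences.
Probabilities are clamped to [10⁻⁹, 1−10⁻⁹] for numerical safety at
extreme latent differences.

## Synthetic data and what passing tests show

`simulate_experiment()` draws participant effects from the configured
multivariate normal, forms the linear predictor from known
coefficients, and draws Bernoulli responses — exactly the fitted
model's generative counterpart. The default scenario mirrors the
five-exposure-group design at its reported effect magnitudes
(roughness −0.13/−0.09/−0.10/−0.29/−0.85 across groups, harmonicity up
to +0.15 in the musician group, no entropy effect), with
post-screening group sizes (22/39/83/60/19), 102 trials per
participant, random-intercept SD 0.3, slope SDs 0.1, uncorrelated —
the random-effect magnitudes are not published and were chosen once as
plausible for forced-choice data of this kind. The mean-pitch delta is
drawn at SD 0.52 semitones, the dispersion of the original stimulus
set. Feature deltas come either from a fast parametric source
(standard normal) or from the package's own enumerated, rendered and
standardized stimulus pairs, which exercises the feature stage end to
end. Pathological blocks (constant/alternating, round-robin) can be
injected at a configured fraction for screening tests.

The generator emulates the *statistical* structure of the experiment,
not its field conditions: no acoustic noise, no headphone transfer
functions, no drift in attention, and timbres that only stand in for
the recorded sample libraries. Passing recovery tests therefore shows
the inference machinery is correct and well calibrated under the
model's own assumptions — it cannot show that the model is adequate
for any particular field dataset.

## Validation problem sizes

The recovery studies are sized to be informative yet routine to run:
the large-effect scenario uses one group of 40 participants × 72
trials (true roughness coefficient −0.85) and the small-effect
scenario 60 × 100 (−0.13); interval-coverage calibration uses 20
seeded replicates of the 40 × 72 design with truths (−0.85, +0.15,
−0.03) and 2-chain samplers; model-subset selection uses 20 replicates
of a 20 × 48 design without an entropy effect, comparing the
three-predictor and four-predictor models by PSIS-LOO; Thurstone
recovery uses 8 types × 50 participants. These choices are the
package's own validation design.

## Known limitations

* Feature values are not numerically comparable to any proprietary
  toolbox; only the documented formulas and their tested properties
  define them.
* The roughness kernel operates on extracted partials, not on a
  cochlear filterbank; masking and loudness models are out of scope.
* Independent random effects (see above); the generator can produce
  correlated effects the fit ignores.
* The evidence-ratio saturation bound depends on the draw count;
  comparisons across fits with different draw counts should use
  posterior probabilities instead.
* JAGS slice sampling mixes slowly for weakly identified random-slope
  SDs; their R̂ warnings at short chain lengths are expected and do
  not affect the population coefficients appreciably.
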