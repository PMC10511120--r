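# chordstab

Tools for studying whether psychoacoustic properties of chords predict
judgements of musical *stability* — operationalized as which of two
chord progressions sounds "finished" — across listener groups with
different exposure to Western-like music.

In each trial a listener hears an ordered pair of chords, then the same
pair reversed, and picks the pair that sounds finished. The probability
of choosing the second pair is modelled from per-trial changes (third
chord → fourth chord) in four predictors:

* **roughness** — beating between unresolved partials, computed as an
  amplitude-weighted sum of a Plomp–Levelt dissonance kernel
  (Sethares parameterization) over all pairs of spectral partials;
* **harmonicity** — maximal cosine similarity between the perceptually
  smoothed log-frequency spectrum and a smoothed harmonic template;
* **spectral entropy** — Shannon entropy of the smoothed spectrum;
* **mean pitch** — mean of the notated pitches in semitones.

The core model is a Bayesian multilevel logistic regression fitted with
JAGS: for each exposure group *g* separately (no pooling across
groups),

    logit P(choose pair two) = b0[g] + Σk bk[g]·Δxk (+ trial-type terms)
                               + participant intercept and slopes,

with Student-t(3, 0, 1) priors on population effects and participant
effects partially pooled within group. Directional hypotheses are
summarized by posterior probabilities, evidence ratios p/(1−p), and the
posterior mass in the region of practical equivalence [−0.036, 0.036].
Predictor subsets are compared by PSIS-LOO (Pareto-smoothed importance
sampling, implemented from pointwise log-likelihoods). A multilevel
Thurstone (probit) paired-comparison model scales chord types on a
latent "finishedness" axis relative to a reference type. A
synthetic-experiment generator with recorded ground truth makes every
stage testable end to end; it is first-class, tested code, not a
fixture.

The package is written tidyverse-style: data frames in, tibbles out,
`tidy()`/`glance()` methods on fits, `autoplot()` for each result type.

## Worked example

Simulate one exposure group with a strong negative roughness effect,
screen it, fit the stability model, and summarize the directional
hypothesis:

```r
library(chordstab)
library(tibble)

cfg <- simulation_config(
  groups = tibble(group = "musicians", n_participants = 20L,
                  intercept = 0, d_roughness = -0.85, d_harmonicity = 0.15,
                  d_spectral_entropy = 0, d_mean_pitch = -0.03),
  trials_per_participant = 72L,
  re_sd = c(intercept = 0.3, d_roughness = 0.1, d_harmonicity = 0.1,
            d_spectral_entropy = 0.1, d_mean_pitch = 0.1))
sim <- simulate_experiment(cfg, seed = 1)
scr <- screen_blocks(sim$trials)
fit <- fit_stability_model(scr$retained,
                           predictors = c("d_roughness", "d_harmonicity",
                                          "d_mean_pitch"),
                           chains = 2, seed = 1)
hypothesis_table(fit)
```

```
# A tibble: 3 × 10
  group     coefficient   hypothesis    mean      q5     q95 evid_ratio
  <chr>     <chr>         <chr>        <dbl>   <dbl>   <dbl>      <dbl>
1 musicians d_roughness   <0         -0.945  -1.11   -0.779    1999
2 musicians d_harmonicity >0          0.0560 -0.0852  0.195       3.01
3 musicians d_mean_pitch  >0         -0.166  -0.450   0.0996      0.195
  evid_ratio_label post_p rope_prob
  <chr>             <dbl>     <dbl>
1 >1999.00          1         0
2 3.01              0.750     0.244
3 0.20              0.164     0.107
```

Reading the first row: the posterior mean effect of a one-SD increase
in Δroughness is −0.95 log-odds with 90% interval [−1.11, −0.78];
every posterior draw is negative, so the evidence ratio saturates at
the draw-resolution bound (">1999.00" with 2000 draws) and no
posterior mass lies in the ROPE — strong evidence that rising
roughness makes the second pair sound less finished, consistent with
the generating coefficient of −0.85. The smaller generating effects
(+0.15 harmonicity, −0.03 mean pitch per semitone) are not
distinguishable from zero at 20 participants: their evidence ratios
(3.01 and 0.20) stay far below the conventional threshold of 19.

`recovery_report(sim, fit)` tabulates truth vs posterior with coverage
flags; `predict_choice_curve()` + `plot_choice_curve()` draw the
predicted-probability curves; `fit_thurstone()` + `autoplot()` give
the latent chord-type scaling.

Features can be computed directly from audio:

```r
chord_features(c(60, 64, 67), source = "audio")   # renders, then measures
chord_features(c(60, 64, 67), source = "idealized")
```

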