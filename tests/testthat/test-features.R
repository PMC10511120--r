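test_that("roughness matches the brute-force pairwise-kernel oracle", {
  expect_equal(roughness(partial_spectrum(440, 1)), 0)
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:20, 1)
    freq <- sort(runif(n, 50, 5000))
    freq <- freq + seq_len(n) * 1e-6        # ensure strictly increasing
    amp <- runif(n, 0, 2)
    expect_equal(roughness(partial_spectrum(freq, amp)),
                 oracle_roughness(freq, amp), tolerance = 1e-9)
  }
})

test_that("roughness orders semitone above octave and scales with amplitude product", {
  semi <- roughness(partial_spectrum(c(440, 466.16), c(1, 1)))
  oct <- roughness(partial_spectrum(c(440, 880), c(1, 1)))
  expect_gt(semi, oct)
  doubled <- roughness(partial_spectrum(c(440, 466.16), c(2, 2)))
  expect_equal(doubled, 4 * semi, tolerance = 1e-12)
})

test_that("smoothing conserves each partial's weight and is linear", {
  one <- smooth_spectrum(partial_spectrum(440, 1.7))
  expect_equal(sum(one$weights), 1.7, tolerance = 1e-6)
  two <- smooth_spectrum(partial_spectrum(440, 3.4))
  expect_equal(two$weights, 2 * one$weights, tolerance = 1e-12)
  # sd -> 0 limit: all mass within one bin of the partial position
  tight <- smooth_spectrum(partial_spectrum(440, 1), sd = 1e-3)
  expect_equal(max(tight$weights), 1, tolerance = 1e-6)
})

test_that("harmonicity is 1 for the template, bounded, and invariant", {
  tmpl <- harmonic_template()
  base <- harmonicity(smooth_spectrum(tmpl))
  expect_equal(base, 1, tolerance = 1e-9)
  # transposition invariance (arbitrary cents offsets)
  for (cents in c(37, 137.25, -250.5)) {
    shifted <- partial_spectrum(tmpl$frequency * 2^(cents / 1200),
                                tmpl$amplitude)
    expect_equal(harmonicity(smooth_spectrum(shifted)), base,
                 tolerance = 1e-6)
  }
  # amplitude-scale invariance
  scaled <- partial_spectrum(tmpl$frequency, tmpl$amplitude * 13.7)
  expect_equal(harmonicity(smooth_spectrum(scaled)), base, tolerance = 1e-6)
  # range on arbitrary spectra
  set.seed(7)
  for (rep in 1:10) {
    f <- sort(runif(8, 100, 4000)) + (1:8) * 1e-6
    h <- harmonicity(smooth_spectrum(partial_spectrum(f, runif(8))))
    expect_gte(h, 0); expect_lte(h, 1)
  }
})

test_that("inharmonicity lowers the template match", {
  f <- 100 * (1:10)
  f[2:10] <- f[2:10] * 2^(37 / 1200)   # all but the fundamental +37 cents
  detuned <- harmonicity(smooth_spectrum(partial_spectrum(f, (1:10)^-0.75)))
  expect_lt(detuned, 1)
  harmonic <- harmonicity(smooth_spectrum(harmonic_template(10)))
  expect_lt(detuned, harmonic)
})

test_that("spectral entropy hits its closed-form bounds", {
  degenerate <- structure(list(weights = c(0, 5, 0), resolution = 1,
                               sd = 6, origin = 0),
                          class = "smoothed_spectrum")
  expect_equal(spectral_entropy(degenerate), 0)
  uniform <- structure(list(weights = rep(2, 128), resolution = 1,
                            sd = 6, origin = 0),
                       class = "smoothed_spectrum")
  expect_equal(spectral_entropy(uniform), log(128), tolerance = 1e-12)
  # amplitude-rescaling invariance
  sm <- smooth_spectrum(idealized_partials(c(60, 64, 67), 12))
  sm2 <- sm; sm2$weights <- sm$weights * 9.1
  expect_equal(spectral_entropy(sm2), spectral_entropy(sm))
  # a cluster spreads more spectral mass than a single tone
  cluster <- smooth_spectrum(idealized_partials(c(60, 61, 62), 12))
  single <- smooth_spectrum(idealized_partials(60, 12))
  expect_gt(spectral_entropy(cluster), spectral_entropy(single))
  zero <- structure(list(weights = c(0, 0), resolution = 1, sd = 6,
                         origin = 0), class = "smoothed_spectrum")
  expect_error(spectral_entropy(zero), "all-zero")
})

test_that("ordinal feature checks hold on idealized 36-harmonic renders", {
  feats <- function(pitches) {
    chord_features(pitches, source = "audio",
                   timbre = timbre_preset("idealized"),
                   duration = 0.3, sample_rate = 22050)
  }
  expect_gt(feats(c(60, 61))$roughness, feats(c(60, 67))$roughness)
  expect_gt(feats(c(60, 72))$harmonicity, feats(c(60, 66))$harmonicity)
  # orderings stable across the two non-idealized presets
  for (tb in c("vocal", "string")) {
    f <- function(p) chord_features(p, source = "audio",
                                    timbre = timbre_preset(tb),
                                    duration = 0.3, sample_rate = 22050)
    expect_gt(f(c(60, 61))$roughness, f(c(60, 67))$roughness)
    expect_gt(f(c(60, 72))$harmonicity, f(c(60, 66))$harmonicity)
  }
})

test_that("mean pitch is the arithmetic mean of notated pitches", {
  expect_equal(mean_pitch(c(60, 64, 67)), 63.667, tolerance = 1e-3)
  expect_equal(mean_pitch(c(60, 64, 67) + 2), mean_pitch(c(60, 64, 67)) + 2)
  expect_equal(mean_pitch(c(60, 60)), 60)
})

test_that("delta features are antisymmetric by construction", {
  a <- chord_features(c(60, 64, 67), source = "idealized")
  b <- chord_features(c(60, 63, 67), source = "idealized")
  d <- delta_features(a, b)
  dr <- delta_features(b, a)
  expect_equal(unlist(d), -unlist(dr))
  expect_equal(unlist(delta_features(a, a)), rep(0, 4), ignore_attr = TRUE)
  expect_equal(d$d_mean_pitch, b$mean_pitch - a$mean_pitch)
})

test_that("standardization z-scores audio features and leaves mean pitch alone", {
  set.seed(1)
  trials <- tibble::tibble(
    d_roughness = rnorm(50, 2, 3),
    d_harmonicity = rnorm(50),
    d_spectral_entropy = rnorm(50, -1, 0.2),
    d_mean_pitch = rnorm(50, 0, 0.5)
  )
  z <- standardize_deltas(trials)
  for (col in c("d_roughness", "d_harmonicity", "d_spectral_entropy")) {
    expect_equal(mean(z[[col]]), 0, tolerance = 1e-8)
    expect_equal(sd(z[[col]]), 1, tolerance = 1e-8)
  }
  expect_identical(z$d_mean_pitch, trials$d_mean_pitch)
  # persisted scaling reapplies identically
  z2 <- apply_delta_scaling(trials, attr(z, "scaling"))
  expect_equal(as.data.frame(z2), as.data.frame(z))
  degen <- trials; degen$d_roughness <- 1
  expect_error(standardize_deltas(degen), "d_roughness")
})

test_that("partial extraction refines frequencies and rejects silence", {
  sr <- 8000
  x <- sin(2 * pi * 1000.3 * (0:7999) / sr)
  p <- extract_partials(list(samples = x, sample_rate = sr))
  expect_equal(nrow(p), 1)
  expect_lt(abs(p$frequency - 1000.3), 0.5)
  expect_error(extract_partials(list(samples = rep(0, 100),
                                     sample_rate = sr)), "silent")
})
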