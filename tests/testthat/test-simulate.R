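test_that("simulation is reproducible and records its generative law", {
  cfg <- small_sim_config(8, 20)
  a <- simulate_experiment(cfg, seed = 9)
  b <- simulate_experiment(cfg, seed = 9)
  expect_identical(a$trials, b$trials)
  c <- simulate_experiment(cfg, seed = 10)
  expect_false(identical(a$trials, c$trials))
  # the recorded probability is exactly the inverse logit of the linear
  # predictor implied by the recorded ground truth
  eff <- a$truth$participant_effects
  tr <- dplyr::left_join(a$trials, eff, by = c("participant", "group"))
  beta <- cfg$groups
  eta <- beta$intercept + tr$u_intercept +
    tr$d_roughness * (beta$d_roughness + tr$u_d_roughness) +
    tr$d_harmonicity * (beta$d_harmonicity + tr$u_d_harmonicity) +
    tr$d_spectral_entropy * (beta$d_spectral_entropy +
                               tr$u_d_spectral_entropy) +
    tr$d_mean_pitch * (beta$d_mean_pitch + tr$u_d_mean_pitch)
  expect_equal(tr$prob, plogis(eta), tolerance = 1e-12)
})

test_that("reversing a pair flips the deltas and complements the probability", {
  # negating every coefficient with identical deltas (same seed) is
  # equivalent to presenting every reversed pair: probabilities must
  # complement exactly when all intercept terms are zero
  cfg_fwd <- small_sim_config(6, 25, intercept = 0, re_int = 0,
                              re_slope = 0)
  cfg_rev <- small_sim_config(6, 25, intercept = 0, re_int = 0,
                              re_slope = 0,
                              d_roughness = 0.8, d_harmonicity = -0.2)
  fwd <- simulate_experiment(cfg_fwd, seed = 3)
  rev <- simulate_experiment(cfg_rev, seed = 3)
  expect_equal(fwd$trials$d_roughness, rev$trials$d_roughness)
  expect_equal(rev$trials$prob, 1 - fwd$trials$prob, tolerance = 1e-12)
})

test_that("empirical choice frequencies converge to the generating law", {
  cfg <- simulation_config(
    groups = tibble::tibble(group = "A", n_participants = 1L,
                            intercept = -0.85, d_roughness = 0,
                            d_harmonicity = 0, d_spectral_entropy = 0,
                            d_mean_pitch = 0),
    trials_per_participant = 100000L,
    re_sd = c(intercept = 0, d_roughness = 0, d_harmonicity = 0,
              d_spectral_entropy = 0, d_mean_pitch = 0))
  sim <- simulate_experiment(cfg, seed = 77)
  expect_equal(mean(sim$trials$response == 2L), plogis(-0.85),
               tolerance = 0.01)
})

test_that("null effects give an even pooled choice rate", {
  cfg <- small_sim_config(10, 200, d_roughness = 0, d_harmonicity = 0,
                          re_int = 0, re_slope = 0)
  sim <- simulate_experiment(cfg, seed = 21)
  n <- nrow(sim$trials)
  expect_lt(abs(mean(sim$trials$response == 2L) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("injected pathological blocks are exactly the ones screening removes", {
  cfg <- simulation_config(
    groups = tibble::tibble(group = "A", n_participants = 50L,
                            intercept = 0, d_roughness = -0.3,
                            d_harmonicity = 0, d_spectral_entropy = 0,
                            d_mean_pitch = 0),
    trials_per_participant = 60L,     # two 30-trial dyad blocks each
    pathological_fraction = 0.27)
  sim <- simulate_experiment(cfg, seed = 8)
  blocks <- dplyr::distinct(sim$trials, participant, block)
  expect_equal(nrow(blocks), 100)
  flagged <- dplyr::distinct(sim$trials[sim$trials$pathological, ],
                             participant, block)
  expect_equal(nrow(flagged), 27)
  res <- screen_blocks(sim$trials)
  removed <- dplyr::select(res$exclusions, participant, block)
  expect_setequal(paste(removed$participant, removed$block),
                  paste(flagged$participant, flagged$block))
})

test_that("the stimulus-derived delta source exercises the feature stage", {
  pool <- chordstab:::stimulus_delta_pool()
  expect_true(all(c("d_roughness", "d_harmonicity", "d_spectral_entropy",
                    "d_mean_pitch") %in% names(pool)))
  expect_gt(nrow(pool), 100)
  expect_equal(mean(pool$d_roughness), 0, tolerance = 1e-8)
  expect_equal(sd(pool$d_roughness), 1, tolerance = 1e-8)
  # mean pitch stays in semitones
  expect_false(isTRUE(all.equal(sd(pool$d_mean_pitch), 1)))
})

test_that("recovery reports flag interval coverage with closed bounds", {
  sim <- simulate_experiment(small_sim_config(10, 30), seed = 19)
  trials <- sim$trials; trials$trial_type <- NULL
  fit <- fit_fast(trials, c("d_roughness", "d_harmonicity"), seed = 2)
  rep <- suppressWarnings(recovery_report(sim, fit))
  expect_true(all(c("group", "term", "true_value", "estimate", "q5", "q95",
                    "covered") %in% names(rep)))
  expect_true("d_roughness" %in% rep$term)
  # closed-interval convention: truth exactly on a boundary is covered
  rep2 <- rep
  rep2$true_value <- rep2$q5
  expect_true(all(rep2$true_value >= rep2$q5 & rep2$true_value <= rep2$q95))
  # coefficients simulated but not fitted are dropped with a warning
  expect_warning(recovery_report(sim, fit), "excluded")
})

test_that("invalid random-effect correlations are rejected", {
  expect_error(
    simulate_experiment(
      simulation_config(re_cor = -0.5,
                        re_sd = c(intercept = 1, d_roughness = 1,
                                  d_harmonicity = 1, d_spectral_entropy = 1,
                                  d_mean_pitch = 1)),
      seed = 1),
    "correlation")
})
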