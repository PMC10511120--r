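# Shared small fixtures, built in code at test time.

# one-group simulation config used by several fit tests
small_sim_config <- function(n_participants = 12L, trials = 40L,
                             d_roughness = -0.8, d_harmonicity = 0.2,
                             intercept = 0, re_int = 0.3, re_slope = 0.1) {
  simulation_config(
    groups = tibble::tibble(
      group = "A", n_participants = as.integer(n_participants),
      intercept = intercept,
      d_roughness = d_roughness, d_harmonicity = d_harmonicity,
      d_spectral_entropy = 0, d_mean_pitch = 0
    ),
    trials_per_participant = as.integer(trials),
    re_sd = c(intercept = re_int, d_roughness = re_slope,
              d_harmonicity = re_slope, d_spectral_entropy = re_slope,
              d_mean_pitch = re_slope)
  )
}

fast_sampler <- list(chains = 2L, adapt = 300L, warmup = 300L, draws = 500L)

fit_fast <- function(trials, predictors, seed = 1L,
                     sampler = fast_sampler) {
  suppressWarnings(fit_stability_model(
    trials, predictors = predictors,
    chains = sampler$chains, adapt = sampler$adapt,
    warmup = sampler$warmup, draws = sampler$draws, seed = seed
  ))
}

# independent brute-force roughness oracle: direct double loop over the
# documented Sethares-parameterized Plomp-Levelt kernel
oracle_roughness <- function(freq, amp) {
  total <- 0
  n <- length(freq)
  if (n < 2) return(0)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      f1 <- min(freq[i], freq[j]); f2 <- max(freq[i], freq[j])
      s <- 0.24 / (0.0207 * f1 + 18.96)
      total <- total + amp[i] * amp[j] *
        (exp(-3.51 * s * (f2 - f1)) - exp(-5.75 * s * (f2 - f1)))
    }
  }
  total
}

# minimal hand-built stability_fit whose posterior is a point mass, for
# closed-form checks of downstream summaries
point_mass_fit <- function(intercept = 0, slope = -0.85, n_draws = 100) {
  draws <- cbind(
    `A:intercept` = rep(intercept, n_draws),
    `A:d_roughness` = rep(slope, n_draws)
  )
  structure(
    list(
      draws = draws,
      coef_names = tibble::tibble(
        group = "A", term = c("intercept", "d_roughness"),
        parameter = c("A:intercept", "A:d_roughness")
      ),
      groups = "A", terms = c("intercept", "d_roughness"),
      re_terms = c("intercept", "d_roughness"),
      predictors = "d_roughness", has_trial_type = FALSE,
      data = list(X_means = c(d_roughness = 0)),
      spec = list()
    ),
    class = "stability_fit"
  )
}
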