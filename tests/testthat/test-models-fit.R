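# MCMC-based checks kept deliberately small: one group, a dozen
# participants, short chains. Monte-Carlo tolerances are commensurately
# loose; systematic errors would exceed them by an order of magnitude.

test_that("the stability model agrees with an independent likelihood fit", {
  sim <- simulate_experiment(small_sim_config(20, 60), seed = 101)
  trials <- sim$trials; trials$trial_type <- NULL
  fit <- fit_fast(trials, c("d_roughness", "d_harmonicity"), seed = 3)
  td <- tidy(fit)
  d <- trials; d$y <- as.integer(d$response == 2L)
  gl <- suppressWarnings(lme4::glmer(
    y ~ d_roughness + d_harmonicity +
      (1 + d_roughness + d_harmonicity | participant),
    data = d, family = stats::binomial))
  co <- lme4::fixef(gl)
  se <- sqrt(diag(as.matrix(stats::vcov(gl))))
  for (term in c("d_roughness", "d_harmonicity")) {
    post <- td[td$term == term, ]
    expect_lt(abs(post$estimate - co[[term]]),
              3 * (post$std.error + se[[which(names(co) == term)]]))
  }
})

test_that("negating a predictor negates its posterior", {
  sim <- simulate_experiment(small_sim_config(12, 40), seed = 55)
  trials <- sim$trials; trials$trial_type <- NULL
  fit1 <- fit_fast(trials, "d_roughness", seed = 8)
  neg <- trials; neg$d_roughness <- -neg$d_roughness
  fit2 <- fit_fast(neg, "d_roughness", seed = 8)
  b1 <- tidy(fit1); b2 <- tidy(fit2)
  expect_equal(b2$estimate[b2$term == "d_roughness"],
               -b1$estimate[b1$term == "d_roughness"],
               tolerance = 0.1, ignore_attr = TRUE)
})

test_that("fixed seeds reproduce draws exactly", {
  sim <- simulate_experiment(small_sim_config(8, 24), seed = 2)
  trials <- sim$trials; trials$trial_type <- NULL
  f1 <- fit_fast(trials, "d_roughness", seed = 77,
                 sampler = list(chains = 2L, adapt = 150L,
                                warmup = 150L, draws = 200L))
  f2 <- fit_fast(trials, "d_roughness", seed = 77,
                 sampler = list(chains = 2L, adapt = 150L,
                                warmup = 150L, draws = 200L))
  expect_identical(f1$draws, f2$draws)
})

test_that("no information is pooled across exposure groups", {
  cfg2 <- simulation_config(
    groups = tibble::tibble(
      group = c("A", "B"), n_participants = 10L, intercept = 0,
      d_roughness = c(-0.9, 0.3), d_harmonicity = 0,
      d_spectral_entropy = 0, d_mean_pitch = 0),
    trials_per_participant = 40L,
    re_sd = c(intercept = 0.2, d_roughness = 0.1, d_harmonicity = 0,
              d_spectral_entropy = 0, d_mean_pitch = 0))
  sim <- simulate_experiment(cfg2, seed = 13)
  trials <- sim$trials; trials$trial_type <- NULL
  fit <- fit_fast(trials, "d_roughness", seed = 21)
  # scramble group A's responses; group B's posterior must not move
  scr <- trials
  idx <- scr$group == "A"
  set.seed(1); scr$response[idx] <- sample(scr$response[idx])
  fit_scr <- fit_fast(scr, "d_roughness", seed = 21)
  bB <- tidy(fit)[tidy(fit)$group == "B" &
                    tidy(fit)$term == "d_roughness", ]
  bB2 <- tidy(fit_scr)[tidy(fit_scr)$group == "B" &
                         tidy(fit_scr)$term == "d_roughness", ]
  expect_lt(abs(bB$estimate - bB2$estimate),
            3 * sqrt(bB$std.error^2 / bB$ess + bB2$std.error^2 / bB2$ess) +
              0.05)
  # group A's posterior, by contrast, collapses towards zero
  bA2 <- tidy(fit_scr)[tidy(fit_scr)$group == "A" &
                         tidy(fit_scr)$term == "d_roughness", ]
  expect_lt(abs(bA2$estimate), 0.25)
})

test_that("the model reproduces generating choice frequencies", {
  sim <- simulate_experiment(small_sim_config(15, 50), seed = 31)
  trials <- sim$trials; trials$trial_type <- NULL
  fit <- fit_fast(trials, c("d_roughness", "d_harmonicity"), seed = 6)
  # posterior predictive mean choice rate vs observed rate
  ll <- pointwise_loglik(fit)
  p_hat <- colMeans(exp(ll))            # P(observed response) per trial
  y <- as.integer(trials$response == 2L)
  p2 <- ifelse(y == 1L, p_hat, 1 - p_hat)
  emp <- mean(y)
  expect_lt(abs(mean(p2) - emp), 2 * sqrt(emp * (1 - emp) / length(y)) + 0.02)
})

test_that("degenerate inputs are rejected with configuration errors", {
  sim <- simulate_experiment(small_sim_config(6, 10), seed = 4)
  trials <- sim$trials; trials$trial_type <- NULL
  bad <- trials; bad$d_roughness <- 0
  expect_error(fit_stability_model(bad, "d_roughness"), "zero variance")
  solo <- trials[trials$participant == trials$participant[1], ]
  expect_error(fit_stability_model(solo, "d_roughness"),
               "at least 2 participants")
  badresp <- trials; badresp$response[1] <- 3L
  expect_error(fit_stability_model(badresp, "d_roughness"), "1 or 2")
})

test_that("Thurstone estimates pin the reference and track dominance", {
  # type A beats the reference in every one of 200 trials
  trials <- tibble::tibble(
    participant = rep(sprintf("p%02d", 1:10), each = 20),
    group = "G",
    type1 = "ref", type2 = "A",
    response = 2L
  )
  fit <- suppressWarnings(fit_thurstone(trials, reference = "ref",
                                        chains = 2, adapt = 200,
                                        warmup = 200, draws = 400, seed = 3))
  est <- fit$estimates
  expect_identical(est$mean[est$type == "ref"], 0)
  expect_identical(est$q2.5[est$type == "ref"], 0)
  a <- est[est$type == "A", ]
  expect_gt(a$mean, 0)
  expect_gt(a$q2.5, 0)
  # 50/50 choices: latent near 0, interval covers 0
  set.seed(12)
  fifty <- trials
  fifty$response <- rbinom(nrow(fifty), 1, 0.5) + 1L
  f2 <- suppressWarnings(fit_thurstone(fifty, reference = "ref",
                                       chains = 2, adapt = 200,
                                       warmup = 200, draws = 400, seed = 3))
  b <- f2$estimates[f2$estimates$type == "A", ]
  expect_lt(b$q2.5, 0); expect_gt(b$q97.5, 0)
  # a type never compared keeps its prior-width interval and warns
  expect_warning(
    f3 <- fit_thurstone(trials, reference = "ref",
                        types = c("ref", "A", "C"),
                        chains = 1, adapt = 100, warmup = 100,
                        draws = 300, seed = 1),
    "never compared")
  cw <- f3$estimates[f3$estimates$type == "C", ]
  expect_gt(cw$q97.5 - cw$q2.5, 2)      # at prior width (prior sd = 2)
})

test_that("model comparison reports near-zero difference for identical models", {
  sim <- simulate_experiment(small_sim_config(10, 30), seed = 17)
  trials <- sim$trials; trials$trial_type <- NULL
  cmp <- suppressWarnings(compare_predictor_subsets(
    trials, subsets = list("d_roughness", "d_roughness"),
    chains = 2L, adapt = 200L, warmup = 200L, draws = 400L, seed = 5))
  expect_equal(nrow(cmp), 2)
  expect_lt(abs(cmp$elpd[1] - cmp$elpd[2]), 2)
  expect_lt(abs(cmp$elpd_diff[2]), max(1, 2 * cmp$se_diff[2]))
})
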