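test_that("inverse logit reproduces the worked probability arithmetic", {
  expect_equal(round(inverse_logit(5 * 0.09), 2), 0.61)
  expect_equal(round(inverse_logit(8 * 0.13), 2), 0.74)
  expect_equal(inverse_logit(0), 0.5)
  expect_error(inverse_logit(Inf), "finite")
})

test_that("evidence ratios convert posterior probabilities to odds", {
  expect_equal(round(evidence_ratio(0.89), 2), 8.09)
  expect_equal(evidence_ratio(0.95), 19)
  expect_equal(evidence_ratio(0.975), 39)
  expect_equal(evidence_ratio(0.5), 1)
  # reciprocal identity over a probability grid
  for (p in seq(0.05, 0.95, by = 0.05)) {
    expect_equal(evidence_ratio(p) * evidence_ratio(1 - p), 1,
                 tolerance = 1e-12)
  }
  # saturation follows the draw-resolution bound convention
  er <- evidence_ratio(1, n_draws = 20000)
  expect_equal(as.numeric(er), 19999)
  expect_equal(format_evidence_ratio(er), ">19999.00")
  expect_error(evidence_ratio(1), "n_draws")
  expect_equal(format_evidence_ratio(evidence_ratio(0.89)), "8.09")
})

test_that("hypothesis summaries match closed-form answers on analytic draws", {
  # all-negative draws with a negative-direction hypothesis saturate
  s <- summarize_hypothesis(c(-3, -2, -1, -0.5), direction = "<0")
  expect_equal(s$post_p, 1)
  expect_equal(s$evid_ratio, 3)          # 4 draws -> bound 3
  expect_equal(s$evid_ratio_label, ">3.00")
  expect_equal(s$mean, -1.625)
  # symmetric draws give even odds
  sym <- summarize_hypothesis(c(-2, -1, 1, 2), direction = "<0")
  expect_equal(sym$post_p, 0.5)
  expect_equal(sym$evid_ratio, 1)
  # narrow posterior mass sits inside the ROPE: 2*pnorm(3.6) - 1
  draws <- qnorm(stats::ppoints(20000), 0, 0.01)
  nr <- summarize_hypothesis(draws, direction = "<0")
  expect_equal(nr$rope_prob, 2 * pnorm(3.6) - 1, tolerance = 1e-3)
  expect_equal(nr$q5, qnorm(0.05, 0, 0.01), tolerance = 1e-3)
  # interval ordering invariant
  expect_lte(nr$q5, nr$mean); expect_lte(nr$mean, nr$q95)
})

test_that("hypothesis summary rejects unknown coefficients", {
  fit <- point_mass_fit()
  expect_error(summarize_hypothesis(fit, "A:nonexistent", "<0"),
               "unknown coefficient")
  s <- summarize_hypothesis(fit, "A:d_roughness", "<0")
  expect_equal(s$mean, -0.85)
  expect_equal(s$post_p, 1)
})

test_that("predicted choice curves follow the inverse-logit closed form", {
  fit <- point_mass_fit(intercept = 0.3, slope = -0.85)
  cv <- predict_choice_curve(fit, "A", "d_roughness", grid = c(-1, 0, 1),
                             n_draw_curves = 0)
  # at grid 0 with predictors at their mean the curve is the intercept
  expect_equal(cv$prob[cv$x == 0], plogis(0.3), tolerance = 1e-12)
  fit0 <- point_mass_fit(intercept = 0, slope = -0.85)
  cv0 <- predict_choice_curve(fit0, "A", "d_roughness", grid = c(0, 1))
  expect_equal(round(cv0$prob[cv0$x == 1 & cv0$draw == 0], 2), 0.30)
  # monotone decreasing when the posterior is entirely negative
  cvm <- predict_choice_curve(fit0, "A", "d_roughness",
                              grid = seq(-2, 2, 0.5), n_draw_curves = 0)
  expect_true(all(diff(cvm$prob) < 0))
  expect_error(predict_choice_curve(fit0, "A", "d_harmonicity"),
               "not in the model")
  expect_error(predict_choice_curve(fit0, "B", "d_roughness"),
               "unknown group")
})

test_that("PSIS smoothing flags heavy-tailed importance ratios", {
  set.seed(33)
  # log-likelihoods whose ratios are approximately Pareto(0.5): benign
  ll_ok <- matrix(rnorm(2000 * 20, -1, 0.1), 2000, 20)
  loo_ok <- loo_psis(ll_ok)
  expect_equal(loo_ok$n_high_k, 0)
  expect_true(all(is.finite(loo_ok$pointwise$elpd_i)))
  # a very heavy-tailed observation (Cauchy log ratios) raises the flag
  ll_bad <- ll_ok
  ll_bad[, 1] <- -abs(stats::rcauchy(2000)) * 5
  expect_warning(loo_bad <- loo_psis(ll_bad), "Pareto k")
  expect_gt(loo_bad$pointwise$pareto_k[1], 0.7)
})

test_that("the generalized Pareto fit recovers known tail shapes", {
  set.seed(5)
  for (k_true in c(0.2, 0.7)) {
    u <- runif(4000)
    x <- 1.5 * (u^(-k_true) - 1) / k_true    # GPD(k_true, sigma=1.5) draws
    fit <- chordstab:::gpd_fit(x, regularize = FALSE)
    expect_equal(fit$k, k_true, tolerance = 0.1)
    expect_equal(fit$sigma, 1.5, tolerance = 0.2)
  }
})
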