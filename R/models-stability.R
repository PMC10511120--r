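#' Fit the Bayesian multilevel logistic stability model
#'
#' Models the probability of choosing the second chord pair as the
#' "finished" one as a function of per-trial feature changes. The
#' linear predictor contains, for every exposure group separately (no
#' pooling of information across groups): an intercept, a coefficient
#' for each included delta-feature, and — when both trial types are
#' present — a sum-coded trial-type effect (dyads +1, triads -1) and
#' its interactions with each feature, so each feature's main effect is
#' its coefficient at trial-type 0. Participants contribute a random
#' intercept and random slopes for every included feature, drawn
#' independently with group-specific standard deviations (partial
#' pooling across participants within, and only within, each exposure
#' group).
#'
#' All population-level effects have Student-t priors (default 3
#' degrees of freedom, location 0, scale 1); random-effect standard
#' deviations have half-Normal priors. Sampling is by JAGS; a fixed
#' `seed` reproduces the draws exactly.
#'
#' @param trials Tibble with columns `participant`, `group`, `response`
#'   (1 = first pair, 2 = second pair), the predictor columns named in
#'   `predictors`, and optionally `trial_type` (`"dyads"`/`"triads"`).
#' @param predictors Character vector of predictor column names.
#' @param prior_df,prior_scale Student-t prior on population effects.
#' @param re_sd_scale Scale of the half-Normal prior on random-effect SDs.
#' @param chains,adapt,warmup,draws MCMC settings (per chain).
#' @param seed Integer seed for the JAGS RNGs.
#' @param quiet Suppress JAGS progress output.
#' @return An object of class `stability_fit`: list with
#'   `draws` (matrix, total draws x named parameters), `coef_names`
#'   (tibble mapping group/term to column names), `diagnostics`
#'   (split-Rhat and effective sample size per parameter), `data`
#'   (the model frame), `spec` (settings echo), and chain structure.
#' @export
fit_stability_model <- function(trials,
                                predictors = c("d_roughness", "d_harmonicity",
                                               "d_mean_pitch"),
                                prior_df = 3, prior_scale = 1,
                                re_sd_scale = 1,
                                chains = 4L, adapt = 500L, warmup = 500L,
                                draws = 1000L, seed = 1L,
                                quiet = TRUE) {
  stopifnot(length(predictors) >= 1L, prior_df > 0, prior_scale > 0)
  need <- c("participant", "group", "response", predictors)
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0) {
    stop("trials is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(trials$response %in% c(1L, 2L))) {
    stop("response must be 1 or 2", call. = FALSE)
  }
  for (p in predictors) {
    v <- trials[[p]]
    if (!all(is.finite(v))) stop("non-finite values in ", p, call. = FALSE)
    if (var(v) == 0) {
      stop("degenerate predictor with zero variance: ", p, call. = FALSE)
    }
  }
  groups <- sort(unique(as.character(trials$group)))
  g <- match(as.character(trials$group), groups)
  n_per_group <- table(tapply(g, trials$participant, unique))
  if (any(n_per_group < 2)) {
    stop("every exposure group needs at least 2 participants", call. = FALSE)
  }
  pids <- sort(unique(as.character(trials$participant)))
  pid <- match(as.character(trials$participant), pids)
  pg <- vapply(pids, function(p) {
    unique(g[trials$participant == p])[1]
  }, integer(1))

  X <- as.matrix(trials[, predictors, drop = FALSE])
  K <- length(predictors)
  has_tt <- "trial_type" %in% names(trials) &&
    length(unique(trials$trial_type)) > 1L
  if (has_tt) {
    tt <- ifelse(trials$trial_type == "dyads", 1, -1)    # sum coding
    W <- cbind(1, X, tt, X * tt)
    terms <- c("intercept", predictors, "trial_type",
               paste0(predictors, ":trial_type"))
  } else {
    W <- cbind(1, X)
    terms <- c("intercept", predictors)
  }
  Z <- cbind(1, X)
  re_terms <- c("intercept", predictors)
  J <- ncol(W); M <- ncol(Z)
  G <- length(groups); P <- length(pids)
  y <- as.integer(trials$response == 2L)

  model_string <- "
model {
  for (i in 1:N) {
    logit(p[i]) <- inprod(b[g[i], 1:J], W[i, 1:J]) +
                   inprod(u[pid[i], 1:M], Z[i, 1:M])
    y[i] ~ dbern(p[i])
  }
  for (gg in 1:G) {
    for (j in 1:J) { b[gg, j] ~ dt(0, prior_tau, prior_df) }
    for (m in 1:M) { sigma_u[gg, m] ~ dnorm(0, re_tau) T(0,) }
  }
  for (pp in 1:P) {
    for (m in 1:M) { u[pp, m] ~ dnorm(0, pow(sigma_u[pg[pp], m], -2)) }
  }
}"
  data <- list(y = y, g = g, pid = pid, pg = pg, W = W, Z = Z,
               N = length(y), J = J, M = M, G = G, P = P,
               prior_tau = 1 / prior_scale^2, prior_df = prior_df,
               re_tau = 1 / re_sd_scale^2)
  inits <- lapply(seq_len(chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) + ch)
  })
  run <- function() {
    jm <- rjags::jags.model(textConnection(model_string), data = data,
                            inits = inits, n.chains = chains,
                            n.adapt = adapt, quiet = TRUE)
    stats::update(jm, warmup, progress.bar = "none")
    rjags::coda.samples(jm, c("b", "sigma_u", "u"), n.iter = draws,
                        progress.bar = "none")
  }
  samples <- if (quiet) suppressWarnings(run()) else run()

  # readable parameter names
  b_cols <- paste0("b[", rep(seq_len(G), times = J), ",",
                   rep(seq_len(J), each = G), "]")
  b_names <- paste0(rep(groups, times = J), ":", rep(terms, each = G))
  s_cols <- paste0("sigma_u[", rep(seq_len(G), times = M), ",",
                   rep(seq_len(M), each = G), "]")
  s_names <- paste0("sd_", rep(groups, times = M), ":",
                    rep(re_terms, each = G))
  rename <- stats::setNames(c(b_names, s_names), c(b_cols, s_cols))
  chain_mats <- lapply(samples, as.matrix)
  keep <- colnames(chain_mats[[1]])
  fixed_idx <- keep %in% names(rename)
  draws_by_chain <- lapply(chain_mats, function(m) {
    out <- m
    colnames(out)[fixed_idx] <- rename[colnames(out)[fixed_idx]]
    out
  })
  all_draws <- do.call(rbind, draws_by_chain)

  diag_cols <- c(b_names, s_names)
  diagnostics <- tibble::tibble(
    parameter = diag_cols,
    rhat = vapply(diag_cols, function(cn) {
      split_rhat(lapply(draws_by_chain, function(m) m[, cn]))
    }, numeric(1)),
    ess = vapply(diag_cols, function(cn) {
      sum(vapply(draws_by_chain, function(m) {
        as.numeric(coda::effectiveSize(m[, cn]))
      }, numeric(1)))
    }, numeric(1))
  )
  bad <- diagnostics$parameter[diagnostics$rhat > 1.01 &
                                 is.finite(diagnostics$rhat)]
  if (length(bad) > 0) {
    warning("possible non-convergence (split-Rhat > 1.01) for: ",
            paste(bad, collapse = ", "), call. = FALSE)
  }

  coef_names <- tibble::tibble(
    group = rep(groups, times = J),
    term = rep(terms, each = G),
    parameter = b_names
  )
  structure(
    list(draws = all_draws, draws_by_chain = draws_by_chain,
         coef_names = coef_names, diagnostics = diagnostics,
         groups = groups, terms = terms, re_terms = re_terms,
         predictors = predictors, has_trial_type = has_tt,
         data = list(y = y, W = W, Z = Z, g = g, pid = pid, pg = pg,
                     X_means = colMeans(X), participants = pids),
         spec = list(prior_df = prior_df, prior_scale = prior_scale,
                     re_sd_scale = re_sd_scale, chains = chains,
                     adapt = adapt, warmup = warmup, draws = draws,
                     seed = seed)),
    class = "stability_fit"
  )
}

# Split-Rhat: each chain halved, classic potential-scale-reduction
# statistic over the resulting 2*chains sequences.
split_rhat <- function(chain_draws) {
  halves <- unlist(lapply(chain_draws, function(x) {
    n <- floor(length(x) / 2)
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior draws of the population-level parameters
#'
#' @param fit A `stability_fit`.
#' @return Matrix of draws (rows) by named parameters (columns):
#'   group-level coefficients `"<group>:<term>"` and random-effect SDs
#'   `"sd_<group>:<term>"`.
#' @export
posterior_draws <- function(fit) {
  stopifnot(inherits(fit, c("stability_fit", "thurstone_fit")))
  cols <- c(fit$coef_names$parameter,
            grep("^sd_", colnames(fit$draws), value = TRUE))
  fit$draws[, intersect(cols, colnames(fit$draws)), drop = FALSE]
}

#' Pointwise log-likelihood matrix
#'
#' Per-draw, per-observation Bernoulli log-likelihood under the fitted
#' stability model, the input to PSIS-LOO model comparison.
#'
#' @param fit A `stability_fit`.
#' @return Matrix, draws x observations.
#' @export
pointwise_loglik <- function(fit) {
  d <- fit$data
  S <- nrow(fit$draws)
  N <- length(d$y)
  eta <- matrix(0, N, S)
  G <- length(fit$groups)
  for (gg in seq_len(G)) {
    idx <- which(d$g == gg)
    if (length(idx) == 0) next
    B <- fit$draws[, fit$coef_names$parameter[fit$coef_names$group ==
                                                fit$groups[gg]], drop = FALSE]
    eta[idx, ] <- d$W[idx, , drop = FALSE] %*% t(B)
  }
  M <- ncol(d$Z)
  for (pp in seq_along(d$participants)) {
    idx <- which(d$pid == pp)
    if (length(idx) == 0) next
    ucols <- paste0("u[", pp, ",", seq_len(M), "]")
    U <- fit$draws[, ucols, drop = FALSE]
    eta[idx, ] <- eta[idx, ] + d$Z[idx, , drop = FALSE] %*% t(U)
  }
  # log-lik for y=1 is log(p) = -log1p(exp(-eta)); for y=0, -log1p(exp(eta))
  sgn <- ifelse(d$y == 1L, 1, -1)
  ll <- -log1p(exp(-sgn * eta))
  t(ll)
}

#' @export
print.stability_fit <- function(x, ...) {
  cat("<stability_fit> ", length(x$data$y), " trials, ",
      length(x$data$participants), " participants, ",
      length(x$groups), " group(s); ",
      x$spec$chains, " chains x ", x$spec$draws, " draws\n", sep = "")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @export
tidy.stability_fit <- function(x, ...) {
  dm <- x$draws
  diag <- x$diagnostics
  x$coef_names |>
    dplyr::mutate(
      estimate = colMeans(dm[, .data$parameter, drop = FALSE]),
      std.error = apply(dm[, .data$parameter, drop = FALSE], 2, sd),
      conf.low = apply(dm[, .data$parameter, drop = FALSE], 2,
                       quantile, 0.05),
      conf.high = apply(dm[, .data$parameter, drop = FALSE], 2,
                        quantile, 0.95),
      rhat = diag$rhat[match(.data$parameter, diag$parameter)],
      ess = diag$ess[match(.data$parameter, diag$parameter)]
    )
}

#' @export
glance.stability_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = length(x$data$y),
    n_participants = length(x$data$participants),
    n_groups = length(x$groups),
    chains = x$spec$chains,
    draws = nrow(x$draws),
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess = min(x$diagnostics$ess, na.rm = TRUE)
  )
}

#' Table of directional hypothesis summaries for every group
#'
#' Builds the hypothesis-test table for the fitted stability model: one
#' row per exposure group per feature, each summarizing the feature's
#' main effect (its coefficient at sum-coded trial type 0) against its
#' hypothesized direction. Default directions follow the pre-registered
#' hypotheses: roughness and spectral entropy reduce finishedness
#' (`"<0"`), harmonicity and mean pitch increase it (`">0"`).
#'
#' @param fit A `stability_fit`.
#' @param directions Named character vector mapping predictor to
#'   `"<0"`/`">0"`.
#' @param rope Region of practical equivalence.
#' @return Tibble with columns `group`, `coefficient`, `hypothesis`,
#'   `mean`, `q5`, `q95`, `evid_ratio`, `evid_ratio_label`, `post_p`,
#'   `rope_prob`.
#' @export
hypothesis_table <- function(fit,
                             directions = c(d_roughness = "<0",
                                            d_harmonicity = ">0",
                                            d_spectral_entropy = "<0",
                                            d_mean_pitch = ">0"),
                             rope = c(-0.036, 0.036)) {
  stopifnot(inherits(fit, "stability_fit"))
  preds <- intersect(fit$predictors, names(directions))
  purrr::map(fit$groups, function(gr) {
    purrr::map(preds, function(p) {
      par <- fit$coef_names$parameter[fit$coef_names$group == gr &
                                        fit$coef_names$term == p]
      summarize_hypothesis(fit, par, directions[[p]], rope) |>
        dplyr::mutate(group = gr, coefficient = p, .before = 1)
    }) |> dplyr::bind_rows()
  }) |>
    dplyr::bind_rows()
}

#' Predicted choice-probability curve for one feature
#'
#' Probability of choosing the second chord pair as "finished", as
#' predicted for one exposure group along a grid of one feature's
#' values, all other predictors held at their sample means and
#' sum-coded trial type at 0 (the main-effect setting). Returns the
#' posterior-mean curve plus a configurable number of individual
#' posterior-draw curves for visualizing uncertainty.
#'
#' @param fit A `stability_fit`.
#' @param group Exposure-group name.
#' @param feature Predictor name.
#' @param grid Numeric grid of feature values (standardized units, or
#'   semitones for mean pitch).
#' @param n_draw_curves Number of individual draw curves to include.
#' @return Tibble with `group`, `feature`, `x`, `draw` (0 for the
#'   posterior-mean curve), `prob`.
#' @export
predict_choice_curve <- function(fit, group, feature,
                                 grid = seq(-3, 3, length.out = 101),
                                 n_draw_curves = 100) {
  stopifnot(inherits(fit, "stability_fit"))
  if (!group %in% fit$groups) {
    stop("unknown group '", group, "'", call. = FALSE)
  }
  if (!feature %in% fit$predictors) {
    stop("feature '", feature, "' is not in the model (predictors: ",
         paste(fit$predictors, collapse = ", "), ")", call. = FALSE)
  }
  pars <- fit$coef_names[fit$coef_names$group == group, ]
  B <- fit$draws[, pars$parameter, drop = FALSE]
  # design row as a function of the grid: intercept 1, feature varies,
  # other predictors at their sample means, trial type at 0
  base <- stats::setNames(rep(0, length(fit$terms)), pars$term)
  base["intercept"] <- 1
  for (p in setdiff(fit$predictors, feature)) {
    base[p] <- fit$data$X_means[[p]]
  }
  S <- nrow(B)
  draw_ids <- if (n_draw_curves > 0) {
    unique(round(seq(1, S, length.out = min(n_draw_curves, S))))
  } else integer(0)
  rows <- purrr::map(grid, function(x0) {
    w <- base
    w[feature] <- x0
    eta <- as.numeric(B %*% w)
    tibble::tibble(
      group = group, feature = feature, x = x0,
      draw = c(0L, draw_ids),
      prob = c(mean(plogis(eta)), plogis(eta[draw_ids]))
    )
  })
  dplyr::bind_rows(rows)
}
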