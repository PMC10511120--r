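# Pareto-smoothed importance-sampling approximation of leave-one-out
# cross-validation, computed from a pointwise log-likelihood matrix.
# The importance ratios for observation i are 1/p(y_i | theta_s); the
# largest 20% of each observation's log ratios are replaced by expected
# order statistics of a generalized Pareto distribution fitted to the
# tail, and the smoothed weights are truncated at the raw maximum.

# Zhang & Stephens (2009) posterior-mean estimator for the generalized
# Pareto shape (k) and scale (sigma), with the small-sample shape
# regularization used in current PSIS practice.
gpd_fit <- function(x, regularize = TRUE) {
  x <- sort(x)
  n <- length(x)
  if (n < 5 || x[n] <= 0) return(list(k = Inf, sigma = NA_real_))
  prior <- 3
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior * xstar)
  k_of <- function(th) -mean(log1p(-th * x))
  l_theta <- vapply(theta, function(th) {
    k <- k_of(th)
    n * (log(th / k) + k - 1)
  }, numeric(1))
  w <- 1 / vapply(seq_len(m), function(j) {
    sum(exp(l_theta - l_theta[j]))
  }, numeric(1))
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))       # = -ZS k; the Pareto shape
  sigma <- -k / theta_hat
  if (regularize) k <- k * n / (n + 10) + 5 / (n + 10)
  list(k = k, sigma = sigma)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# Smooth one observation's log importance ratios; returns the smoothed
# log weights and the fitted Pareto k.
psis_smooth <- function(log_ratios, tail_frac = 0.2) {
  S <- length(log_ratios)
  lw <- log_ratios - max(log_ratios)
  n_tail <- ceiling(tail_frac * S)
  if (n_tail < 5) return(list(log_weights = lw, k = NA_real_))
  ord <- order(lw)
  tail_idx <- ord[(S - n_tail + 1):S]
  cutoff <- lw[ord[S - n_tail]]
  exceed <- exp(lw[tail_idx]) - exp(cutoff)
  fit <- gpd_fit(exceed)
  if (!is.finite(fit$k)) return(list(log_weights = lw, k = Inf))
  # replace tail by expected order statistics of the fitted GPD
  pq <- (seq_len(n_tail) - 0.5) / n_tail
  smoothed <- log(exp(cutoff) +
                    vapply(pq, gpd_quantile, numeric(1),
                           k = fit$k, sigma = fit$sigma))
  lw[tail_idx[order(lw[tail_idx])]] <- pmin(smoothed, 0)
  list(log_weights = lw, k = fit$k)
}

#' PSIS-LOO expected log predictive density
#'
#' Estimates leave-one-out cross-validated expected log predictive
#' density (ELPD) from a pointwise log-likelihood matrix by
#' Pareto-smoothed importance sampling: per observation, importance
#' ratios are the reciprocal likelihoods, the largest 20% are smoothed
#' against a fitted generalized Pareto distribution, and observations
#' whose Pareto shape `k` exceeds 0.7 are flagged as unreliable.
#'
#' @param log_lik Matrix of pointwise log likelihoods, draws x
#'   observations (see [pointwise_loglik()]).
#' @return An object of class `psis_loo`: list with `elpd`, `se`,
#'   `pointwise` (tibble: `elpd_i`, `pareto_k`), `n_high_k` (count of
#'   `k > 0.7`).
#' @export
loo_psis <- function(log_lik) {
  if (is.null(dim(log_lik))) {
    stop("log_lik must be a draws x observations matrix", call. = FALSE)
  }
  N <- ncol(log_lik)
  elpd_i <- numeric(N)
  k_i <- numeric(N)
  for (i in seq_len(N)) {
    ll <- log_lik[, i]
    sm <- psis_smooth(-ll)               # log importance ratios = -log lik
    lw <- sm$log_weights
    lw <- lw - log_sum_exp(lw)           # normalize
    elpd_i[i] <- log_sum_exp(lw + ll)
    k_i[i] <- sm$k
  }
  high <- sum(k_i > 0.7, na.rm = TRUE)
  if (high > 0) {
    warning(high, " observation(s) with Pareto k > 0.7; ",
            "the PSIS-LOO estimate may be unreliable", call. = FALSE)
  }
  structure(
    list(elpd = sum(elpd_i),
         se = sqrt(N * var(elpd_i)),
         pointwise = tibble::tibble(elpd_i = elpd_i, pareto_k = k_i),
         n_high_k = high),
    class = "psis_loo"
  )
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' @export
print.psis_loo <- function(x, ...) {
  cat("<psis_loo> elpd = ", round(x$elpd, 1), " (se ", round(x$se, 1),
      "), ", x$n_high_k, " observation(s) with Pareto k > 0.7\n", sep = "")
  invisible(x)
}

#' Compare predictor subsets by PSIS-LOO
#'
#' Fits the stability model for each listed subset of predictors (by
#' default all non-empty subsets of the four features) and ranks the
#' models by PSIS-LOO expected log predictive density. The difference
#' to the best model and the standard error of that difference (from
#' the paired pointwise ELPDs) are reported, and observations with
#' Pareto `k > 0.7` are counted per model.
#'
#' @param trials Trial tibble (see [fit_stability_model()]).
#' @param subsets List of character vectors of predictor names; `NULL`
#'   means all non-empty subsets of
#'   `c("d_roughness","d_harmonicity","d_spectral_entropy","d_mean_pitch")`.
#' @param ... Passed to [fit_stability_model()] (sampler settings etc.).
#' @return Tibble ranked by `elpd`: `model`, `predictors`
#'   (list-column), `elpd`, `se`, `elpd_diff`, `se_diff`, `n_high_k`.
#' @export
compare_predictor_subsets <- function(trials, subsets = NULL, ...) {
  if (is.null(subsets)) {
    feats <- c("d_roughness", "d_harmonicity", "d_spectral_entropy",
               "d_mean_pitch")
    subsets <- unlist(lapply(seq_along(feats), function(k) {
      asplit(combn(feats, k), 2)
    }), recursive = FALSE)
    subsets <- lapply(subsets, as.character)
  }
  loos <- purrr::map(subsets, function(preds) {
    fit <- fit_stability_model(trials, predictors = preds, ...)
    loo_psis(pointwise_loglik(fit))
  })
  out <- tibble::tibble(
    model = purrr::map_chr(subsets, paste, collapse = "+"),
    predictors = subsets,
    elpd = purrr::map_dbl(loos, "elpd"),
    se = purrr::map_dbl(loos, "se"),
    n_high_k = purrr::map_int(loos, "n_high_k")
  )
  best <- which.max(out$elpd)
  best_pw <- loos[[best]]$pointwise$elpd_i
  out$elpd_diff <- out$elpd - out$elpd[best]
  out$se_diff <- purrr::map_dbl(loos, function(l) {
    d <- l$pointwise$elpd_i - best_pw
    sqrt(length(d) * var(d))
  })
  dplyr::arrange(out, dplyr::desc(.data$elpd))
}
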