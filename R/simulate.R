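#' Configuration for a synthetic forced-choice experiment
#'
#' Defines the generative model for a complete synthetic experiment:
#' per-group true coefficients on the log-odds scale (per standardized
#' unit for roughness, harmonicity and spectral entropy; per semitone
#' for mean pitch), per-group intercepts, participant random-effect
#' SDs and correlation, group sizes, trials per participant, and the
#' fraction of pathological response blocks to inject for exercising
#' the screening filter.
#'
#' The default scenario mirrors the five-exposure-group design:
#' group-level roughness/harmonicity/mean-pitch coefficients at the
#' magnitudes reported for the field study (e.g. roughness -0.13 for
#' the minimal-exposure group through -0.85 for Sydney musicians), no
#' spectral-entropy effect, post-screening group sizes, 102 trials per
#' participant (two 30-trial dyad blocks plus a 42-trial triad block),
#' random-intercept SD 0.3 and random-slope SDs 0.1, uncorrelated.
#'
#' @param groups Tibble with one row per group: `group`, `n_participants`,
#'   `intercept`, and one column per predictor coefficient. `NULL` gives
#'   the default five-group scenario.
#' @param trials_per_participant Trials per participant (dyad blocks are
#'   filled first: 30 + 30, remainder triads).
#' @param re_sd Named vector of random-effect SDs: `intercept` plus one
#'   per predictor.
#' @param re_cor Common pairwise correlation of the random effects.
#' @param pathological_fraction Fraction of response blocks replaced by
#'   pathological patterns (constant or alternating).
#' @param predictors Predictor names.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(groups = NULL,
                              trials_per_participant = 102L,
                              re_sd = c(intercept = 0.3, d_roughness = 0.1,
                                        d_harmonicity = 0.1,
                                        d_spectral_entropy = 0.1,
                                        d_mean_pitch = 0.1),
                              re_cor = 0,
                              pathological_fraction = 0,
                              predictors = c("d_roughness", "d_harmonicity",
                                             "d_spectral_entropy",
                                             "d_mean_pitch")) {
  if (is.null(groups)) {
    groups <- tibble::tibble(
      group = c("Uruwa-minimal", "Uruwa-Lutheran", "Uruwa-SDA",
                "Sydney-nonmusician", "Sydney-musician"),
      n_participants = c(22L, 39L, 83L, 60L, 19L),
      intercept = 0,
      d_roughness = c(-0.13, -0.09, -0.10, -0.29, -0.85),
      d_harmonicity = c(-0.04, -0.08, -0.01, 0.05, 0.15),
      d_spectral_entropy = 0,
      d_mean_pitch = c(-0.10, 0.11, -0.03, -0.15, -0.03)
    )
  }
  stopifnot(all(c("group", "n_participants", "intercept") %in% names(groups)),
            all(predictors %in% names(groups)),
            all(groups$n_participants >= 1L),
            trials_per_participant >= 1L,
            pathological_fraction >= 0, pathological_fraction <= 1,
            all(re_sd >= 0), re_cor > -1, re_cor < 1)
  miss <- setdiff(c("intercept", predictors), names(re_sd))
  if (length(miss) > 0) {
    stop("re_sd is missing entries for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(groups = groups, trials_per_participant = trials_per_participant,
         re_sd = re_sd, re_cor = re_cor,
         pathological_fraction = pathological_fraction,
         predictors = predictors),
    class = "simulation_config"
  )
}

# draw participant random effects from the implied multivariate normal
draw_random_effects <- function(n, sds, rho) {
  m <- length(sds)
  R <- matrix(rho, m, m); diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("random-effect correlation ", rho, " gives an invalid ",
         "correlation matrix for ", m, " effects", call. = FALSE)
  }
  L <- chol(R + diag(1e-12, m))
  z <- matrix(rnorm(n * m), n, m) %*% L
  sweep(z, 2, sds, `*`)
}

#' Simulate a complete forced-choice experiment
#'
#' Generates trial-level data from the same model family the stability
#' model fits: participant random effects from the configured
#' multivariate normal, per-trial feature deltas from the chosen
#' source, a Bernoulli response for "pair two" with probability
#' `inverse_logit(eta)`, and (optionally) pathological response blocks
#' for the screening filter. Identical seeds give identical datasets.
#'
#' Delta sources: `"parametric"` draws roughness, harmonicity and
#' spectral-entropy deltas from standard normals and mean-pitch deltas
#' from Normal(0, 0.52) semitones (the dispersion of the field
#' stimulus set); `"stimuli"` derives deltas from the package's own
#' enumerated and rendered stimulus pairs, exercising the feature
#' stage end to end.
#'
#' @param config A [simulation_config()].
#' @param delta_source `"parametric"` or `"stimuli"`.
#' @param seed Master seed; per-stage streams are derived from it.
#' @param feature_args For the `"stimuli"` source, arguments passed on
#'   to [chord_features()] (e.g. `source = "idealized"` for speed).
#' @return List of class `simulated_experiment`:
#' \describe{
#'   \item{trials}{tibble: `participant`, `group`, `block`,
#'     `trial_type`, delta features, `prob` (generating probability of
#'     choosing pair two), `response`, `pathological` flag}
#'   \item{truth}{list: the config, per-group coefficient table,
#'     participant effects, seed}
#' }
#' @export
simulate_experiment <- function(config = simulation_config(),
                                delta_source = c("parametric", "stimuli"),
                                seed = 1L,
                                feature_args = list(source = "idealized")) {
  stopifnot(inherits(config, "simulation_config"))
  delta_source <- match.arg(delta_source)
  local_rng(derive_seeds(seed, 1, stream = 1L))
  preds <- config$predictors
  npt <- config$trials_per_participant
  block_of <- function(i) {
    dplyr::case_when(i <= 30 ~ "dyads1",
                     i <= 60 & npt > 60 ~ "dyads2",
                     .default = "triads")
  }
  delta_pool <- if (delta_source == "stimuli") {
    stimulus_delta_pool(feature_args, seed = derive_seeds(seed, 1, 2L))
  } else NULL

  groups <- config$groups
  trials <- vector("list", nrow(groups))
  effects <- vector("list", nrow(groups))
  pid0 <- 0L
  for (gi in seq_len(nrow(groups))) {
    grow <- groups[gi, ]
    n_p <- grow$n_participants
    sds <- config$re_sd[c("intercept", preds)]
    u <- draw_random_effects(n_p, sds, config$re_cor)
    beta <- unlist(grow[preds])
    rows <- purrr::map(seq_len(n_p), function(p) {
      d <- draw_deltas(npt, preds, delta_pool)
      i <- seq_len(npt)
      eta <- grow$intercept + u[p, 1] +
        as.matrix(d[, preds]) %*% (beta + u[p, -1])
      prob <- plogis(as.numeric(eta))
      d |>
        dplyr::mutate(
          participant = sprintf("p%03d", pid0 + p),
          group = grow$group,
          trial = i,
          block = block_of(i),
          trial_type = ifelse(.data$block == "triads", "triads", "dyads"),
          prob = prob,
          response = ifelse(rbinom(npt, 1, prob) == 1L, 2L, 1L),
          pathological = FALSE
        )
    })
    trials[[gi]] <- dplyr::bind_rows(rows)
    effects[[gi]] <- tibble::tibble(
      participant = sprintf("p%03d", pid0 + seq_len(n_p)),
      group = grow$group
    ) |> dplyr::bind_cols(tibble::as_tibble(u, .name_repair = ~ c(
      "u_intercept", paste0("u_", preds))))
    pid0 <- pid0 + n_p
  }
  trials <- dplyr::bind_rows(trials)

  if (config$pathological_fraction > 0) {
    trials <- inject_pathological(trials, config$pathological_fraction)
  }
  truth <- list(
    config = config,
    coefficients = tidyr::pivot_longer(
      groups[, c("group", "intercept", preds)],
      -"group", names_to = "term", values_to = "true_value"),
    participant_effects = dplyr::bind_rows(effects),
    seed = seed
  )
  structure(list(trials = trials, truth = truth),
            class = "simulated_experiment")
}

draw_deltas <- function(n, preds, pool = NULL) {
  if (!is.null(pool)) {
    idx <- sample.int(nrow(pool), n, replace = n > nrow(pool))
    return(pool[idx, preds, drop = FALSE])
  }
  out <- purrr::map(preds, function(p) {
    if (p == "d_mean_pitch") rnorm(n, 0, 0.52) else rnorm(n)
  })
  names(out) <- preds
  tibble::as_tibble(out)
}

# Delta-feature pool from the package's own stimulus pairs: features of
# both chords of each enumerated dyad pair plus the triad-type pairs,
# standardized over the pool (mean pitch kept in semitones).
stimulus_delta_pool <- function(feature_args = list(source = "idealized"),
                                seed = 1L) {
  dy <- enumerate_dyad_pairs(quiet = TRUE)
  tr <- enumerate_triad_pairs(quiet = TRUE)
  pairs <- dplyr::bind_rows(
    dplyr::select(dy, "chord1", "chord2"),
    dplyr::select(tr, "chord1", "chord2")
  )
  feat <- function(ch) do.call(chord_features, c(list(ch), feature_args))
  chords <- unique(c(pairs$chord1, pairs$chord2))
  keys <- vapply(chords, paste, character(1), collapse = ",")
  featmap <- purrr::map(chords, feat)
  names(featmap) <- keys
  deltas <- purrr::map2(pairs$chord1, pairs$chord2, function(c1, c2) {
    delta_features(featmap[[paste(c1, collapse = ",")]],
                   featmap[[paste(c2, collapse = ",")]])
  }) |> dplyr::bind_rows()
  standardize_deltas(deltas)
}

# Replace a fraction of response blocks with pathological patterns,
# cycling constant-1, constant-2 and the two alternating phases.
inject_pathological <- function(trials, fraction) {
  blocks <- dplyr::distinct(trials, .data$participant, .data$block)
  n_bad <- round(fraction * nrow(blocks))
  if (n_bad == 0) return(trials)
  bad <- blocks[sample.int(nrow(blocks), n_bad), ]
  bad$pattern <- rep_len(c("constant-1", "constant-2",
                           "alternating-12", "alternating-21"), n_bad)
  for (i in seq_len(n_bad)) {
    idx <- which(trials$participant == bad$participant[i] &
                   trials$block == bad$block[i])
    n <- length(idx)
    trials$response[idx] <- switch(
      bad$pattern[i],
      "constant-1" = rep(1L, n),
      "constant-2" = rep(2L, n),
      "alternating-12" = rep_len(c(1L, 2L), n),
      "alternating-21" = rep_len(c(2L, 1L), n)
    )
    trials$pathological[idx] <- TRUE
  }
  trials
}

#' @export
print.simulated_experiment <- function(x, ...) {
  cat("<simulated_experiment> ", nrow(x$trials), " trials, ",
      dplyr::n_distinct(x$trials$participant), " participants, ",
      dplyr::n_distinct(x$trials$group), " group(s); seed ",
      x$truth$seed, "\n", sep = "")
  invisible(x)
}

#' Parameter-recovery report
#'
#' Compares the generating coefficients of a simulated experiment with
#' the posterior of a stability model fitted to it: one row per group
#' and coefficient with the truth, the posterior mean, the 90%
#' equal-tailed interval, and a coverage flag (closed interval: a truth
#' exactly on the boundary counts as covered).
#'
#' @param truth The `truth` element of a [simulate_experiment()] result
#'   (or the whole result).
#' @param fit A `stability_fit` fitted to the simulated trials.
#' @return Tibble: `group`, `term`, `true_value`, `estimate`, `q5`,
#'   `q95`, `covered`.
#' @export
recovery_report <- function(truth, fit) {
  if (inherits(truth, "simulated_experiment")) truth <- truth$truth
  stopifnot(inherits(fit, "stability_fit"))
  est <- tidy(fit)
  tab <- dplyr::inner_join(truth$coefficients, est,
                           by = c("group", "term"))
  if (nrow(tab) == 0) {
    stop("no coefficient names shared between truth and fit", call. = FALSE)
  }
  dropped <- dplyr::anti_join(truth$coefficients, est,
                              by = c("group", "term"))
  dropped <- dropped[dropped$term != "intercept" |
                       !"intercept" %in% est$term, ]
  if (nrow(dropped) > 0) {
    warning("coefficient(s) without a matching estimate excluded: ",
            paste(paste0(dropped$group, ":", dropped$term), collapse = ", "),
            call. = FALSE)
  }
  tab |>
    dplyr::transmute(
      group = .data$group, term = .data$term,
      true_value = .data$true_value, estimate = .data$estimate,
      q5 = .data$conf.low, q95 = .data$conf.high,
      covered = .data$true_value >= .data$q5 &
        .data$true_value <= .data$q95
    )
}
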