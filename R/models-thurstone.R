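#' Fit the Bayesian multilevel Thurstone paired-comparison model
#'
#' Places chord types on a normally distributed latent "finishedness"
#' scale, separately for each exposure group. In each trial the
#' participant hears two ordered chord pairs (the second reversing the
#' first) and chooses the "finished" one; the probability of choosing
#' the second pair is the standard normal CDF (probit link) of the
#' difference between the latent values of the two pairs' final chord
#' types, plus a participant effect. The reference type's latent value
#' is fixed at exactly 0 in every group, so estimates are relative to
#' the reference (the unison for dyads, the semitone cluster for
#' triads, in the original design). Latent values have zero-centred
#' Normal(0, 2) priors; participant effects are pooled within exposure
#' group only, with half-Normal(1) priors on their SDs.
#'
#' @param trials Tibble with columns `participant`, `group`, `type1`
#'   (final chord type of the first pair), `type2` (final chord type of
#'   the second pair), `response` (1 or 2).
#' @param reference Chord-type label fixed at latent 0.
#' @param types Optional character vector of all chord types to
#'   estimate; types that never occur in the trials keep their prior
#'   (a warning is raised). Defaults to the types present in the data.
#' @param prior_sd Prior SD of the free latent values.
#' @param chains,adapt,warmup,draws MCMC settings.
#' @param seed Integer seed.
#' @param quiet Suppress JAGS output.
#' @return An object of class `thurstone_fit` with `estimates` (tibble:
#'   `group`, `type`, `mean`, `q2.5`, `q97.5`, `reference` flag),
#'   `draws`, and settings.
#' @export
fit_thurstone <- function(trials, reference = NULL, types = NULL,
                          prior_sd = 2,
                          chains = 2L, adapt = 500L, warmup = 500L,
                          draws = 1000L, seed = 1L, quiet = TRUE) {
  need <- c("participant", "group", "type1", "type2", "response")
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0) {
    stop("trials is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  observed <- sort(unique(c(as.character(trials$type1),
                            as.character(trials$type2))))
  types <- if (is.null(types)) observed else sort(unique(as.character(types)))
  if (!all(observed %in% types)) {
    stop("trials contain type(s) missing from `types`: ",
         paste(setdiff(observed, types), collapse = ", "), call. = FALSE)
  }
  if (is.null(reference)) reference <- types[1]
  if (!reference %in% types) {
    stop("reference type '", reference, "' is not among the types",
         call. = FALSE)
  }
  # reference goes last so s[, Tt] can be pinned at zero
  types <- c(setdiff(types, reference), reference)
  Tt <- length(types)
  never <- setdiff(types, observed)
  if (length(never) > 0) {
    warning("chord type(s) never compared: ", paste(never, collapse = ", "),
            "; their estimates reflect the prior only", call. = FALSE)
  }
  groups <- sort(unique(as.character(trials$group)))
  g <- match(as.character(trials$group), groups)
  pids <- sort(unique(as.character(trials$participant)))
  pid <- match(as.character(trials$participant), pids)
  pg <- vapply(pids, function(p) unique(g[trials$participant == p])[1],
               integer(1))
  data <- list(
    y = as.integer(trials$response == 2L),
    t1 = match(as.character(trials$type1), types),
    t2 = match(as.character(trials$type2), types),
    g = g, pid = pid, pg = pg,
    N = nrow(trials), G = length(groups), P = length(pids), Tt = Tt,
    s_tau = 1 / prior_sd^2
  )
  model_string <- "
model {
  for (i in 1:N) {
    d[i] <- s[g[i], t2[i]] - s[g[i], t1[i]] + u[pid[i]]
    p[i] <- max(1.0E-9, min(1 - 1.0E-9, phi(d[i])))
    y[i] ~ dbern(p[i])
  }
  for (gg in 1:G) {
    for (t in 1:(Tt - 1)) { s[gg, t] ~ dnorm(0, s_tau) }
    s[gg, Tt] <- 0
    sigma_u[gg] ~ dnorm(0, 1) T(0,)
  }
  for (pp in 1:P) { u[pp] ~ dnorm(0, pow(sigma_u[pg[pp]], -2)) }
}"
  inits <- lapply(seq_len(chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) + ch)
  })
  run <- function() {
    jm <- rjags::jags.model(textConnection(model_string), data = data,
                            inits = inits, n.chains = chains,
                            n.adapt = adapt, quiet = TRUE)
    stats::update(jm, warmup, progress.bar = "none")
    rjags::coda.samples(jm, c("s", "sigma_u"), n.iter = draws,
                        progress.bar = "none")
  }
  samples <- if (quiet) suppressWarnings(run()) else run()
  dm <- do.call(rbind, lapply(samples, as.matrix))
  est <- tidyr::expand_grid(group = groups, type = types) |>
    dplyr::mutate(
      column = paste0("s[", match(.data$group, groups), ",",
                      match(.data$type, types), "]"),
      mean = unname(colMeans(dm[, .data$column, drop = FALSE])),
      q2.5 = unname(apply(dm[, .data$column, drop = FALSE], 2,
                          quantile, 0.025)),
      q97.5 = unname(apply(dm[, .data$column, drop = FALSE], 2,
                           quantile, 0.975)),
      reference = .data$type == reference
    ) |>
    dplyr::select(-"column")
  structure(
    list(estimates = est, draws = dm, groups = groups, types = types,
         reference = reference,
         spec = list(prior_sd = prior_sd, chains = chains, adapt = adapt,
                     warmup = warmup, draws = draws, seed = seed)),
    class = "thurstone_fit"
  )
}

#' @export
print.thurstone_fit <- function(x, ...) {
  cat("<thurstone_fit> ", length(x$types), " chord types, ",
      length(x$groups), " group(s), reference '", x$reference, "'\n",
      sep = "")
  print(x$estimates, n = Inf)
  invisible(x)
}

#' @export
tidy.thurstone_fit <- function(x, ...) {
  dplyr::rename(x$estimates, term = "type", estimate = "mean",
                conf.low = "q2.5", conf.high = "q97.5")
}

#' @export
glance.thurstone_fit <- function(x, ...) {
  tibble::tibble(
    n_types = length(x$types),
    n_groups = length(x$groups),
    draws = nrow(x$draws),
    reference = x$reference
  )
}
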