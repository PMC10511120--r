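#' Inverse logit
#'
#' Maps log-odds to probability, `1 / (1 + exp(-x))`. A thin wrapper
#' over [stats::plogis()].
#'
#' @param x Log-odds.
#' @return Probability in `(0, 1)`.
#' @export
#' @examples
#' inverse_logit(5 * 0.09)   # 0.61: the gain from a 5-SD roughness drop
inverse_logit <- function(x) {
  stopifnot(all(is.finite(x)))
  plogis(x)
}

#' Evidence ratio for a directional hypothesis
#'
#' Converts the posterior probability that an effect lies in the
#' hypothesized direction into posterior odds, `p / (1 - p)`. A
#' posterior probability of 0.95 corresponds to an evidence ratio of 19
#' (the conventional "strong evidence" threshold for a directional
#' hypothesis); 0.975 corresponds to 39 (the bidirectional threshold).
#'
#' When `p` saturates at 0 or 1 the odds exceed the resolution of the
#' posterior sample; if `n_draws` is supplied the value is reported as
#' the bound `n_draws - 1` (e.g. 19999 with 20000 draws) and
#' [format_evidence_ratio()] renders it with a `">"` prefix.
#'
#' @param post_p Posterior probability in `[0, 1]`.
#' @param n_draws Number of posterior draws behind `post_p` (optional,
#'   needed only when `post_p` can saturate).
#' @return Odds (possibly the saturation bound, flagged with attribute
#'   `"saturated"`).
#' @export
#' @examples
#' evidence_ratio(0.89)   # 8.09
#' evidence_ratio(0.95)   # 19
evidence_ratio <- function(post_p, n_draws = NULL) {
  stopifnot(length(post_p) == 1L, post_p >= 0, post_p <= 1)
  if (post_p %in% c(0, 1)) {
    if (is.null(n_draws)) {
      stop("post_p saturates the posterior sample; supply n_draws to ",
           "report the resolution bound", call. = FALSE)
    }
    bound <- n_draws - 1
    return(structure(if (post_p == 1) bound else 1 / bound,
                     saturated = TRUE))
  }
  post_p / (1 - post_p)
}

#' @rdname evidence_ratio
#' @param x An evidence ratio (possibly saturated).
#' @export
format_evidence_ratio <- function(x) {
  prefix <- if (isTRUE(attr(x, "saturated"))) {
    if (x >= 1) ">" else "<"
  } else ""
  paste0(prefix, formatC(as.numeric(x), format = "f", digits = 2))
}

#' Directional hypothesis summary for one coefficient
#'
#' Summarizes the posterior draws of one coefficient for a directional
#' hypothesis: posterior mean, 90% equal-tailed interval (Q5%, Q95%),
#' the posterior probability that the effect lies on the hypothesized
#' side of zero, the corresponding evidence ratio, and the posterior
#' probability that the effect is practically equivalent to zero, i.e.
#' lies inside the region of practical equivalence (ROPE; closed
#' interval, default `[-0.036, 0.036]`).
#'
#' @param fit A `stability_fit`, or a numeric vector of posterior draws.
#' @param coefficient Coefficient name (ignored when `fit` is a vector).
#' @param direction `"<0"` or `">0"`: the hypothesized sign.
#' @param rope Length-2 ROPE interval.
#' @return One-row tibble: `coefficient`, `hypothesis`, `mean`, `q5`,
#'   `q95`, `evid_ratio`, `evid_ratio_label`, `post_p`, `rope_prob`.
#' @export
summarize_hypothesis <- function(fit, coefficient = NULL,
                                 direction = c("<0", ">0"),
                                 rope = c(-0.036, 0.036)) {
  direction <- match.arg(direction)
  stopifnot(length(rope) == 2L, rope[1] < rope[2])
  draws <- if (is.numeric(fit)) {
    as.numeric(fit)
  } else {
    dm <- posterior_draws(fit)
    if (is.null(coefficient) || !coefficient %in% colnames(dm)) {
      stop("unknown coefficient '", coefficient, "'; available: ",
           paste(colnames(dm), collapse = ", "), call. = FALSE)
    }
    dm[, coefficient]
  }
  post_p <- if (direction == "<0") mean(draws < 0) else mean(draws > 0)
  er <- evidence_ratio(post_p, n_draws = length(draws))
  q <- unname(quantile(draws, c(0.05, 0.95)))
  tibble::tibble(
    coefficient = coefficient %||% NA_character_,
    hypothesis = direction,
    mean = mean(draws),
    q5 = q[1],
    q95 = q[2],
    evid_ratio = as.numeric(er),
    evid_ratio_label = format_evidence_ratio(er),
    post_p = post_p,
    rope_prob = mean(draws >= rope[1] & draws <= rope[2])
  )
}
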