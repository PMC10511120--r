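#' Is a response sequence a pathological pattern?
#'
#' A block of responses is pathological when the participant always
#' answered "one", always answered "two", or answered "one" and "two" in
#' strict alternation over the whole block (starting with either value).
#' Such patterns indicate the task instructions were not followed.
#' Alternation must be strict: a single break in the pattern makes the
#' block non-pathological. A block of length one counts as constant.
#'
#' @param responses Integer vector over \{1, 2\}.
#' @return `TRUE`/`FALSE`, with attribute `"reason"` one of
#'   `"constant-1"`, `"constant-2"`, `"alternating"`, or `NA`.
#' @export
is_pathological <- function(responses) {
  if (length(responses) == 0L) {
    stop("response block must be non-empty", call. = FALSE)
  }
  if (!all(responses %in% c(1L, 2L))) {
    stop("responses must be 1 or 2", call. = FALSE)
  }
  reason <- NA_character_
  if (all(responses == 1L)) {
    reason <- "constant-1"
  } else if (all(responses == 2L)) {
    reason <- "constant-2"
  } else if (all(abs(diff(responses)) == 1L)) {
    reason <- "alternating"
  }
  structure(!is.na(reason), reason = reason)
}

#' Blockwise screening of response data
#'
#' Removes whole response blocks whose pattern is pathological (see
#' [is_pathological()]). Screening operates blockwise, not per
#' participant: a participant can contribute their dyad block yet lose
#' their triad block. The filter is idempotent.
#'
#' @param trials Tibble of trial rows with at least `participant`,
#'   `block`, and `response` columns (`response` in \{1, 2\}); rows
#'   within a block must be in presentation order. A `group` column, if
#'   present, is carried into the report.
#' @return A list of class `screening_result`:
#' \describe{
#'   \item{retained}{trial rows belonging to retained blocks}
#'   \item{exclusions}{one row per removed block: participant, block,
#'     (group,) reason}
#'   \item{summary}{removal counts and fraction, by group and block if
#'     available}
#' }
#' @export
screen_blocks <- function(trials) {
  stopifnot(all(c("participant", "block", "response") %in% names(trials)))
  has_group <- "group" %in% names(trials)
  keys <- c("participant", if (has_group) "group", "block")
  blocks <- trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(responses = list(.data$response), .groups = "drop")
  flags <- purrr::map(blocks$responses, is_pathological)
  blocks$pathological <- purrr::map_lgl(flags, identity)
  blocks$reason <- purrr::map_chr(flags, ~ attr(.x, "reason"))
  exclusions <- blocks |>
    dplyr::filter(.data$pathological) |>
    dplyr::select(dplyr::all_of(keys), "reason")
  retained <- dplyr::anti_join(trials, exclusions, by = keys)
  summ <- blocks |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c(if (has_group) "group", "block")))) |>
    dplyr::summarise(
      n_blocks = dplyr::n(),
      n_removed = sum(.data$pathological),
      fraction_removed = mean(.data$pathological),
      .groups = "drop"
    )
  structure(
    list(retained = retained, exclusions = exclusions, summary = summ),
    class = "screening_result"
  )
}

#' @export
print.screening_result <- function(x, ...) {
  n_total <- sum(x$summary$n_blocks)
  n_rm <- sum(x$summary$n_removed)
  cat("<screening_result> removed ", n_rm, " of ", n_total, " blocks (",
      round(100 * n_rm / n_total, 1), "%)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.screening_result <- function(x, ...) x$exclusions

#' @export
glance.screening_result <- function(x, ...) {
  tibble::tibble(
    n_blocks = sum(x$summary$n_blocks),
    n_removed = sum(x$summary$n_removed),
    fraction_removed = sum(x$summary$n_removed) / sum(x$summary$n_blocks)
  )
}

#' Write a screening exclusion report
#'
#' @param result A `screening_result`.
#' @param path TSV path; a JSON copy is written alongside.
#' @return `path`, invisibly.
#' @export
write_screening_report <- function(result, path) {
  readr::write_tsv(result$exclusions, path)
  jsonlite::write_json(result$exclusions, sub("\\.[^.]+$", ".json", path),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
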