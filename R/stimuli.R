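#' The seven triad types
#'
#' Chords are classified by Tn-type: the set of semitone offsets above a
#' root, octave-reduced, invariant to transposition and octave placement.
#' The experiment uses seven three-tone types: major, minor, augmented,
#' the semitone cluster, a dominant-seventh subset (root, third, seventh),
#' a half-diminished subset (root, fifth, seventh), and a seventh chord
#' with no third.
#'
#' @return A tibble with columns `name` and `intervals` (list-column of
#'   integer offsets above the root, each within 0..11).
#' @export
#' @examples
#' tn_types()
tn_types <- function() {
  tibble::tibble(
    name = c("major", "minor", "augmented", "semitone cluster",
             "dom7-subset", "half-dim-subset", "7th-no-3rd"),
    intervals = list(
      c(0L, 4L, 7L),   # major
      c(0L, 3L, 7L),   # minor
      c(0L, 4L, 8L),   # augmented
      c(0L, 1L, 2L),   # semitone cluster
      c(0L, 4L, 10L),  # dominant seventh: root, major third, minor seventh
      c(0L, 6L, 10L),  # half-diminished: root, diminished fifth, minor seventh
      c(0L, 7L, 10L)   # seventh with no third: root, fifth, minor seventh
    )
  )
}

#' Construct a chord from a Tn-type
#'
#' Realizes a named Tn-type above a root pitch, in closed position (all
#' offsets packed within one octave above the root) or open position (the
#' middle tone raised one octave).
#'
#' Pitches follow the standard note-number convention: semitone units in
#' 12-tone equal temperament with pitch 69 sounding at 440 Hz.
#'
#' @param type Name of a Tn-type (see [tn_types()]), or an integer vector
#'   of octave-reduced offsets above the root.
#' @param root Root pitch in semitones.
#' @param voicing `"closed"` or `"open"`.
#' @return Numeric vector of ascending pitches.
#' @export
#' @examples
#' make_tn_chord("major", 60)           # C major: 60 64 67
#' make_tn_chord("major", 60, "open")   # 60 67 76
make_tn_chord <- function(type, root, voicing = c("closed", "open")) {
  voicing <- match.arg(voicing)
  if (is.character(type)) {
    types <- tn_types()
    idx <- match(type, types$name)
    if (is.na(idx)) {
      stop("unknown Tn-type '", type, "'; see tn_types() for the valid names",
           call. = FALSE)
    }
    offs <- types$intervals[[idx]]
  } else {
    offs <- as.integer(type)
    if (any(offs < 0L | offs > 11L)) {
      stop("Tn-type offsets must lie in 0..11", call. = FALSE)
    }
  }
  stopifnot(is.numeric(root), length(root) == 1L, is.finite(root))
  pitches <- sort(root + offs)
  if (voicing == "open" && length(pitches) == 3L) {
    pitches[2L] <- pitches[2L] + 12
    pitches <- sort(pitches)
  }
  pitches
}

#' Octave-reduced interval classification of a chord
#'
#' Recovers the set of semitone offsets above the lowest tone, modulo 12.
#' Round-trips with [make_tn_chord()]: a chord generated from a type, in
#' either voicing and at any transposition, classifies back to that type.
#'
#' @param pitches Numeric vector of chord pitches (semitones).
#' @return Sorted integer vector of distinct octave-reduced offsets.
#' @export
tn_type_of <- function(pitches) {
  check_chord(pitches)
  sort(unique(as.integer(round(pitches - min(pitches))) %% 12L))
}

check_chord <- function(pitches) {
  if (length(pitches) == 0L) {
    stop("a chord must contain at least one pitch", call. = FALSE)
  }
  if (!all(is.finite(pitches))) {
    stop("chord pitches must all be finite", call. = FALSE)
  }
  if (is.unsorted(pitches)) {
    stop("chord pitches must be sorted ascending", call. = FALSE)
  }
  invisible(pitches)
}

#' Dyad width and chord mean pitch
#'
#' `dyad_width()` is the semitone distance between the two pitches of a
#' dyad; `mean_pitch()` is the arithmetic mean of the notated pitches
#' (a log-frequency measure, so the mean is taken in semitone units).
#'
#' @param pitches Numeric vector of chord pitches (semitones).
#' @return A single number.
#' @export
dyad_width <- function(pitches) {
  check_chord(pitches)
  if (length(pitches) != 2L) stop("width is defined for dyads only", call. = FALSE)
  pitches[2L] - pitches[1L]
}

#' @rdname dyad_width
#' @export
mean_pitch <- function(pitches) {
  check_chord(pitches)
  mean(pitches)
}

#' Enumerate ordered dyad pairs under width and mean-pitch constraints
#'
#' All dyad widths from 0 (unison) up to `max_width` semitones are
#' considered, and ordered pairs of widths are kept when the widths differ
#' by no more than `max_width_diff` semitones. Each retained pair is
#' realized so that the two dyads share the same mean pitch (centred on
#' `centre_pitch`), which automatically satisfies the mean-pitch
#' constraint (difference at most `max_meanpitch_diff` semitones). The
#' enumeration is deterministic and the resulting pair count is reported
#' with a message.
#'
#' @param max_width Largest dyad width in semitones.
#' @param max_width_diff Largest permitted width difference within a pair.
#' @param max_meanpitch_diff Largest permitted mean-pitch difference.
#' @param centre_pitch Mean pitch at which each dyad is realized.
#' @param include_equal_widths Keep pairs whose two widths are equal.
#' @param quiet Suppress the count message.
#' @return A tibble with one row per ordered pair: `pair_id`, `width1`,
#'   `width2`, list-columns `chord1` and `chord2` (pitch vectors), and the
#'   realized `mean_pitch1`, `mean_pitch2`.
#' @export
enumerate_dyad_pairs <- function(max_width = 15, max_width_diff = 3,
                                 max_meanpitch_diff = 0.5,
                                 centre_pitch = 60,
                                 include_equal_widths = TRUE,
                                 quiet = FALSE) {
  stopifnot(max_width >= 0, max_width_diff >= 0, max_meanpitch_diff >= 0)
  widths <- 0:max_width
  grid <- tidyr::expand_grid(width1 = widths, width2 = widths) |>
    dplyr::filter(abs(.data$width1 - .data$width2) <= max_width_diff)
  if (!include_equal_widths) {
    grid <- dplyr::filter(grid, .data$width1 != .data$width2)
  }
  realize <- function(w) sort(c(centre_pitch - w / 2, centre_pitch + w / 2))
  out <- grid |>
    dplyr::mutate(
      pair_id = dplyr::row_number(),
      chord1 = purrr::map(.data$width1, realize),
      chord2 = purrr::map(.data$width2, realize),
      mean_pitch1 = purrr::map_dbl(.data$chord1, mean_pitch),
      mean_pitch2 = purrr::map_dbl(.data$chord2, mean_pitch)
    ) |>
    dplyr::relocate("pair_id")
  bad <- abs(out$mean_pitch1 - out$mean_pitch2) > max_meanpitch_diff
  out <- out[!bad, , drop = FALSE]
  if (!quiet) {
    message("enumerated ", nrow(out), " ordered dyad pairs (widths 0..",
            max_width, ", width diff <= ", max_width_diff,
            ", mean-pitch diff <= ", max_meanpitch_diff, ")")
  }
  out
}

#' Enumerate ordered triad-type pairs
#'
#' Ordered pairs of the seven triad types, each type realized in closed
#' and (optionally) open position. Pitches of the two triads in a pair
#' are chosen to minimize the difference between their mean pitches: the
#' second triad's root is offset so the two mean pitches agree as closely
#' as integer-semitone roots allow.
#'
#' @param centre_pitch Approximate mean pitch of the realized triads.
#' @param voicings Character vector of voicings to include.
#' @param quiet Suppress the count message.
#' @return A tibble with one row per ordered pair of distinct
#'   (type, voicing) combinations: `pair_id`, `type1`, `voicing1`,
#'   `type2`, `voicing2`, list-columns `chord1`, `chord2`, and the
#'   realized mean pitches.
#' @export
enumerate_triad_pairs <- function(centre_pitch = 60,
                                  voicings = c("closed", "open"),
                                  quiet = FALSE) {
  types <- tn_types()
  combos <- tidyr::expand_grid(type = types$name, voicing = voicings)
  base_root <- round(centre_pitch)
  realize <- function(type, voicing, target_mean) {
    c0 <- make_tn_chord(type, base_root, voicing)
    # integer root shift bringing the triad's mean pitch closest to target
    shift <- round(target_mean - mean(c0))
    c0 + shift
  }
  grid <- tidyr::expand_grid(i = seq_len(nrow(combos)), j = seq_len(nrow(combos))) |>
    dplyr::filter(.data$i != .data$j)
  out <- grid |>
    dplyr::mutate(
      pair_id = dplyr::row_number(),
      type1 = combos$type[.data$i], voicing1 = combos$voicing[.data$i],
      type2 = combos$type[.data$j], voicing2 = combos$voicing[.data$j],
      chord1 = purrr::map2(.data$type1, .data$voicing1,
                           ~ realize(.x, .y, centre_pitch)),
      chord2 = purrr::pmap(list(.data$type2, .data$voicing2, .data$chord1),
                           function(t, v, c1) realize(t, v, mean(c1))),
      mean_pitch1 = purrr::map_dbl(.data$chord1, mean),
      mean_pitch2 = purrr::map_dbl(.data$chord2, mean)
    ) |>
    dplyr::select(-"i", -"j")
  if (!quiet) {
    message("enumerated ", nrow(out), " ordered triad pairs (",
            nrow(combos), " type/voicing combinations)")
  }
  out
}

#' Build counterbalanced stimulus-set versions
#'
#' Splits the enumerated ordered pairs into per-participant versions:
#' each version holds a subset of `n_dyad_pairs` dyad pairs and
#' `n_triad_pairs` triad pairs, is assigned one of two timbres
#' (counterbalanced across versions), and every pair receives a random
#' transposition within one octave (uniform on `[0, 12)` semitones) from
#' a seeded generator. The block layout follows the experiment: the dyad
#' pairs are split over two 30-trial blocks, the triad pairs form one
#' block.
#'
#' @param dyad_pairs Tibble from [enumerate_dyad_pairs()].
#' @param triad_pairs Tibble from [enumerate_triad_pairs()].
#' @param n_versions Number of counterbalanced versions.
#' @param n_dyad_pairs,n_triad_pairs Pairs per version.
#' @param timbres Two timbre names to counterbalance.
#' @param seed Integer seed; identical seeds give identical sets.
#' @return A tibble with one row per presented pair: `version`, `timbre`,
#'   `block` (dyads1/dyads2/triads), `trial`, `pair_id`, `transposition`,
#'   and transposed `chord1`, `chord2` list-columns.
#' @export
build_stimulus_sets <- function(dyad_pairs, triad_pairs,
                                n_versions = 12,
                                n_dyad_pairs = 60, n_triad_pairs = 42,
                                timbres = c("vocal", "string"),
                                seed = 1L) {
  if (nrow(dyad_pairs) < n_dyad_pairs) {
    stop("need at least ", n_dyad_pairs, " dyad pairs, got ",
         nrow(dyad_pairs), call. = FALSE)
  }
  if (nrow(triad_pairs) < n_triad_pairs) {
    stop("need at least ", n_triad_pairs, " triad pairs, got ",
         nrow(triad_pairs), call. = FALSE)
  }
  stopifnot(length(timbres) == 2L)
  rng <- local_rng(seed)
  one_version <- function(v) {
    dsel <- dyad_pairs[sample.int(nrow(dyad_pairs), n_dyad_pairs), ]
    tsel <- triad_pairs[sample.int(nrow(triad_pairs), n_triad_pairs), ]
    half <- ceiling(n_dyad_pairs / 2)
    block <- c(rep("dyads1", half), rep("dyads2", n_dyad_pairs - half),
               rep("triads", n_triad_pairs))
    sel <- dplyr::bind_rows(
      dplyr::select(dsel, "pair_id", "chord1", "chord2"),
      dplyr::select(tsel, "pair_id", "chord1", "chord2")
    )
    sel$block <- block
    sel$trial <- c(seq_len(n_dyad_pairs),
                   n_dyad_pairs + seq_len(n_triad_pairs))
    sel$transposition <- runif(nrow(sel), 0, 12)
    sel$version <- v
    sel$timbre <- timbres[(v - 1L) %% 2L + 1L]
    sel$chord1 <- purrr::map2(sel$chord1, sel$transposition, `+`)
    sel$chord2 <- purrr::map2(sel$chord2, sel$transposition, `+`)
    sel
  }
  purrr::map(seq_len(n_versions), one_version) |>
    dplyr::bind_rows() |>
    dplyr::select("version", "timbre", "block", "trial", "pair_id",
                  "transposition", "chord1", "chord2") |>
    tibble::as_tibble()
}

#' Write a stimulus set to delimited text and a JSON manifest
#'
#' @param sets Tibble from [build_stimulus_sets()].
#' @param path Path of the TSV file to write; a `.json` manifest with the
#'   version/timbre layout is written alongside it.
#' @return `path`, invisibly.
#' @export
write_stimulus_sets <- function(sets, path) {
  flat <- sets |>
    dplyr::mutate(
      chord1 = purrr::map_chr(.data$chord1, ~ paste(round(.x, 4), collapse = " ")),
      chord2 = purrr::map_chr(.data$chord2, ~ paste(round(.x, 4), collapse = " "))
    )
  readr::write_tsv(flat, path)
  manifest <- sets |>
    dplyr::distinct(.data$version, .data$timbre) |>
    dplyr::mutate(n_pairs = purrr::map_int(
      .data$version, ~ sum(sets$version == .x)))
  jsonlite::write_json(manifest, sub("\\.[^.]+$", ".json", path),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
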