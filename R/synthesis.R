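#' Timbre presets for additive synthesis
#'
#' A timbre preset maps harmonic number `h >= 1` to a linear amplitude.
#' Three presets are provided:
#'
#' * `"idealized"`: 36 harmonics with amplitude `1/h` — the idealized
#'   harmonic-complex-tone spectrum used for notation-based feature
#'   calculation.
#' * `"vocal"`: `1/h` shaped by two broad formant bumps (centred near
#'   500 Hz and 1500 Hz at the rendered frequency), a spectrally
#'   plausible stand-in for a sung vowel.
#' * `"string"`: `1/h` with a mild high-frequency boost.
#'
#' The vocal and string presets exist to test feature sensitivity to
#' timbre; they emulate no particular instrument.
#'
#' @param name Preset name.
#' @param n_partials Number of harmonics.
#' @param attack,release Raised-cosine fade durations in seconds.
#' @return A list of class `timbre_preset` with elements `name`,
#'   `n_partials`, `amplitude_fn(h, f0)`, `attack`, `release`.
#' @export
#' @examples
#' tp <- timbre_preset("idealized")
#' tp$amplitude_fn(1:4, 440)   # 1, 1/2, 1/3, 1/4
timbre_preset <- function(name = c("idealized", "vocal", "string"),
                          n_partials = 36L,
                          attack = 0.01, release = 0.01) {
  name <- match.arg(name)
  stopifnot(n_partials >= 1L, attack >= 0, release >= 0)
  amplitude_fn <- switch(
    name,
    idealized = function(h, f0) 1 / h,
    vocal = function(h, f0) {
      f <- h * f0
      formant <- 1 + 1.5 * exp(-((f - 500) / 250)^2) +
        0.8 * exp(-((f - 1500) / 400)^2)
      formant / h
    },
    string = function(h, f0) {
      f <- h * f0
      (1 + 0.3 * pmin(f / 4000, 1)) / h
    }
  )
  structure(
    list(name = name, n_partials = as.integer(n_partials),
         amplitude_fn = amplitude_fn, attack = attack, release = release),
    class = "timbre_preset"
  )
}

#' Convert between semitone pitch and frequency
#'
#' Standard note-number convention: pitch 69 sounds at 440 Hz, 12-tone
#' equal temperament.
#'
#' @param pitch Pitch in semitones.
#' @param freq Frequency in Hz.
#' @return Frequency in Hz, or pitch in semitones.
#' @export
pitch_to_freq <- function(pitch) 440 * 2^((pitch - 69) / 12)

#' @rdname pitch_to_freq
#' @export
freq_to_pitch <- function(freq) 69 + 12 * log2(freq / 440)

#' Render a chord to audio by additive synthesis
#'
#' Each chord tone contributes `timbre$n_partials` sinusoidal harmonics
#' at integer multiples of its fundamental, with amplitudes from the
#' preset's amplitude rule; partials at or above the Nyquist frequency
#' are dropped. The summed signal is peak-normalized and given
#' raised-cosine attack and release fades. Synthesis is deterministic.
#'
#' @param pitches Numeric vector of chord pitches (semitones; 69 = 440 Hz).
#' @param timbre A [timbre_preset()].
#' @param duration Duration in seconds.
#' @param sample_rate Sample rate in Hz.
#' @return An object of class `rendered_stimulus`: list with `samples`,
#'   `sample_rate`, `pitches`, `timbre` (the preset name).
#' @export
#' @examples
#' stim <- render_chord(c(60, 64, 67), timbre_preset("idealized"),
#'                      duration = 0.25, sample_rate = 22050)
#' range(stim$samples)
render_chord <- function(pitches, timbre = timbre_preset(),
                         duration = 1.0, sample_rate = 44100) {
  check_chord(pitches)
  stopifnot(inherits(timbre, "timbre_preset"), duration > 0, sample_rate > 0)
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  nyquist <- sample_rate / 2
  samples <- numeric(n)
  any_partial <- FALSE
  for (p in pitches) {
    f0 <- pitch_to_freq(p)
    h <- seq_len(timbre$n_partials)
    h <- h[h * f0 < nyquist]
    if (length(h) == 0L) next
    any_partial <- TRUE
    amps <- timbre$amplitude_fn(h, f0)
    for (k in seq_along(h)) {
      samples <- samples + amps[k] * sin(2 * pi * h[k] * f0 * t)
    }
  }
  if (!any_partial) {
    stop("all partials lie at or above the Nyquist frequency (",
         nyquist, " Hz)", call. = FALSE)
  }
  peak <- max(abs(samples))
  if (peak > 0) samples <- samples / peak
  samples <- apply_fades(samples, sample_rate, timbre$attack, timbre$release)
  structure(
    list(samples = samples, sample_rate = sample_rate,
         pitches = pitches, timbre = timbre$name),
    class = "rendered_stimulus"
  )
}

apply_fades <- function(samples, sample_rate, attack, release) {
  n <- length(samples)
  na <- min(n, round(attack * sample_rate))
  nr <- min(n, round(release * sample_rate))
  if (na > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(na) / na))
    samples[seq_len(na)] <- samples[seq_len(na)] * ramp
  }
  if (nr > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    idx <- n - seq_len(nr) + 1L
    samples[idx] <- samples[idx] * ramp
  }
  samples
}

#' @export
print.rendered_stimulus <- function(x, ...) {
  cat("<rendered_stimulus> ", length(x$samples), " samples @ ",
      x$sample_rate, " Hz, pitches [",
      paste(round(x$pitches, 2), collapse = ", "),
      "], timbre '", x$timbre, "'\n", sep = "")
  invisible(x)
}
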