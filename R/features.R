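#' Construct a partial spectrum
#'
#' A partial spectrum is the list of sinusoidal components of a sound:
#' (frequency, amplitude) pairs with strictly positive, strictly
#' increasing frequencies and non-negative linear amplitudes.
#'
#' @param frequency Frequencies in Hz.
#' @param amplitude Linear amplitudes.
#' @return A tibble of class `partial_spectrum`.
#' @export
partial_spectrum <- function(frequency, amplitude) {
  stopifnot(length(frequency) == length(amplitude), length(frequency) >= 1L)
  if (any(!is.finite(frequency)) || any(frequency <= 0)) {
    stop("partial frequencies must be finite and strictly positive",
         call. = FALSE)
  }
  if (any(diff(frequency) <= 0)) {
    stop("partial frequencies must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(amplitude)) || any(amplitude < 0)) {
    stop("partial amplitudes must be finite and non-negative", call. = FALSE)
  }
  out <- tibble::tibble(frequency = as.numeric(frequency),
                        amplitude = as.numeric(amplitude))
  class(out) <- c("partial_spectrum", class(out))
  out
}

#' Idealized partial spectrum of a notated chord
#'
#' Treats every notated pitch as a harmonic complex tone with
#' `n_harmonics` harmonics of amplitude `1/h` (harmonic number `h`).
#' This is the idealized, notation-based spectrum; coincident
#' frequencies across tones have their amplitudes summed.
#'
#' @param pitches Chord pitches in semitones (69 = 440 Hz).
#' @param n_harmonics Harmonics per tone.
#' @return A `partial_spectrum`.
#' @export
#' @examples
#' idealized_partials(c(60, 67), n_harmonics = 4)
idealized_partials <- function(pitches, n_harmonics = 36L) {
  check_chord(pitches)
  stopifnot(n_harmonics >= 1L)
  h <- seq_len(n_harmonics)
  df <- purrr::map(pitches, function(p) {
    tibble::tibble(frequency = pitch_to_freq(p) * h, amplitude = 1 / h)
  }) |>
    dplyr::bind_rows() |>
    dplyr::group_by(frequency = round(.data$frequency, 6)) |>
    dplyr::summarise(amplitude = sum(.data$amplitude), .groups = "drop") |>
    dplyr::arrange(.data$frequency)
  partial_spectrum(df$frequency, df$amplitude)
}

#' Extract partials from a rendered stimulus
#'
#' Computes a Hann-windowed magnitude spectrum and keeps local maxima
#' lying above `floor_db` decibels relative to the strongest peak.
#' Peak frequencies and amplitudes are refined by quadratic
#' interpolation of log magnitude around each maximum.
#'
#' @param stimulus A `rendered_stimulus` (see [render_chord()], [read_wav()]).
#' @param floor_db Threshold relative to the strongest peak, in dB (negative).
#' @param min_freq Discard peaks below this frequency (Hz).
#' @return A `partial_spectrum`.
#' @export
extract_partials <- function(stimulus, floor_db = -60, min_freq = 25) {
  x <- stimulus$samples
  sr <- stimulus$sample_rate
  if (length(x) == 0L || all(x == 0) || sd(x) < 1e-12) {
    stop("cannot extract partials from silent input", call. = FALSE)
  }
  stopifnot(floor_db < 0)
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))   # Hann
  spec <- Mod(fft(x * w))[seq_len(floor(n / 2))]
  amp <- 2 * spec / sum(w)
  freqs <- (seq_along(amp) - 1) * sr / n
  k <- 2:(length(amp) - 1)
  is_peak <- amp[k] > amp[k - 1] & amp[k] >= amp[k + 1]
  peaks <- k[is_peak]
  peaks <- peaks[freqs[peaks] >= min_freq & amp[peaks] > 0]
  if (length(peaks) == 0L) {
    stop("no spectral peaks found above ", min_freq, " Hz", call. = FALSE)
  }
  thresh <- max(amp[peaks]) * 10^(floor_db / 20)
  peaks <- peaks[amp[peaks] >= thresh]
  refine <- function(i) {
    la <- log(pmax(amp[(i - 1):(i + 1)], 1e-300))
    denom <- la[1] - 2 * la[2] + la[3]
    delta <- if (abs(denom) > 1e-12) 0.5 * (la[1] - la[3]) / denom else 0
    delta <- max(-0.5, min(0.5, delta))
    c(freq = freqs[i] + delta * sr / n,
      amp = exp(la[2] - 0.25 * (la[1] - la[3]) * delta))
  }
  ref <- t(vapply(peaks, refine, c(freq = 0, amp = 0)))
  ord <- order(ref[, "freq"])
  partial_spectrum(ref[ord, "freq"], ref[ord, "amp"])
}

# Sethares parameterization of the Plomp-Levelt dissonance curve. The
# kernel peaks near a quarter of the critical bandwidth at the lower
# partial's frequency and decays to zero both at unison and for widely
# separated partials. Constants are the published Sethares values.
.rough_const <- list(b1 = 3.51, b2 = 5.75, dstar = 0.24,
                     s1 = 0.0207, s2 = 18.96)

roughness_kernel <- function(f_low, f_high, a1, a2) {
  k <- .rough_const
  s <- k$dstar / (k$s1 * f_low + k$s2)
  df <- f_high - f_low
  (a1 * a2) * (exp(-k$b1 * s * df) - exp(-k$b2 * s * df))
}

#' Roughness of a partial spectrum
#'
#' Roughness models the rapid beating (loudness undulation) produced by
#' frequency components too close to be resolved by the auditory system.
#' It is computed as the sum, over all unordered pairs of partials, of an
#' amplitude-product-weighted Plomp-Levelt dissonance kernel in the
#' Sethares parameterization: the kernel is zero at unison, peaks when
#' the frequency separation is near a quarter of the critical bandwidth
#' at the lower frequency, and decays to zero for well-separated
#' partials. A single partial has roughness 0.
#'
#' @param spectrum A `partial_spectrum`.
#' @return Non-negative unitless roughness.
#' @export
#' @examples
#' s <- partial_spectrum(c(440, 466.16), c(1, 1))
#' roughness(s)
roughness <- function(spectrum) {
  f <- spectrum$frequency
  a <- spectrum$amplitude
  n <- length(f)
  if (n < 2L) return(0)
  total <- 0
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    total <- total + sum(roughness_kernel(f[i], f[j], a[i], a[j]))
  }
  total
}

#' Perceptually smoothed log-frequency spectrum
#'
#' Projects a partial spectrum onto a cents grid (1200 cents per octave)
#' and smooths it to represent the inaccuracy of pitch perception: each
#' partial contributes a Gaussian bump with standard deviation `sd`
#' cents whose total area equals the partial's amplitude weight. The
#' grid is anchored at the first partial's log-frequency position, so
#' transposing every partial by a common cents offset leaves the weight
#' vector unchanged.
#'
#' @param spectrum A `partial_spectrum`.
#' @param resolution Grid resolution in cents per bin.
#' @param sd Smoothing standard deviation in cents.
#' @param pad Grid padding beyond the outermost partials, in multiples of `sd`.
#' @return An object of class `smoothed_spectrum`: list with `weights`,
#'   `resolution`, `sd`, and `origin` (cents position of the first bin
#'   relative to the first partial).
#' @export
smooth_spectrum <- function(spectrum, resolution = 1, sd = 6, pad = 6) {
  stopifnot(sd > 0, resolution > 0)
  f <- spectrum$frequency
  a <- spectrum$amplitude
  pos <- 1200 * log2(f / f[1])              # cents relative to first partial
  lo <- floor((min(pos) - pad * sd) / resolution)
  hi <- ceiling((max(pos) + pad * sd) / resolution)
  bins <- (lo:hi) * resolution
  weights <- numeric(length(bins))
  half_width <- ceiling(pad * sd / resolution)
  for (i in seq_along(pos)) {
    centre <- round((pos[i] - bins[1]) / resolution) + 1L
    idx <- max(1L, centre - half_width):min(length(bins), centre + half_width)
    g <- exp(-0.5 * ((bins[idx] - pos[i]) / sd)^2)
    weights[idx] <- weights[idx] + a[i] * g / sum(g)
  }
  structure(
    list(weights = weights, resolution = resolution, sd = sd,
         origin = bins[1]),
    class = "smoothed_spectrum"
  )
}

#' Harmonic template for harmonicity calculation
#'
#' The template is a harmonic complex tone with `n_harmonics` harmonics
#' whose amplitudes roll off as `h^(-rolloff)`.
#'
#' @param n_harmonics Number of harmonics.
#' @param rolloff Amplitude roll-off exponent.
#' @param f0 Nominal fundamental in Hz (irrelevant to harmonicity, which
#'   is transposition invariant).
#' @return A `partial_spectrum`.
#' @export
harmonic_template <- function(n_harmonics = 12L, rolloff = 0.75, f0 = 100) {
  stopifnot(n_harmonics >= 1L)
  h <- seq_len(n_harmonics)
  partial_spectrum(f0 * h, h^(-rolloff))
}

#' Harmonicity of a smoothed spectrum
#'
#' Harmonicity quantifies the similarity of a sound's spectrum to that of
#' a single harmonic complex tone (such as a vowel sound), allowing for
#' the inaccuracy of pitch perception. It is the maximum, over all
#' candidate fundamental positions (grid shifts), of the cosine
#' similarity between the smoothed spectrum and an equally smoothed
#' harmonic-template spectrum. By construction it lies in `[0, 1]`, and
#' it is invariant to global amplitude rescaling and to transposition.
#'
#' @param smoothed A `smoothed_spectrum`.
#' @param n_harmonics,rolloff Template parameters (see [harmonic_template()]).
#' @return Harmonicity in `[0, 1]`.
#' @export
harmonicity <- function(smoothed, n_harmonics = 12L, rolloff = 0.75) {
  w <- smoothed$weights
  if (all(w == 0)) stop("all-zero spectrum", call. = FALSE)
  tmpl <- smooth_spectrum(harmonic_template(n_harmonics, rolloff),
                          resolution = smoothed$resolution,
                          sd = smoothed$sd)
  v <- tmpl$weights
  # sliding dot products of w against v at every integer-bin lag
  cc <- convolve(w, v, type = "open")
  max(cc) / sqrt(sum(w^2) * sum(v^2))
}

#' Spectral entropy of a smoothed spectrum
#'
#' Shannon entropy (natural log, nats) of the smoothed spectral weight
#' vector normalized to sum to one. Quantifies the complexity of the
#' spectrum given the inaccuracy of pitch perception: 0 for all mass in
#' one bin, `log(n_bins)` for a uniform spectrum. Invariant to amplitude
#' rescaling.
#'
#' @param smoothed A `smoothed_spectrum`.
#' @return Entropy in nats.
#' @export
spectral_entropy <- function(smoothed) {
  w <- smoothed$weights
  total <- sum(w)
  if (total <= 0) stop("all-zero spectrum", call. = FALSE)
  p <- w / total
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Psychoacoustic feature set of one chord
#'
#' Computes the four predictors for a single chord: roughness,
#' harmonicity and spectral entropy from its (rendered or idealized)
#' partial spectrum, and mean pitch from its notation. The default
#' `source = "audio"` renders the chord and extracts partials from the
#' signal, matching the principle that audio features are measured from
#' the sound actually heard; `source = "idealized"` uses the notation
#' based 36-harmonic `1/h` spectrum instead and is labelled as such in
#' the output.
#'
#' @param pitches Chord pitches (semitones).
#' @param source `"audio"` or `"idealized"`.
#' @param timbre [timbre_preset()] for audio rendering.
#' @param duration,sample_rate Render settings for the audio path.
#' @param floor_db Peak-picking threshold, dB below the strongest peak.
#' @param resolution,sd Smoothing grid settings (cents).
#' @param n_harmonics,rolloff Harmonic-template settings.
#' @return One-row tibble: `roughness`, `harmonicity`, `spectral_entropy`,
#'   `mean_pitch`, `source`.
#' @export
#' @examples
#' chord_features(c(60, 64, 67), source = "idealized")
chord_features <- function(pitches, source = c("audio", "idealized"),
                           timbre = timbre_preset("idealized"),
                           duration = 0.5, sample_rate = 44100,
                           floor_db = -60,
                           resolution = 1, sd = 6,
                           n_harmonics = 12L, rolloff = 0.75) {
  source <- match.arg(source)
  spec <- if (source == "audio") {
    stim <- render_chord(pitches, timbre, duration, sample_rate)
    extract_partials(stim, floor_db = floor_db)
  } else {
    idealized_partials(pitches, n_harmonics = 36L)
  }
  sm <- smooth_spectrum(spec, resolution = resolution, sd = sd)
  tibble::tibble(
    roughness = roughness(spec),
    harmonicity = harmonicity(sm, n_harmonics, rolloff),
    spectral_entropy = spectral_entropy(sm),
    mean_pitch = mean_pitch(pitches),
    source = source
  )
}

#' Per-trial feature changes
#'
#' In each trial the participant hears an ordered chord pair and then
#' the same pair reversed, and judges which pair has "finished". Each
#' feature's predictor is its change from the penultimate (third) chord
#' to the final (fourth) chord; because the second pair reverses the
#' first, this change is the negative of the change from the first chord
#' to the second, so one delta per feature suffices.
#'
#' @param third,fourth One-row feature tibbles (see [chord_features()])
#'   for the third (penultimate) and fourth (final) chords.
#' @return One-row tibble of `d_roughness`, `d_harmonicity`,
#'   `d_spectral_entropy`, `d_mean_pitch`.
#' @export
delta_features <- function(third, fourth) {
  cols <- c("roughness", "harmonicity", "spectral_entropy", "mean_pitch")
  stopifnot(all(cols %in% names(third)), all(cols %in% names(fourth)))
  out <- purrr::map(cols, ~ fourth[[.x]] - third[[.x]])
  names(out) <- paste0("d_", cols)
  tibble::as_tibble(out)
}

#' Standardize per-trial feature deltas
#'
#' Z-scores the roughness, harmonicity and spectral-entropy deltas over
#' the supplied trial set; the mean-pitch delta is left in semitone
#' units. The scaling (means and standard deviations) is recorded in the
#' `"scaling"` attribute so it can be re-applied to new data with
#' [apply_delta_scaling()].
#'
#' @param trials Tibble with columns `d_roughness`, `d_harmonicity`,
#'   `d_spectral_entropy` (and optionally `d_mean_pitch`, untouched).
#' @return `trials` with the three columns standardized; attribute
#'   `scaling` is a tibble (feature, mean, sd).
#' @export
standardize_deltas <- function(trials) {
  cols <- intersect(c("d_roughness", "d_harmonicity", "d_spectral_entropy"),
                    names(trials))
  scaling <- tibble::tibble(
    feature = cols,
    mean = purrr::map_dbl(cols, ~ mean(trials[[.x]])),
    sd = purrr::map_dbl(cols, ~ sd(trials[[.x]]))
  )
  zero <- scaling$feature[scaling$sd == 0 | !is.finite(scaling$sd)]
  if (length(zero) > 0) {
    stop("cannot standardize zero-variance feature(s): ",
         paste(zero, collapse = ", "), call. = FALSE)
  }
  apply_delta_scaling(trials, scaling)
}

#' @rdname standardize_deltas
#' @param scaling A scaling tibble from a previous [standardize_deltas()] call
#'   (its `"scaling"` attribute).
#' @export
apply_delta_scaling <- function(trials, scaling) {
  for (i in seq_len(nrow(scaling))) {
    f <- scaling$feature[i]
    trials[[f]] <- (trials[[f]] - scaling$mean[i]) / scaling$sd[i]
  }
  attr(trials, "scaling") <- scaling
  trials
}
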