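# Minimal RIFF/WAVE PCM-16 reader and writer. Mono on write; stereo
# accepted on read and down-mixed by channel averaging.

#' Write a rendered stimulus to a 16-bit PCM WAV file
#'
#' @param stimulus A `rendered_stimulus` (see [render_chord()]), or any
#'   list with numeric `samples` in `[-1, 1]` and a `sample_rate`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(stimulus, path) {
  samples <- stimulus$samples
  sr <- as.integer(stimulus$sample_rate)
  stopifnot(is.numeric(samples), length(samples) > 0, sr > 0)
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_bytes, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L, con, size = 4, endian = "little")      # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' Stereo files are down-mixed to mono by averaging the two channels.
#'
#' @param path Path to a WAV file.
#' @return An object of class `rendered_stimulus` with `samples` scaled
#'   to `[-1, 1]`, `sample_rate`, `pitches = NULL` and `timbre = NA`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    stop("WAV file not found: ", path, call. = FALSE)
  }
  size <- file.info(path)$size
  if (is.na(size) || size < 44) {
    stop("not a readable WAV file (too short): ", path, call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  }
  sr <- NULL; n_channels <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4) break
    len <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (fmt != 1L) stop("only PCM WAV is supported: ", path, call. = FALSE)
      n_channels <- readBin(con, "integer", 1, size = 2, endian = "little")
      sr <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")  # byte rate
      readBin(con, "integer", 1, size = 2, endian = "little")  # block align
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (bits != 16L) stop("only 16-bit PCM is supported: ", path, call. = FALSE)
      extra <- len - 16L
      if (extra > 0) readBin(con, "raw", extra)
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", len / 2L, size = 2,
                         endian = "little", signed = TRUE)
      break
    } else {
      readBin(con, "raw", len)
    }
  }
  if (is.null(sr) || is.null(samples)) {
    stop("malformed WAV file (missing fmt or data chunk): ", path,
         call. = FALSE)
  }
  x <- samples / 32767
  if (n_channels == 2L) {
    x <- (x[seq(1, length(x), by = 2)] + x[seq(2, length(x), by = 2)]) / 2
  } else if (n_channels != 1L) {
    stop("only mono or stereo WAV is supported: ", path, call. = FALSE)
  }
  structure(
    list(samples = x, sample_rate = sr, pitches = NULL, timbre = NA_character_),
    class = "rendered_stimulus"
  )
}
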