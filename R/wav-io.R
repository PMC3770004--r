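#' Read a mono 16-bit PCM WAV recording
#'
#' Parses a RIFF/WAVE file and returns the raw integer samples together
#' with subject metadata. Only uncompressed PCM, single-channel, 16-bit
#' content is accepted; anything else is rejected rather than silently
#' downmixed or requantized, so that every recording entering the pipeline
#' has the acquisition format the method assumes.
#'
#' @param path path to a `.wav` file.
#' @param subject_id,gender,age subject metadata carried alongside the
#'   samples; `gender` must be `"male"`, `"female"` or `NA`.
#' @return An object of class `AudioRecording`: a list with `samples`
#'   (integer vector), `sample_rate`, `bit_depth`, `channels`,
#'   `subject_id`, `gender`, `age`.
#' @export
#' @examples
#' path <- tempfile(fileext = ".wav")
#' writeWav(rep(0L, 44100), 44100, path)   # one second of silence
#' rec <- readWav(path, subject_id = "s1", gender = "female", age = 30)
#' length(rec$samples)
readWav <- function(path, subject_id = NA_character_,
                    gender = NA_character_, age = NA_real_) {
  if (!file.exists(path)) stop("WAV file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))

  readTag <- function() rawToChar(readBin(con, "raw", 4L))
  readU32 <- function() {
    b <- readBin(con, "raw", 4L)
    if (length(b) < 4L) stop("malformed WAV: truncated file: ", path, call. = FALSE)
    sum(as.numeric(b) * c(1, 256, 65536, 16777216))
  }
  readU16 <- function() {
    b <- readBin(con, "raw", 2L)
    if (length(b) < 2L) stop("malformed WAV: truncated file: ", path, call. = FALSE)
    sum(as.numeric(b) * c(1, 256))
  }

  if (!identical(readTag(), "RIFF"))
    stop("malformed WAV: missing RIFF header: ", path, call. = FALSE)
  readU32()  # declared size, unused
  if (!identical(readTag(), "WAVE"))
    stop("malformed WAV: missing WAVE tag: ", path, call. = FALSE)

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readBin(con, "raw", 4L)
    if (length(id) < 4L) break
    id <- rawToChar(id)
    size <- readU32()
    if (identical(id, "fmt ")) {
      audio_format <- readU16()
      channels <- readU16()
      sample_rate <- readU32()
      readU32()  # byte rate
      readU16()  # block align
      bit_depth <- readU16()
      if (size > 16) readBin(con, "raw", size - 16L)
      fmt <- list(audio_format = audio_format, channels = channels,
                  sample_rate = sample_rate, bit_depth = bit_depth)
    } else if (identical(id, "data")) {
      if (is.null(fmt))
        stop("malformed WAV: data chunk before fmt chunk: ", path, call. = FALSE)
      n <- size %/% 2L
      samples <- readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                         endian = "little")
      if (length(samples) < n)
        stop("malformed WAV: truncated data chunk: ", path, call. = FALSE)
      if (size %% 2L == 1L) readBin(con, "raw", 1L)
    } else {
      skipped <- readBin(con, "raw", size + size %% 2L)
      if (length(skipped) < size)
        stop("malformed WAV: truncated chunk '", id, "': ", path, call. = FALSE)
    }
  }
  if (is.null(fmt) || is.null(samples))
    stop("malformed WAV: missing fmt or data chunk: ", path, call. = FALSE)
  if (fmt$audio_format != 1)
    stop("unsupported WAV content: not uncompressed PCM (format tag ",
         fmt$audio_format, "): ", path, call. = FALSE)
  if (fmt$channels != 1)
    stop("unsupported WAV content: ", fmt$channels,
         " channels; only mono input is accepted (no downmix): ", path,
         call. = FALSE)
  if (fmt$bit_depth != 16)
    stop("unsupported WAV content: ", fmt$bit_depth,
         "-bit samples; only 16-bit PCM is accepted: ", path, call. = FALSE)
  if (length(samples) == 0L)
    stop("malformed WAV: empty data chunk: ", path, call. = FALSE)

  audioRecording(samples, fmt$sample_rate, subject_id = subject_id,
                 gender = gender, age = age)
}

#' Construct an in-memory audio recording
#'
#' @param samples integer PCM amplitudes (16-bit range).
#' @param sample_rate sampling frequency in Hz.
#' @inheritParams readWav
#' @return An `AudioRecording` object.
#' @export
audioRecording <- function(samples, sample_rate,
                           subject_id = NA_character_,
                           gender = NA_character_, age = NA_real_) {
  if (length(samples) == 0L) stop("recording has no samples", call. = FALSE)
  if (!is.finite(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be positive", call. = FALSE)
  if (!is.na(gender) && !gender %in% c("male", "female"))
    stop("gender must be 'male', 'female' or NA", call. = FALSE)
  rec <- list(samples = as.integer(samples),
              sample_rate = as.numeric(sample_rate),
              bit_depth = 16L, channels = 1L,
              subject_id = as.character(subject_id),
              gender = as.character(gender), age = as.numeric(age))
  class(rec) <- "AudioRecording"
  rec
}

#' @export
print.AudioRecording <- function(x, ...) {
  cat(sprintf("AudioRecording: %d samples, %.3f s at %g Hz (mono, %d-bit)\n",
              length(x$samples), length(x$samples) / x$sample_rate,
              x$sample_rate, x$bit_depth))
  cat(sprintf("  subject %s, %s, age %s\n", x$subject_id, x$gender,
              format(x$age)))
  invisible(x)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples numeric or integer amplitudes; values are rounded and
#'   clamped to the signed 16-bit range.
#' @param sample_rate sampling frequency in Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeWav <- function(samples, sample_rate, path) {
  x <- as.integer(pmin(pmax(round(samples), -32768), 32767))
  n_bytes <- length(x) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeU32 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  writeU16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  writeChar("RIFF", con, eos = NULL)
  writeU32(36L + n_bytes)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeU32(16L)
  writeU16(1L)                       # PCM
  writeU16(1L)                       # mono
  writeU32(sample_rate)
  writeU32(sample_rate * 2L)         # byte rate
  writeU16(2L)                       # block align
  writeU16(16L)                      # bits per sample
  writeChar("data", con, eos = NULL)
  writeU32(n_bytes)
  writeBin(x, con, size = 2L, endian = "little")
  invisible(path)
}
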