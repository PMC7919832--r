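#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader for the recordings this package produces and
#' consumes: mono PCM 16-bit or IEEE float 32-bit. Amplitudes are returned
#' on the dimensionless [-1, 1] scale.
#'
#' @param path path to a `.wav` file.
#' @param start_time epoch of the clip start in seconds (stored on the
#'   returned clip; WAV carries no timestamp).
#' @return an [audio_clip()].
#' @export
read_wav <- function(path, start_time = 0) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        channels = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      )
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      if (fmt$channels != 1L) stop("only mono WAV is supported")
      if (fmt$format == 1L && fmt$bits == 16L) {
        n <- size %/% 2L
        raw <- readBin(con, "integer", n, 2, endian = "little", signed = TRUE)
        samples <- raw / 32768
      } else if (fmt$format == 3L && fmt$bits == 32L) {
        n <- size %/% 4L
        samples <- readBin(con, "double", n, 4, endian = "little")
      } else {
        stop("unsupported WAV encoding: format ", fmt$format, ", ", fmt$bits, " bits")
      }
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  audio_clip(samples, fmt$sample_rate, start_time = start_time)
}

#' Write a mono PCM 16-bit WAV file
#'
#' @param clip an [audio_clip()] (samples in [-1, 1]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- clip$samples
  if (any(abs(x) > 1)) stop("samples outside [-1, 1]; refusing to clip on write")
  pcm <- as.integer(round(pmax(pmin(x, 1), -1) * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(clip$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(clip$sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
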