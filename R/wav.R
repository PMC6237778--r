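# Minimal PCM WAV writer/reader for the click-pair stimuli (mono, 24-bit by
# default, matching the experiment's 24-bit / 96 kHz audio chain).

#' Write samples to a PCM WAV file
#'
#' @param x A `click_pair` or a numeric vector of amplitudes in \[-1, 1\].
#' @param path Output file.
#' @param sample_rate Samples per second; taken from a `click_pair`
#'   automatically.
#' @param bit_depth 16 or 24 (default 24).
#' @return `path`, invisibly.
#' @examples
#' \donttest{
#' f <- tempfile(fileext = ".wav")
#' write_wav(synthesize_click_pair(10), f)
#' }
#' @export
write_wav <- function(x, path, sample_rate = 96000, bit_depth = 24) {
  if (inherits(x, "click_pair")) {
    sample_rate <- x$sample_rate
    x <- x$samples
  }
  cf_assert(is.numeric(x) && length(x) >= 1, "`x` must be non-empty numeric")
  cf_assert(bit_depth %in% c(16, 24), "`bit_depth` must be 16 or 24")

  max_int <- 2^(bit_depth - 1) - 1
  v <- as.integer(round(clamp(x, -1, 1) * max_int))
  neg <- v < 0
  v[neg] <- v[neg] + 2^bit_depth # two's complement
  bytes_per <- bit_depth / 8
  data <- raw(length(v) * bytes_per)
  for (b in seq_len(bytes_per)) { # little-endian
    data[seq(b, length(data), by = bytes_per)] <-
      as.raw((v %/% 256^(b - 1)) %% 256)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(n) writeBin(as.integer(n), con, size = 4, endian = "little")
  w16 <- function(n) writeBin(as.integer(n), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL)
  w32(36 + length(data))
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w32(16); w16(1); w16(1) # PCM, mono
  w32(sample_rate)
  w32(sample_rate * bytes_per)
  w16(bytes_per); w16(bit_depth)
  writeChar("data", con, eos = NULL)
  w32(length(data))
  writeBin(data, con)
  invisible(path)
}

#' Read a PCM WAV file written by [write_wav()]
#'
#' @param path WAV file (mono PCM, 16 or 24 bit).
#' @return List with `samples` (amplitudes in \[-1, 1\]), `sample_rate`,
#'   `bit_depth`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  r32 <- function() readBin(con, "integer", size = 4, endian = "little")
  r16 <- function() readBin(con, "integer", size = 2, endian = "little")
  cf_assert(readChar(con, 4) == "RIFF", "not a RIFF file")
  r32()
  cf_assert(readChar(con, 4) == "WAVE", "not a WAVE file")
  cf_assert(readChar(con, 4) == "fmt ", "missing fmt chunk")
  r32()
  cf_assert(r16() == 1, "only PCM is supported")
  cf_assert(r16() == 1, "only mono is supported")
  sample_rate <- r32()
  r32(); r16()
  bit_depth <- r16()
  cf_assert(bit_depth %in% c(16, 24), "only 16/24-bit PCM is supported")
  cf_assert(readChar(con, 4) == "data", "missing data chunk")
  n_bytes <- r32()
  data <- readBin(con, "raw", n = n_bytes)
  bytes_per <- bit_depth / 8
  v <- numeric(n_bytes / bytes_per)
  for (b in seq_len(bytes_per)) {
    v <- v + as.numeric(data[seq(b, n_bytes, by = bytes_per)]) * 256^(b - 1)
  }
  v[v >= 2^(bit_depth - 1)] <- v[v >= 2^(bit_depth - 1)] - 2^bit_depth
  list(samples = v / (2^(bit_depth - 1) - 1), sample_rate = sample_rate,
       bit_depth = bit_depth)
}
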