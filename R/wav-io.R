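# RIFF/WAVE I/O for the two dialects the pipeline uses: 16-bit PCM and
# IEEE float32. Written with readBin/writeBin; chunk-walking tolerates
# extra chunks (LIST, fact, ...) before/after "data".

#' Read a WAV file
#'
#' Supports 16-bit PCM and 32-bit IEEE float RIFF/WAVE files. PCM samples are
#' scaled to \[-1, 1\] by 1/32768. Multi-channel data are de-interleaved into
#' a frames x channels matrix.
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_segment].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read WAV file: '%s' does not exist", path),
         call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  read_chars <- function(n) {
    raw <- readBin(con, "raw", n = n)
    if (length(raw) < n) {
      stop(sprintf("corrupt WAV file '%s': truncated header", path),
           call. = FALSE)
    }
    rawToChar(raw)
  }
  read_u32 <- function() {
    v <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (length(v) < 1L) {
      stop(sprintf("corrupt WAV file '%s': truncated header", path),
           call. = FALSE)
    }
    v
  }
  read_u16 <- function() {
    v <- readBin(con, "integer", n = 1L, size = 2L, signed = FALSE,
                 endian = "little")
    if (length(v) < 1L) {
      stop(sprintf("corrupt WAV file '%s': truncated header", path),
           call. = FALSE)
    }
    v
  }

  if (read_chars(4L) != "RIFF") {
    stop(sprintf("'%s' is not a RIFF/WAVE file", path), call. = FALSE)
  }
  read_u32() # overall size, unused
  if (read_chars(4L) != "WAVE") {
    stop(sprintf("'%s' is not a RIFF/WAVE file", path), call. = FALSE)
  }

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id_raw <- readBin(con, "raw", n = 4L)
    if (length(id_raw) < 4L) break
    chunk_id <- rawToChar(id_raw)
    chunk_size <- read_u32()
    if (chunk_id == "fmt ") {
      fmt <- list(format = read_u16(), channels = read_u16(),
                  rate = read_u32(), byte_rate = read_u32(),
                  block_align = read_u16(), bits = read_u16())
      extra <- chunk_size - 16L
      if (extra > 0L) readBin(con, "raw", n = extra)
    } else if (chunk_id == "data") {
      data_raw <- readBin(con, "raw", n = chunk_size)
      if (length(data_raw) < chunk_size) {
        stop(sprintf("corrupt WAV file '%s': data chunk truncated", path),
             call. = FALSE)
      }
    } else {
      skip <- chunk_size + (chunk_size %% 2L)
      readBin(con, "raw", n = skip)
    }
    if (chunk_size %% 2L == 1L && chunk_id %in% c("fmt ", "data")) {
      readBin(con, "raw", n = 1L)
    }
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop(sprintf("corrupt WAV file '%s': missing fmt or data chunk", path),
         call. = FALSE)
  }

  if (fmt$format == 1L && fmt$bits == 16L) {
    n <- length(data_raw) %/% 2L
    vals <- readBin(data_raw, "integer", n = n, size = 2L, signed = TRUE,
                    endian = "little") / 32768
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    n <- length(data_raw) %/% 4L
    vals <- readBin(data_raw, "double", n = n, size = 4L, endian = "little")
  } else {
    stop(sprintf("unsupported WAV encoding in '%s': format tag %d, %d bits (PCM16 or float32 required)",
                 path, fmt$format, fmt$bits), call. = FALSE)
  }

  ch <- fmt$channels
  if (ch < 1L) {
    stop(sprintf("corrupt WAV file '%s': zero channels", path), call. = FALSE)
  }
  n_fr <- length(vals) %/% ch
  vals <- vals[seq_len(n_fr * ch)]
  samples <- if (ch == 1L) vals else t(matrix(vals, nrow = ch))
  audio_segment(samples, fmt$rate)
}

#' Write a WAV file
#'
#' Writes 32-bit IEEE float WAV by default (keeping splice and envelope
#' arithmetic exact on round-trip), or 16-bit PCM on request.
#'
#' @param audio An [audio_segment].
#' @param path Output path.
#' @param format `"float32"` (default) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path, format = c("float32", "pcm16")) {
  stopifnot(inherits(audio, "audio_segment"))
  format <- match.arg(format)
  s <- audio$samples
  ch <- n_channels(audio)
  interleaved <- if (is.matrix(s)) as.numeric(t(s)) else as.numeric(s)

  bits <- if (format == "pcm16") 16L else 32L
  bytes_per_sample <- bits %/% 8L
  fmt_tag <- if (format == "pcm16") 1L else 3L
  data_bytes <- length(interleaved) * bytes_per_sample
  block_align <- ch * bytes_per_sample

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(fmt_tag, con, size = 2L, endian = "little")
  writeBin(as.integer(ch), con, size = 2L, endian = "little")
  writeBin(as.integer(audio$rate), con, size = 4L, endian = "little")
  writeBin(as.integer(audio$rate * block_align), con, size = 4L,
           endian = "little")
  writeBin(as.integer(block_align), con, size = 2L, endian = "little")
  writeBin(bits, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4L, endian = "little")
  if (format == "pcm16") {
    q <- as.integer(pmax(pmin(round(interleaved * 32768), 32767L), -32768L))
    writeBin(q, con, size = 2L, endian = "little")
  } else {
    writeBin(interleaved, con, size = 4L, endian = "little")
  }
  invisible(path)
}
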