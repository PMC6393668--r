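# Synthetic stand-ins for the two stream classes of the paradigm:
# speech-like sources with prominent quasi-rhythmic 4-8 Hz envelope
# modulation, and stationary environment-like noise textures.

# Paul Kellet's "economy" pinking filter; a standard -3 dB/octave
# approximation for white noise shaped into pink noise.
.pink_noise <- function(n) {
  w <- stats::rnorm(n)
  b <- c(0.049922035, -0.095993537, 0.050612699, -0.004408786)
  a <- c(1, -2.494956002, 2.017265875, -0.522189400)
  as.numeric(signal::filter(b, a, w))
}

# Modulator ground truth: a raised (DC-offset) sum of random-phase
# sinusoids with frequencies drawn inside mod_rate_range, normalised to
# peak 1 with a positive floor. Its spectral lines sit exactly at the
# drawn frequencies, so envelope-recovery tests have an analytic target.
.speech_modulator <- function(n, rate, mod_rate_range, n_components = 3L,
                              floor_level = 0.1) {
  freqs <- stats::runif(n_components, mod_rate_range[1], mod_rate_range[2])
  phases <- stats::runif(n_components, 0, 2 * pi)
  amps <- stats::runif(n_components, 0.5, 1)
  t <- (seq_len(n) - 1) / rate
  m <- rep(0, n)
  for (k in seq_len(n_components)) {
    m <- m + amps[k] * (1 + cos(2 * pi * freqs[k] * t + phases[k])) / 2
  }
  m <- m / max(m)
  m <- floor_level + (1 - floor_level) * m
  list(values = m, freqs = freqs, phases = phases, amps = amps)
}

# Full deterministic realisation (waveform + modulator truth); the RNG
# sequence is fixed: modulator parameters first, then the carrier.
.synth_speechlike_full <- function(duration, rate, mod_rate_range, seed) {
  n <- round(duration * rate)
  withr::with_seed(seed, {
    mod <- .speech_modulator(n, rate, mod_rate_range)
    carrier <- .pink_noise(n)
  })
  x <- carrier * mod$values
  x <- 0.9 * x / max(abs(x))
  list(audio = audio_segment(x, rate), modulator = mod$values,
       freqs = mod$freqs)
}

#' Synthesise a speech-like source
#'
#' Broadband (pink) noise carrier, amplitude-modulated by a positive
#' quasi-rhythmic modulator whose spectral energy is concentrated in
#' `mod_rate_range` (default 4-8 Hz, the range of prominent envelope
#' modulation in running speech). Deterministic given `seed`; output peak
#' is guarded to 0.9.
#'
#' @param duration Duration in seconds (> 0).
#' @param rate Sampling rate in Hz.
#' @param mod_rate_range Length-2 numeric, modulation band in Hz (low < high).
#' @param seed Integer RNG seed.
#' @return A mono [audio_segment].
#' @examples
#' s <- synth_speechlike(2, seed = 1)
#' @export
synth_speechlike <- function(duration, rate = 44100, mod_rate_range = c(4, 8),
                             seed = 1L) {
  if (!is.numeric(duration) || duration <= 0) {
    stop("`duration` must be positive", call. = FALSE)
  }
  if (mod_rate_range[1] >= mod_rate_range[2]) {
    stop("`mod_rate_range` must satisfy low < high", call. = FALSE)
  }
  .synth_speechlike_full(duration, rate, mod_rate_range, seed)$audio
}

#' Synthesise an environment-like source
#'
#' A stationary pink-noise texture: its windowed-RMS profile is flat
#' compared with the strongly modulated speech-like sources. Deterministic
#' given `seed`; output peak is guarded to 0.9.
#'
#' @inheritParams synth_speechlike
#' @return A mono [audio_segment].
#' @export
synth_envlike <- function(duration, rate = 44100, seed = 1L) {
  if (!is.numeric(duration) || duration <= 0) {
    stop("`duration` must be positive", call. = FALSE)
  }
  n <- round(duration * rate)
  x <- withr::with_seed(seed, .pink_noise(n))
  x <- 0.9 * x / max(abs(x))
  audio_segment(x, rate)
}

#' Windowed RMS profile
#'
#' RMS computed in consecutive non-overlapping windows; used to inspect the
#' coarse temporal dynamics (stationarity) of a signal.
#'
#' @param x An [audio_segment] or numeric vector.
#' @param window_s Window length in seconds (requires an `audio_segment`
#'   unless `rate` is given).
#' @param rate Sampling rate, taken from `x` when it is an `audio_segment`.
#' @return Numeric vector of per-window RMS values.
#' @export
windowed_rms <- function(x, window_s = 1, rate = NULL) {
  if (inherits(x, "audio_segment")) {
    rate <- x$rate
    x <- x$samples
  }
  if (is.null(rate)) stop("`rate` required for plain vectors", call. = FALSE)
  w <- round(window_s * rate)
  n_win <- floor(length(x) / w)
  if (n_win < 1L) stop("signal shorter than one window", call. = FALSE)
  vapply(seq_len(n_win), function(i) {
    sqrt(mean(x[((i - 1) * w + 1):(i * w)]^2))
  }, numeric(1))
}
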