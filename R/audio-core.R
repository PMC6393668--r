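#' Audio segment container
#'
#' A sampled waveform with a sampling rate. Mono audio is stored as a numeric
#' vector; multi-channel audio as a numeric matrix with one column per channel
#' (frames in rows). Amplitudes are dimensionless, nominal full scale
#' \[-1, 1\].
#'
#' @param samples Numeric vector (mono) or matrix (frames x channels).
#' @param rate Sampling rate in Hz (positive scalar).
#'
#' @return An object of class `audio_segment` with elements `samples` and
#'   `rate`.
#' @examples
#' x <- audio_segment(sin(2 * pi * 440 * seq(0, 1, length.out = 44100)), 44100)
#' duration(x)
#' @export
audio_segment <- function(samples, rate) {
  if (!is.numeric(samples)) {
    stop("`samples` must be numeric", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("`rate` must be a single positive number", call. = FALSE)
  }
  if (length(samples) == 0L) {
    stop("`samples` must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("all samples must be finite", call. = FALSE)
  }
  structure(list(samples = samples, rate = as.numeric(rate)),
            class = "audio_segment")
}

#' @export
print.audio_segment <- function(x, ...) {
  cat(sprintf("<audio_segment> %d channel(s), %d samples @ %g Hz (%.4f s)\n",
              n_channels(x), n_frames(x), x$rate, duration(x)))
  invisible(x)
}

#' Number of audio channels
#' @param x An `audio_segment`.
#' @return Integer channel count.
#' @export
n_channels <- function(x) {
  stopifnot(inherits(x, "audio_segment"))
  if (is.matrix(x$samples)) ncol(x$samples) else 1L
}

#' Number of frames (samples per channel)
#' @param x An `audio_segment`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "audio_segment"))
  if (is.matrix(x$samples)) nrow(x$samples) else length(x$samples)
}

#' Duration in seconds
#' @param x An `audio_segment`.
#' @return Duration, `n_frames(x) / x$rate`, in seconds.
#' @export
duration <- function(x) {
  n_frames(x) / x$rate
}

#' Stimulus construction constants
#'
#' Bundles the fixed parameters of the stimulus pipeline: sampling rate,
#' prepared segment length, one-back repetition length, cross-fade ramp
#' length, minimum envelope-peak separation, and the RMS normalisation
#' target. Defaults reproduce the reference construction: 44.1 kHz audio,
#' 5-s scenes, 750-ms repetitions, 220-sample (5 ms) linear ramps,
#' 4410-sample (0.1 s) peak separation, and -23 dB RMS re full scale.
#'
#' @param sample_rate Sampling rate in Hz.
#' @param segment_duration Final stimulus duration in seconds.
#' @param repetition_duration Repetition-target duration in seconds; must be
#'   an integer number of samples at `sample_rate`.
#' @param ramp_samples Linear cross-fade ramp length in samples (>= 1).
#' @param envelope_min_separation Minimum distance between envelope peaks in
#'   samples (>= 1).
#' @param target_level_db RMS normalisation target in dB relative to
#'   full-scale RMS (RMS of 1.0 = 0 dB).
#' @param edge_margin Minimum distance, in seconds, between the repetition
#'   pair and the stimulus onset/offset.
#'
#' @return A `stimulus_config` list.
#' @export
stimulus_config <- function(sample_rate = 44100,
                            segment_duration = 5.0,
                            repetition_duration = 0.750,
                            ramp_samples = 220,
                            envelope_min_separation = 4410,
                            target_level_db = -23,
                            edge_margin = 0.250) {
  rep_samples <- repetition_duration * sample_rate
  if (abs(rep_samples - round(rep_samples)) > 1e-9) {
    stop("repetition_duration must be an integer number of samples",
         call. = FALSE)
  }
  if (ramp_samples < 1 || envelope_min_separation < 1) {
    stop("ramp_samples and envelope_min_separation must be >= 1",
         call. = FALSE)
  }
  if (2 * ramp_samples >= rep_samples) {
    stop("2 * ramp_samples must be smaller than the repetition in samples",
         call. = FALSE)
  }
  structure(list(sample_rate = sample_rate,
                 segment_duration = segment_duration,
                 repetition_duration = repetition_duration,
                 ramp_samples = as.integer(ramp_samples),
                 envelope_min_separation = as.integer(envelope_min_separation),
                 target_level_db = target_level_db,
                 edge_margin = edge_margin),
            class = "stimulus_config")
}

#' Average channels down to mono
#'
#' Per-frame arithmetic mean across channels; length and rate are unchanged.
#' Mono input is returned as-is (the operation is idempotent).
#'
#' @param audio An `audio_segment`.
#' @return A mono `audio_segment`.
#' @export
to_mono <- function(audio) {
  stopifnot(inherits(audio, "audio_segment"))
  if (!is.matrix(audio$samples)) {
    return(audio)
  }
  if (ncol(audio$samples) == 0L) {
    stop("audio has zero channels", call. = FALSE)
  }
  audio_segment(rowMeans(audio$samples), audio$rate)
}

#' Cut a fixed-duration window out of a segment
#'
#' Extracts `duration` seconds as a verbatim slice of the input (no
#' resampling or filtering). `anchor = "center"` takes the central window,
#' with ties broken toward the earlier start.
#'
#' @param audio An `audio_segment` (any channel count).
#' @param duration Requested duration in seconds.
#' @param anchor One of `"center"`, `"start"`, `"offset"`.
#' @param offset Start frame (1-based) when `anchor = "offset"`.
#' @return An `audio_segment` of exactly the requested duration.
#' @export
cut_segment <- function(audio, duration, anchor = c("center", "start", "offset"),
                        offset = 1L) {
  stopifnot(inherits(audio, "audio_segment"))
  anchor <- match.arg(anchor)
  n <- n_frames(audio)
  n_req <- round(duration * audio$rate)
  if (n_req > n) {
    stop(sprintf("source is shorter than requested cut: %.6f s available, %.6f s requested",
                 n / audio$rate, duration), call. = FALSE)
  }
  start <- switch(anchor,
                  center = floor((n - n_req) / 2) + 1L,
                  start = 1L,
                  offset = as.integer(offset))
  if (start < 1L || start + n_req - 1L > n) {
    stop("requested window falls outside the source", call. = FALSE)
  }
  idx <- start:(start + n_req - 1L)
  out <- if (is.matrix(audio$samples)) audio$samples[idx, , drop = FALSE] else audio$samples[idx]
  audio_segment(out, audio$rate)
}

#' Root-mean-square amplitude
#' @param x An `audio_segment` or numeric vector.
#' @return RMS of all samples.
#' @export
rms <- function(x) {
  s <- if (inherits(x, "audio_segment")) x$samples else x
  sqrt(mean(s^2))
}

#' RMS level in dB re full scale
#' @param x An `audio_segment` or numeric vector.
#' @return `20 * log10(rms(x))`.
#' @export
rms_db <- function(x) {
  20 * log10(rms(x))
}

#' Normalise to a target RMS level
#'
#' Rescales the waveform by a single scalar so its RMS equals
#' `10^(target_db / 20)` (dB relative to full-scale RMS). Shape-preserving.
#'
#' @param audio An `audio_segment`.
#' @param target_db Target level in dB re full-scale RMS.
#' @return The rescaled `audio_segment`.
#' @export
normalize_rms <- function(audio, target_db = -23) {
  stopifnot(inherits(audio, "audio_segment"))
  r <- rms(audio)
  if (r < 1e-12) {
    stop("degenerate signal: RMS below 1e-12, cannot normalize", call. = FALSE)
  }
  gain <- 10^(target_db / 20) / r
  audio_segment(audio$samples * gain, audio$rate)
}
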