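# Per-trial diotic scene assembly: prepare two streams (mono, cut,
# normalise), equalise envelopes where configured, embed the one-back
# target in the designated stream, and superimpose linearly.

#' Linear superposition of two streams
#'
#' Sample-wise sum of two equal-length streams (the linear mixing model of a
#' natural auditory scene). If the sum clips (any `|sample| > 1`) the whole
#' mix is rescaled by one scalar to peak 0.99, preserving its shape.
#'
#' @param a,b Mono [audio_segment]s of equal length and rate.
#' @return The mixed [audio_segment].
#' @export
mix_scene <- function(a, b) {
  stopifnot(inherits(a, "audio_segment"), inherits(b, "audio_segment"))
  if (n_frames(a) != n_frames(b)) {
    stop(sprintf("length mismatch: %d vs %d samples", n_frames(a), n_frames(b)),
         call. = FALSE)
  }
  if (a$rate != b$rate) stop("sampling rates differ", call. = FALSE)
  s <- a$samples + b$samples
  peak <- max(abs(s))
  if (peak > 1) s <- s * (0.99 / peak)
  audio_segment(s, a$rate)
}

#' Build a complete trial stimulus
#'
#' Runs the full per-trial pipeline: each source is converted to mono, cut
#' (centre anchor) to `segment + repetition` duration, and RMS-normalised.
#' In `speech_env` mode the environment source (`source_b`) additionally
#' receives the speech stream's peak-spline envelope via
#' [transfer_envelope()], equalising the coarse temporal dynamics of the two
#' streams. The one-back repetition is embedded in exactly the target
#' stream; the other stream is centre-cut to the final duration. Both
#' streams are re-normalised to the configured level (equal RMS, 0 dB
#' target-to-masker ratio) and summed.
#'
#' @param source_a,source_b [audio_segment]s of duration at least
#'   `segment_duration + repetition_duration`. In `speech_env` mode `source_a`
#'   is the speech-like stream and `source_b` the environment-like stream.
#' @param target_stream `"A"` or `"B"`: which stream carries the repetition.
#' @param mode `"speech_env"` (envelope transfer onto B) or `"speech_speech"`.
#' @param cfg A [stimulus_config].
#' @param seed Seed for the repetition cut draw.
#' @param cut_sample Optional explicit cut sample (overrides the draw).
#' @return A `trial_stimulus`: list with `mix`, isolated `stream_a` and
#'   `stream_b` (post-embedding), `target_stream`, `annotation`, `mode`, and
#'   `config`.
#' @export
build_trial_stimulus <- function(source_a, source_b, target_stream = c("A", "B"),
                                 mode = c("speech_env", "speech_speech"),
                                 cfg = stimulus_config(), seed = 1L,
                                 cut_sample = NULL) {
  target_stream <- match.arg(target_stream)
  mode <- match.arg(mode)
  stopifnot(inherits(cfg, "stimulus_config"))
  prep_dur <- cfg$segment_duration + cfg$repetition_duration
  prep <- function(src) {
    normalize_rms(cut_segment(to_mono(src), prep_dur, anchor = "center"),
                  cfg$target_level_db)
  }
  a <- prep(source_a)
  b <- prep(source_b)
  if (mode == "speech_env") {
    donor <- extract_envelope(a, cfg$envelope_min_separation)
    b <- transfer_envelope(b, donor, cfg$envelope_min_separation,
                           cfg$target_level_db)
  }
  if (target_stream == "A") {
    emb <- embed_repetition(a, cfg, cut_sample = cut_sample, seed = seed)
    a <- emb$audio
    b <- cut_segment(b, cfg$segment_duration, anchor = "center")
  } else {
    emb <- embed_repetition(b, cfg, cut_sample = cut_sample, seed = seed)
    b <- emb$audio
    a <- cut_segment(a, cfg$segment_duration, anchor = "center")
  }
  a <- normalize_rms(a, cfg$target_level_db)
  b <- normalize_rms(b, cfg$target_level_db)
  structure(list(mix = mix_scene(a, b), stream_a = a, stream_b = b,
                 target_stream = target_stream, annotation = emb$annotation,
                 mode = mode, config = cfg),
            class = "trial_stimulus")
}

#' @export
print.trial_stimulus <- function(x, ...) {
  cat(sprintf("<trial_stimulus> mode %s, target stream %s, %.3f s @ %g Hz, repetition at %.3f s\n",
              x$mode, x$target_stream, duration(x$mix), x$mix$rate,
              x$annotation$onset_s))
  invisible(x)
}

#' Write a trial stimulus as a diotic WAV
#'
#' The scene is diotic (identical signal at both ears); for player
#' compatibility the mono mix can be duplicated into two channels.
#'
#' @param trial A `trial_stimulus`.
#' @param path Output path.
#' @param channels 1 (mono) or 2 (duplicated diotic pair).
#' @param format Passed to [write_wav()].
#' @return `path`, invisibly.
#' @export
write_trial_wav <- function(trial, path, channels = 1L,
                            format = c("float32", "pcm16")) {
  stopifnot(inherits(trial, "trial_stimulus"))
  s <- trial$mix$samples
  if (channels == 2L) s <- cbind(s, s)
  write_wav(audio_segment(s, trial$mix$rate), path, match.arg(format))
}

#' Write repetition annotations to CSV
#'
#' @param annotations A list of `repetition_annotation` objects (possibly
#'   named by stimulus id).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_csv <- function(annotations, path) {
  if (inherits(annotations, "repetition_annotation")) {
    annotations <- list(annotations)
  }
  ids <- names(annotations)
  if (is.null(ids)) ids <- sprintf("stim_%04d", seq_along(annotations))
  df <- do.call(rbind, lapply(seq_along(annotations), function(i) {
    an <- annotations[[i]]
    data.frame(stimulus_id = ids[i], cut_sample = an$cut_sample,
               first_onset = an$first_onset, second_onset = an$second_onset,
               rep_length = an$rep_length, ramp_samples = an$ramp_samples)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
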