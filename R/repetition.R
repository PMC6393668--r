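# One-back repetition embedding. A source is cut at a (random) sample, the
# 750 ms immediately preceding the cut is repeated, and beginning,
# repetition and end are concatenated with 220-sample linear-ramp
# cross-fades, giving a click-free seamless replay of the just-heard epoch.

#' Cross-fade two segments together
#'
#' Concatenates `a` and `b` with a linear-ramp cross-fade of `ramp` samples:
#' in the overlap, the ramped-down tail of `a` is added to the ramped-up head
#' of `b` with weights summing to one at every sample (weights run 1 -> 0 and
#' 0 -> 1 inclusive of both endpoints). Outside the overlap samples are
#' verbatim copies.
#'
#' @param a,b Mono [audio_segment]s at the same rate.
#' @param ramp Ramp length in samples (>= 1, no longer than either input).
#' @return An [audio_segment] of length `n_frames(a) + n_frames(b) - ramp`.
#' @export
crossfade_concat <- function(a, b, ramp) {
  stopifnot(inherits(a, "audio_segment"), inherits(b, "audio_segment"))
  if (a$rate != b$rate) stop("sampling rates differ", call. = FALSE)
  ramp <- as.integer(ramp)
  if (ramp < 1L) stop("`ramp` must be >= 1 sample", call. = FALSE)
  na <- n_frames(a); nb <- n_frames(b)
  if (ramp > na || ramp > nb) {
    stop(sprintf("ramp (%d) longer than an input (%d, %d samples)",
                 ramp, na, nb), call. = FALSE)
  }
  w_up <- if (ramp == 1L) 0.5 else seq(0, 1, length.out = ramp)
  w_down <- 1 - w_up
  out <- numeric(na + nb - ramp)
  out[seq_len(na - ramp)] <- a$samples[seq_len(na - ramp)]
  ov <- (na - ramp + 1L):na
  out[ov] <- a$samples[ov] * w_down + b$samples[seq_len(ramp)] * w_up
  out[(na + 1L):(na + nb - ramp)] <- b$samples[(ramp + 1L):nb]
  audio_segment(out, a$rate)
}

# Splice geometry shared by embed_repetition() and the trial-design
# generator (which records target onsets without rendering audio).
# All indices 1-based. cut = length of the original beginning A;
# B = x[(cut - R + 1):cut] is repeated. Before trimming,
# first_onset = cut - R + 1, second_onset = cut - ramp + 1.
.repetition_geometry <- function(cut, n_src, cfg) {
  r <- as.integer(round(cfg$repetition_duration * cfg$sample_rate))
  ramp <- cfg$ramp_samples
  n_seg <- as.integer(round(cfg$segment_duration * cfg$sample_rate))
  m <- as.integer(round(cfg$edge_margin * cfg$sample_rate))
  pre_trim_len <- n_src + r - 2L * ramp
  first_raw <- cut - r + 1L
  second_raw <- cut - ramp + 1L
  lo_t <- max(0L, cut + r - ramp - n_seg + m)
  hi_t <- min(pre_trim_len - n_seg, cut - r - m)
  if (lo_t > hi_t) {
    stop(sprintf("cut_sample %d outside admissible range [%d, %d]",
                 cut, .admissible_cut_range(n_src, cfg)[1],
                 .admissible_cut_range(n_src, cfg)[2]), call. = FALSE)
  }
  t <- min(max(as.integer(round((pre_trim_len - n_seg) / 2)), lo_t), hi_t)
  list(rep_samples = r, ramp = ramp, n_seg = n_seg,
       pre_trim_len = pre_trim_len, trim_start = t,
       first_onset = first_raw - t, second_onset = second_raw - t)
}

.admissible_cut_range <- function(n_src, cfg) {
  r <- as.integer(round(cfg$repetition_duration * cfg$sample_rate))
  m <- as.integer(round(cfg$edge_margin * cfg$sample_rate))
  c(r + m, n_src - cfg$ramp_samples - m)
}

#' Embed a one-back repetition target
#'
#' Cuts `x` at `cut_sample`, takes the `repetition_duration` epoch
#' immediately preceding the cut, and concatenates beginning, repetition and
#' end with linear-ramp cross-fades. The spliced stream is then trimmed to
#' exactly `cfg$segment_duration`, keeping the full repetition pair at least
#' `cfg$edge_margin` seconds away from stream onset and offset.
#'
#' @param x A mono [audio_segment] of duration at least
#'   `cfg$segment_duration + cfg$repetition_duration`.
#' @param cfg A [stimulus_config].
#' @param cut_sample 1-based cut index (length of the original beginning), or
#'   `NULL` to draw uniformly from the admissible range.
#' @param seed RNG seed for the cut draw (used when `cut_sample` is `NULL`).
#' @return A list with `audio` (the trimmed stimulus) and `annotation`, a
#'   `repetition_annotation` with fields `cut_sample`, `rep_length`,
#'   `first_onset`, `second_onset` (1-based, post-trim), `ramp_samples`,
#'   `onset_s` (seconds to the start of the repeated epoch) and `rate`.
#' @export
embed_repetition <- function(x, cfg = stimulus_config(), cut_sample = NULL,
                             seed = 1L) {
  stopifnot(inherits(x, "audio_segment"), inherits(cfg, "stimulus_config"))
  if (is.matrix(x$samples)) stop("mono input required", call. = FALSE)
  n_src <- n_frames(x)
  need <- cfg$segment_duration + cfg$repetition_duration
  if (duration(x) < need - 1e-9) {
    stop(sprintf("source too short: %.3f s given, %.3f s (segment + repetition) required",
                 duration(x), need), call. = FALSE)
  }
  rng <- .admissible_cut_range(n_src, cfg)
  if (is.null(cut_sample)) {
    cut_sample <- withr::with_seed(seed,
      sample.int(rng[2] - rng[1] + 1L, 1L) + rng[1] - 1L)
  }
  cut_sample <- as.integer(cut_sample)
  if (cut_sample < rng[1] || cut_sample > rng[2]) {
    stop(sprintf("cut_sample %d outside admissible range [%d, %d]",
                 cut_sample, rng[1], rng[2]), call. = FALSE)
  }
  geo <- .repetition_geometry(cut_sample, n_src, cfg)
  r <- geo$rep_samples

  a <- audio_segment(x$samples[1:cut_sample], x$rate)
  b <- audio_segment(x$samples[(cut_sample - r + 1L):cut_sample], x$rate)
  cc <- audio_segment(x$samples[(cut_sample + 1L):n_src], x$rate)
  spliced <- crossfade_concat(crossfade_concat(a, b, geo$ramp), cc, geo$ramp)
  stopifnot(n_frames(spliced) == geo$pre_trim_len)
  out <- cut_segment(spliced, cfg$segment_duration, anchor = "offset",
                     offset = geo$trim_start + 1L)

  ann <- structure(list(cut_sample = cut_sample,
                        rep_length = r,
                        first_onset = geo$first_onset,
                        second_onset = geo$second_onset,
                        ramp_samples = geo$ramp,
                        onset_s = (geo$second_onset - 1L) / x$rate,
                        rate = x$rate),
                   class = "repetition_annotation")
  list(audio = out, annotation = ann)
}

#' @export
print.repetition_annotation <- function(x, ...) {
  cat(sprintf("<repetition_annotation> %d-sample epoch, onsets %d / %d (lag %d), ramp %d, target at %.3f s\n",
              x$rep_length, x$first_onset, x$second_onset,
              x$second_onset - x$first_onset, x$ramp_samples, x$onset_s))
  invisible(x)
}

# Brute-force self-similarity scan: sliding normalized cross-correlation
# between x[i..i+w-1] and x[i+lag..], O(n) via running sums. Validation
# utility for the splice construction (not a detection feature).
.lag_scan <- function(x, lag, window) {
  s <- if (inherits(x, "audio_segment")) x$samples else x
  n <- length(s)
  if (n < lag + window) stop("signal too short for lag scan", call. = FALSE)
  u <- s[1:(n - lag)]
  v <- s[(lag + 1L):n]
  # windowed sums of u, v, u^2, v^2, uv
  wsum <- function(z) {
    cz <- c(0, cumsum(z))
    cz[(window + 1L):(length(z) + 1L)] - cz[1:(length(z) - window + 1L)]
  }
  su <- wsum(u); sv <- wsum(v)
  suu <- wsum(u^2); svv <- wsum(v^2); suv <- wsum(u * v)
  num <- suv - su * sv / window
  den <- sqrt(pmax(suu - su^2 / window, 0) * pmax(svv - sv^2 / window, 0))
  corr <- ifelse(den > 0, num / den, 0)
  # ties plateau across the whole matched region; report its first sample
  best <- which(corr >= max(corr) - 1e-9)[1]
  list(best_start = best, best_corr = corr[best], corr = corr)
}
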