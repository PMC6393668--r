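# Peak-spline envelope extraction and envelope transfer. The envelope is a
# cubic spline through local maxima of |x| separated by at least
# `min_sep` samples (4410 samples = 0.1 s at 44.1 kHz by default); transfer
# divides a signal by its own envelope and multiplies by a donor envelope,
# imposing the donor's coarse temporal dynamics.

#' Local maxima with a minimum separation
#'
#' Finds local maxima of `|x|` such that any two returned indices differ by
#' at least `min_sep` samples. Conflicts between nearby maxima are resolved
#' greedily by descending magnitude (ties -> earlier index). The global
#' maximum of `|x|` is always included for non-constant input.
#'
#' @param x Numeric amplitude sequence.
#' @param min_sep Minimum index separation in samples (>= 1).
#' @return Sorted integer vector of 1-based peak indices.
#' @export
find_peaks_minsep <- function(x, min_sep) {
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  if (min_sep < 1) stop("`min_sep` must be >= 1", call. = FALSE)
  a <- abs(x)
  n <- length(a)
  cand <- integer(0)
  if (n >= 3L) {
    interior <- 2:(n - 1L)
    is_peak <- a[interior] > a[interior - 1L] & a[interior] >= a[interior + 1L]
    cand <- interior[is_peak]
  }
  gmax <- which.max(a)
  if (!(gmax %in% cand)) cand <- c(cand, gmax)
  ord <- order(-a[cand], cand)
  cand <- cand[ord]
  kept <- integer(0)
  for (i in cand) {
    if (length(kept) == 0L || min(abs(kept - i)) >= min_sep) {
      kept <- c(kept, i)
    }
  }
  sort(kept)
}

#' Peak-spline amplitude envelope
#'
#' Cubic-spline interpolation through `(peak index, |x| at peak)` pairs,
#' where peaks are local maxima of `|x|` separated by at least `min_sep`
#' samples, evaluated at every sample. Virtual anchor points at the first
#' and last sample (with value `|x|` there) keep the spline on-support;
#' the result is clamped below at a positivity floor
#' `eps = 1e-4 * max(|x|)` so downstream envelope division is safe.
#'
#' @param x A mono [audio_segment].
#' @param min_sep Minimum peak separation in samples.
#' @return An `envelope_track`: list with `values` (>= eps everywhere),
#'   `rate`, `floor` (the eps used) and `peaks` (the peak indices).
#' @export
extract_envelope <- function(x, min_sep = 4410) {
  stopifnot(inherits(x, "audio_segment"))
  if (is.matrix(x$samples)) stop("mono input required", call. = FALSE)
  s <- x$samples
  if (max(s) - min(s) < 1e-12) {
    stop("degenerate signal: constant input has no envelope", call. = FALSE)
  }
  a <- abs(s)
  eps <- 1e-4 * max(a)
  pk <- find_peaks_minsep(s, min_sep)
  idx <- pk
  vals <- a[idx]
  n <- length(s)
  half <- max(1L, as.integer(min_sep / 2))
  # virtual endpoint anchors keep the spline on-support. They carry the
  # local |x| maximum of the edge half-window (a single edge sample is
  # usually near a zero-crossing and would drag the spline to zero), and
  # are only added when the nearest real peak is at least half a min_sep
  # away - a low knot right next to a tall peak makes the cubic oscillate.
  if (idx[1] - 1L >= half) {
    idx <- c(1L, idx)
    vals <- c(max(a[seq_len(half)]), vals)
  }
  if (n - idx[length(idx)] >= half) {
    idx <- c(idx, n)
    vals <- c(vals, max(a[(n - half + 1L):n]))
  }
  env <- stats::spline(idx, vals, xout = seq_along(s), method = "natural")$y
  # constant extension outside the outermost knots: extrapolating the cubic
  # toward the signal edge can dive to zero and break envelope division
  if (idx[1] > 1L) env[seq_len(idx[1] - 1L)] <- vals[1]
  if (idx[length(idx)] < n) env[(idx[length(idx)] + 1L):n] <- vals[length(vals)]
  env <- pmax(env, eps)
  structure(list(values = env, rate = x$rate, floor = eps, peaks = pk),
            class = "envelope_track")
}

#' @export
print.envelope_track <- function(x, ...) {
  cat(sprintf("<envelope_track> %d samples @ %g Hz, %d peaks, floor %.3g\n",
              length(x$values), x$rate, length(x$peaks), x$floor))
  invisible(x)
}

#' Transfer a donor envelope onto a signal
#'
#' Divides `target` by its own peak-spline envelope (floored at eps) and
#' multiplies by `donor_env`, then re-normalises to `target_level_db` so
#' enveloping never changes overall level. The target's fine structure is
#' preserved: the envelope-divided output equals the envelope-divided input
#' up to a positive scalar.
#'
#' @param target A mono [audio_segment].
#' @param donor_env An `envelope_track` of the same length and rate.
#' @param min_sep Peak separation used for the target's own envelope.
#' @param target_level_db RMS level the output is normalised back to.
#' @return An [audio_segment] carrying the donor's coarse dynamics.
#' @export
transfer_envelope <- function(target, donor_env, min_sep = 4410,
                              target_level_db = -23) {
  stopifnot(inherits(target, "audio_segment"),
            inherits(donor_env, "envelope_track"))
  if (n_frames(target) != length(donor_env$values)) {
    stop(sprintf("length mismatch: target has %d samples, donor envelope %d",
                 n_frames(target), length(donor_env$values)), call. = FALSE)
  }
  if (target$rate != donor_env$rate) {
    stop("sampling rates of target and donor envelope differ", call. = FALSE)
  }
  own <- extract_envelope(target, min_sep)
  flat <- target$samples / pmax(own$values, own$floor)
  out <- audio_segment(flat * donor_env$values, target$rate)
  normalize_rms(out, target_level_db)
}

#' Export an envelope as single-column CSV
#' @param env An `envelope_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_envelope_csv <- function(env, path) {
  stopifnot(inherits(env, "envelope_track"))
  utils::write.csv(data.frame(envelope = env$values), path, row.names = FALSE)
  invisible(path)
}
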