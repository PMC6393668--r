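# Simulated yes/no SDT participant. Evidence on each trial is Gaussian with
# unit variance and mean d'_eff (attended / unattended / neutral, set by the
# cue-target relation); a response is emitted when evidence exceeds the
# absolute cutoff k = d'_eff/2 + c_eff, so the generative d' and bias c are
# exactly what the downstream SDT analysis estimates. Premature (pre-target)
# responses occur with a probability that scales with Phi(-k): liberal
# conditions produce more false alarms.

#' Observer parameters
#'
#' Generative parameters for the simulated SDT participant. Sensitivities
#' `dprime_*` and biases `criterion_*` are per attention state: `attended`
#' (cued stream contains the target, i.e. a valid cue), `unattended`
#' (invalid cue), `neutral` (no cue). Criteria are SDT bias `c` (distance
#' from the d'/2 midpoint); the evidence cutoff used internally is
#' `k = d'/2 + c`. Response latency for hits is
#' `lognormal(rt_mu, rt_sigma)` seconds after target onset, shifted earlier
#' by `rt_attention_shift` when attended and later by the same amount when
#' invalidly cued.
#'
#' Premature responses (the task's false alarms) occur with probability
#' `premature_rate * g(condition)` where `g = pnorm(-k_cond) /
#' pnorm(-k_attended)` scales with how liberal the condition's criterion is.
#' The default `premature_rate = pnorm(-k_attended)` makes the per-condition
#' false-alarm probability exactly `pnorm(-k)`, the SDT-consistent value, so
#' the analysis pipeline recovers both d' and c.
#'
#' @param dprime_attended,dprime_neutral,dprime_unattended Sensitivities
#'   (>= 0); intended ordering attended > neutral > unattended.
#' @param criterion_attended,criterion_neutral,criterion_unattended SDT bias
#'   c per attention state.
#' @param rt_mu,rt_sigma Log-scale location and spread of the hit latency
#'   (seconds); `exp(rt_mu)` is the median neutral latency.
#' @param rt_attention_shift Latency shift in seconds (subtracted when
#'   attended, added when invalidly cued).
#' @param premature_rate Base probability of a pre-target response, or
#'   `NULL` for the SDT-consistent default.
#' @param seed RNG seed for [simulate_observer()].
#' @return An `observer_params` list (with the derived cutoffs `k_*`).
#' @export
observer_params <- function(dprime_attended = 3.3, dprime_neutral = 2.4,
                            dprime_unattended = 1.9,
                            criterion_attended = 0.55,
                            criterion_neutral = 0.50,
                            criterion_unattended = 0.74,
                            rt_mu = log(0.85), rt_sigma = 0.30,
                            rt_attention_shift = 0.10,
                            premature_rate = NULL, seed = 1L) {
  d <- c(attended = dprime_attended, neutral = dprime_neutral,
         unattended = dprime_unattended)
  cc <- c(attended = criterion_attended, neutral = criterion_neutral,
          unattended = criterion_unattended)
  if (any(d < 0)) stop("d' values must be >= 0", call. = FALSE)
  if (rt_sigma <= 0) stop("rt_sigma must be > 0", call. = FALSE)
  k <- d / 2 + cc
  if (is.null(premature_rate)) premature_rate <- stats::pnorm(-k[["attended"]])
  if (premature_rate < 0 || premature_rate >= 1) {
    stop("premature_rate must be in [0, 1)", call. = FALSE)
  }
  structure(list(dprime = d, criterion = cc, k = k,
                 rt_mu = rt_mu, rt_sigma = rt_sigma,
                 rt_attention_shift = rt_attention_shift,
                 premature_rate = premature_rate, seed = as.integer(seed)),
            class = "observer_params")
}

#' Observer presets
#'
#' Ready-made parameter sets whose generative d' and c sit near the
#' published group means of the two-stream (speech/environment) and
#' two-speech-stream versions of the paradigm. These are presets for
#' simulation, not ground-truth participant values.
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param seed RNG seed.
#' @return An [observer_params()] object.
#' @export
observer_preset <- function(experiment = c("exp1", "exp2"), seed = 1L) {
  experiment <- match.arg(experiment)
  if (experiment == "exp1") {
    observer_params(dprime_attended = 3.3, dprime_neutral = 2.4,
                    dprime_unattended = 1.9,
                    criterion_attended = 0.55, criterion_neutral = 0.50,
                    criterion_unattended = 0.74, seed = seed)
  } else {
    observer_params(dprime_attended = 3.05, dprime_neutral = 1.98,
                    dprime_unattended = 1.57,
                    criterion_attended = 0.50, criterion_neutral = 0.77,
                    criterion_unattended = 1.15, seed = seed)
  }
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf("<observer_params> d' att/neu/unatt = %.2f/%.2f/%.2f, c = %.2f/%.2f/%.2f, premature %.3f\n",
              x$dprime[1], x$dprime[2], x$dprime[3],
              x$criterion[1], x$criterion[2], x$criterion[3],
              x$premature_rate))
  invisible(x)
}

#' Simulate an observer on a trial design
#'
#' One decision per trial: with probability `premature_rate * g(condition)`
#' a premature response is emitted uniformly before target onset (false
#' alarm); otherwise Gaussian evidence `e ~ N(d'_eff, 1)` is compared with
#' the cutoff `k_eff = d'_eff/2 + c_eff` and, on `e > k_eff`, a response
#' follows the target at a lognormal latency (shifted by attention),
#' truncated to the stream duration. Deterministic given `params$seed`.
#'
#' @param design A trial table from [generate_design()] (validated first).
#' @param params An [observer_params()] object.
#' @param stream_duration_s Stimulus duration in seconds.
#' @return A response table: `data.frame` with `trial_id`, `responded`,
#'   `response_time_s` (NA when no response; measured from stream onset)
#'   and `premature`.
#' @export
simulate_observer <- function(design, params = observer_params(),
                              stream_duration_s = 5.0) {
  stopifnot(inherits(params, "observer_params"))
  validate_trial_table(design, cfg = NULL)
  n <- nrow(design)
  state <- ifelse(design$cue_condition == "neutral", "neutral",
                  ifelse(design$cued_stream == design$target_stream,
                         "attended", "unattended"))
  d_eff <- params$dprime[state]
  k_eff <- params$k[state]
  g <- stats::pnorm(-k_eff) / stats::pnorm(-params$k[["attended"]])
  p_prem <- pmin(params$premature_rate * g, 0.999)
  onset <- design$target_onset_s

  withr::with_seed(params$seed, {
    u_prem <- stats::runif(n)
    t_prem <- stats::runif(n) * onset
    evidence <- stats::rnorm(n, mean = d_eff)
    latency <- exp(stats::rnorm(n, params$rt_mu, params$rt_sigma))
  })
  shift <- ifelse(state == "attended", -params$rt_attention_shift,
                  ifelse(state == "unattended", params$rt_attention_shift, 0))
  latency <- pmax(latency + shift, 0.01)

  premature <- u_prem < p_prem
  detect <- !premature & evidence > k_eff
  rt <- rep(NA_real_, n)
  rt[premature] <- t_prem[premature]
  rt[detect] <- pmin(onset[detect] + latency[detect], stream_duration_s)

  data.frame(trial_id = design$trial_id,
             responded = premature | detect,
             response_time_s = rt,
             premature = premature)
}

#' Write/read response tables as CSV
#' @param responses A response table from [simulate_observer()].
#' @param path File path.
#' @return `write_response_table()` returns `path` invisibly;
#'   `read_response_table()` returns the table.
#' @export
write_response_table <- function(responses, path) {
  utils::write.csv(responses[, c("trial_id", "responded", "response_time_s",
                                 "premature")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_response_table
#' @export
read_response_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
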