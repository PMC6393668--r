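# Cue-validity trial designs. Condition counts are exact per session
# (largest-remainder apportionment of the 70/20/10 split), target stream is
# balanced 50/50 within each condition, and all conditions are trial-wise
# intermixed by a seeded shuffle.

#' Design configuration
#'
#' Parameters of a cue-validity session. Defaults reproduce the two-stream
#' speech/environment layout: 3 blocks of 100 trials, 70% valid / 20%
#' invalid / 10% neutral cues, target stream balanced 50/50, fixation
#' interval jittered 1.0-2.0 s and cue-to-audio interval 0.5-0.75 s, visual
#' cue.
#'
#' @param n_blocks,trials_per_block Session layout.
#' @param p_valid,p_invalid,p_neutral Cue-validity proportions, must sum to 1.
#' @param target_stream_balance Proportion of targets in stream A.
#' @param fixation_jitter,cue_to_audio_jitter Length-2 ranges in seconds.
#' @param cue_kind `"visual_label"`, `"auditory_preplay"` or `"none"`.
#' @param seed RNG seed for shuffling, jitters and per-trial stimulus seeds.
#' @return A `design_config` list.
#' @export
design_config <- function(n_blocks = 3L, trials_per_block = 100L,
                          p_valid = 0.7, p_invalid = 0.2, p_neutral = 0.1,
                          target_stream_balance = 0.5,
                          fixation_jitter = c(1.0, 2.0),
                          cue_to_audio_jitter = c(0.5, 0.75),
                          cue_kind = c("visual_label", "auditory_preplay",
                                       "none"),
                          seed = 1L) {
  cue_kind <- match.arg(cue_kind)
  if (abs(p_valid + p_invalid + p_neutral - 1) > 1e-9) {
    stop("cue-validity proportions must sum to 1", call. = FALSE)
  }
  if (n_blocks < 1L || trials_per_block < 1L) {
    stop("n_blocks and trials_per_block must be >= 1", call. = FALSE)
  }
  structure(list(n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 p_valid = p_valid, p_invalid = p_invalid,
                 p_neutral = p_neutral,
                 target_stream_balance = target_stream_balance,
                 fixation_jitter = fixation_jitter,
                 cue_to_audio_jitter = cue_to_audio_jitter,
                 cue_kind = cue_kind, seed = as.integer(seed)),
            class = "design_config")
}

#' Experiment presets for the design generator
#'
#' `exp1_design_config()`: 3 blocks x 100 trials, visual cue, fixation
#' jitter 1.0-2.0 s, cue-to-audio jitter 0.5-0.75 s (speech + environment
#' streams). `exp2_design_config()`: 5 blocks x 60 trials, auditory pre-play
#' cue, both intervals jittered 1.0-1.5 s (two speech streams).
#'
#' @param seed RNG seed.
#' @return A [design_config()].
#' @export
exp1_design_config <- function(seed = 1L) {
  design_config(seed = seed)
}

#' @rdname exp1_design_config
#' @export
exp2_design_config <- function(seed = 1L) {
  design_config(n_blocks = 5L, trials_per_block = 60L,
                fixation_jitter = c(1.0, 1.5),
                cue_to_audio_jitter = c(1.0, 1.5),
                cue_kind = "auditory_preplay", seed = seed)
}

# Largest-remainder apportionment: floor the quotas, then hand the
# remaining units to the largest fractional remainders (ties -> earlier).
.largest_remainder <- function(n, p) {
  q <- n * p
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(-(q - base), seq_along(p))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a cue-validity trial table
#'
#' Builds the per-session trial design: exact condition counts via
#' largest-remainder apportionment (never binomial draws), target stream
#' balanced within each condition, a seeded global shuffle intermixing all
#' conditions across blocks, uniform jitters within the configured ranges, a
#' per-trial target onset drawn from the repetition embedder's admissible
#' range, and a per-trial stimulus seed.
#'
#' @param cfg A [design_config()].
#' @param stim_cfg A [stimulus_config()]; sets the target-onset geometry.
#' @return A `data.frame` with columns `trial_id`, `block`, `cue_condition`,
#'   `cued_stream`, `target_stream`, `target_onset_s`, `fixation_interval_s`,
#'   `cue_interval_s`, `stimulus_seed`.
#' @export
generate_design <- function(cfg = design_config(),
                            stim_cfg = stimulus_config()) {
  stopifnot(inherits(cfg, "design_config"), inherits(stim_cfg, "stimulus_config"))
  n <- cfg$n_blocks * cfg$trials_per_block
  counts <- .largest_remainder(n, c(cfg$p_valid, cfg$p_invalid, cfg$p_neutral))
  conds <- c("valid", "invalid", "neutral")

  cond_col <- character(0)
  target_col <- character(0)
  for (i in seq_along(conds)) {
    n_c <- counts[i]
    n_a <- .largest_remainder(n_c, c(cfg$target_stream_balance,
                                     1 - cfg$target_stream_balance))[1]
    cond_col <- c(cond_col, rep(conds[i], n_c))
    target_col <- c(target_col, rep(c("A", "B"), c(n_a, n_c - n_a)))
  }
  cued_col <- ifelse(cond_col == "valid", target_col,
                     ifelse(cond_col == "invalid",
                            ifelse(target_col == "A", "B", "A"), "none"))

  n_src <- round((stim_cfg$segment_duration + stim_cfg$repetition_duration) *
                   stim_cfg$sample_rate)
  rng <- .admissible_cut_range(n_src, stim_cfg)

  withr::with_seed(cfg$seed, {
    ord <- sample.int(n)
    fixation <- stats::runif(n, cfg$fixation_jitter[1], cfg$fixation_jitter[2])
    cue_int <- stats::runif(n, cfg$cue_to_audio_jitter[1],
                            cfg$cue_to_audio_jitter[2])
    cuts <- sample.int(rng[2] - rng[1] + 1L, n, replace = TRUE) + rng[1] - 1L
    stim_seeds <- sample.int(.Machine$integer.max - 1L, n)
  })

  onsets <- vapply(cuts, function(cut) {
    geo <- .repetition_geometry(cut, n_src, stim_cfg)
    (geo$second_onset - 1L) / stim_cfg$sample_rate
  }, numeric(1))

  df <- data.frame(trial_id = seq_len(n),
                   block = rep(seq_len(cfg$n_blocks),
                               each = cfg$trials_per_block),
                   cue_condition = cond_col[ord],
                   cued_stream = cued_col[ord],
                   target_stream = target_col[ord],
                   target_onset_s = onsets,
                   fixation_interval_s = fixation,
                   cue_interval_s = cue_int,
                   stimulus_seed = stim_seeds,
                   cut_sample = cuts,
                   stringsAsFactors = FALSE)
  attr(df, "design_config") <- cfg
  attr(df, "stimulus_config") <- stim_cfg
  df
}

#' Validate a trial table
#'
#' Checks the structural invariants of a cue-validity trial table: cue/target
#' consistency (valid => cued = target; invalid => cued is the other stream;
#' neutral => no cue), condition proportions exact for the session, target
#' stream balanced within condition up to rounding, onsets and jitters
#' positive.
#'
#' @param design A trial table from [generate_design()].
#' @param cfg The [design_config()] to check proportions against (taken from
#'   the table's attribute when `NULL`).
#' @return `TRUE` invisibly, or an error listing every violated invariant.
#' @export
validate_trial_table <- function(design, cfg = NULL) {
  if (is.null(cfg)) cfg <- attr(design, "design_config")
  problems <- character(0)
  need <- c("trial_id", "cue_condition", "cued_stream", "target_stream",
            "target_onset_s")
  miss <- setdiff(need, names(design))
  if (length(miss)) {
    stop("trial table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  v <- design$cue_condition == "valid" & design$cued_stream != design$target_stream
  i <- design$cue_condition == "invalid" &
    (design$cued_stream == design$target_stream | design$cued_stream == "none")
  nn <- design$cue_condition == "neutral" & design$cued_stream != "none"
  if (any(v)) problems <- c(problems, sprintf("%d valid trials with cued != target", sum(v)))
  if (any(i)) problems <- c(problems, sprintf("%d invalid trials miscued", sum(i)))
  if (any(nn)) problems <- c(problems, sprintf("%d neutral trials with a cue", sum(nn)))
  if (any(design$target_onset_s <= 0)) {
    problems <- c(problems, "non-positive target onsets")
  }
  if (!is.null(cfg)) {
    n <- nrow(design)
    want <- .largest_remainder(n, c(cfg$p_valid, cfg$p_invalid, cfg$p_neutral))
    got <- c(sum(design$cue_condition == "valid"),
             sum(design$cue_condition == "invalid"),
             sum(design$cue_condition == "neutral"))
    if (!all(want == got)) {
      problems <- c(problems,
                    sprintf("condition counts %s != expected %s",
                            paste(got, collapse = "/"),
                            paste(want, collapse = "/")))
    }
    for (cond in c("valid", "invalid", "neutral")) {
      sub <- design$target_stream[design$cue_condition == cond]
      if (abs(sum(sub == "A") - sum(sub == "B")) > 1) {
        problems <- c(problems,
                      sprintf("target stream unbalanced in %s condition", cond))
      }
    }
  }
  if (length(problems)) {
    stop("invalid trial table:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read/write trial tables as CSV
#'
#' The CSV carries the canonical header
#' `trial_id,block,cue_condition,cued_stream,target_stream,target_onset_s,fixation_interval_s,cue_interval_s,stimulus_seed`.
#'
#' @param design A trial table.
#' @param path File path.
#' @return `write_trial_table()` returns `path` invisibly;
#'   `read_trial_table()` returns the trial table.
#' @export
write_trial_table <- function(design, path) {
  cols <- c("trial_id", "block", "cue_condition", "cued_stream",
            "target_stream", "target_onset_s", "fixation_interval_s",
            "cue_interval_s", "stimulus_seed")
  utils::write.csv(design[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
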