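# Behavioural analysis: trial scoring (hit / miss / false alarm), SDT
# indices with the 1/(2N) extreme-rate correction, per-cell condition
# summaries, and the inferential layer (paired contrasts, repeated-measures
# ANOVA) in stats.R.

#' Score trials against responses
#'
#' Joins a trial design with a response table by `trial_id` and labels each
#' trial: a response before target onset is a `false_alarm` (the task's
#' operational false-alarm definition), a response between target onset and
#' stream end is a `hit` (with `rt_s = response_time - target_onset`), and
#' a trial without a qualifying response is a `miss`.
#'
#' @param design A trial table from [generate_design()].
#' @param responses A response table from [simulate_observer()].
#' @param stream_duration_s End of the hit window, in seconds.
#' @return A `data.frame` with the design columns plus `outcome`
#'   (`"hit"`/`"miss"`/`"false_alarm"`) and `rt_s` (hit latency, NA else).
#' @export
score_trials <- function(design, responses, stream_duration_s = 5.0) {
  orphans_d <- setdiff(design$trial_id, responses$trial_id)
  orphans_r <- setdiff(responses$trial_id, design$trial_id)
  if (length(orphans_d) || length(orphans_r)) {
    stop(sprintf("trial_id mismatch between design and responses (design-only: %s; response-only: %s)",
                 paste(utils::head(orphans_d, 5), collapse = ","),
                 paste(utils::head(orphans_r, 5), collapse = ",")),
         call. = FALSE)
  }
  m <- match(design$trial_id, responses$trial_id)
  rt <- responses$response_time_s[m]
  responded <- responses$responded[m]
  onset <- design$target_onset_s

  outcome <- rep("miss", nrow(design))
  fa <- responded & !is.na(rt) & rt < onset
  hit <- responded & !is.na(rt) & rt >= onset & rt <= stream_duration_s
  outcome[fa] <- "false_alarm"
  outcome[hit] <- "hit"
  out <- design
  out$outcome <- outcome
  out$rt_s <- ifelse(hit, rt - onset, NA_real_)
  out
}

#' Standard normal quantile (z transform)
#'
#' `inverse_normal(p)` returns the z with `pnorm(z) = p`; the building block
#' of d' and criterion.
#'
#' @param p Probability strictly inside (0, 1).
#' @return The standard normal quantile.
#' @export
inverse_normal <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("`p` must lie strictly inside (0, 1)", call. = FALSE)
  }
  stats::qnorm(p)
}

#' SDT sensitivity and criterion from counts
#'
#' Computes hit and false-alarm rates, applies the 1/(2N) extreme-rate
#' correction (a rate of 0 becomes `1/(2N)`, a rate of 1 becomes
#' `1 - 1/(2N)`; Macmillan & Creelman's recommendation), and returns
#' `d' = z(H) - z(FA)` and `c = -(z(H) + z(FA)) / 2`.
#'
#' @param hits,n_signal Hit count and number of signal opportunities.
#' @param fas,n_noise False-alarm count and number of noise opportunities.
#' @return An `sdt_scores` list: `hit_rate`, `fa_rate` (corrected), `dprime`,
#'   `criterion`, `n_signal`, `n_noise`.
#' @examples
#' sdt_indices(17, 20, 1, 20) # d' = 2.681, c = 0.304
#' @export
sdt_indices <- function(hits, n_signal, fas, n_noise) {
  if (n_signal < 1 || n_noise < 1) {
    stop("n_signal and n_noise must be >= 1", call. = FALSE)
  }
  if (hits < 0 || fas < 0 || hits > n_signal || fas > n_noise) {
    stop("counts must satisfy 0 <= hits <= n_signal, 0 <= fas <= n_noise",
         call. = FALSE)
  }
  correct <- function(k, n) {
    r <- k / n
    if (r == 0) r <- 1 / (2 * n)
    if (r == 1) r <- 1 - 1 / (2 * n)
    r
  }
  h <- correct(hits, n_signal)
  f <- correct(fas, n_noise)
  zh <- inverse_normal(h)
  zf <- inverse_normal(f)
  structure(list(hit_rate = h, fa_rate = f,
                 dprime = zh - zf, criterion = -(zh + zf) / 2,
                 n_signal = n_signal, n_noise = n_noise),
            class = "sdt_scores")
}

#' @export
print.sdt_scores <- function(x, ...) {
  cat(sprintf("<sdt_scores> H = %.3f (n=%d), FA = %.3f (n=%d), d' = %.3f, c = %.3f\n",
              x$hit_rate, x$n_signal, x$fa_rate, x$n_noise,
              x$dprime, x$criterion))
  invisible(x)
}

# Per-cell measures for one participant's scored trials. n_signal excludes
# premature trials (the target was never reached); the false-alarm
# denominator is every trial in the cell (one pre-target opportunity each).
.cell_measures <- function(scored) {
  hits <- sum(scored$outcome == "hit")
  misses <- sum(scored$outcome == "miss")
  fas <- sum(scored$outcome == "false_alarm")
  n_sig <- hits + misses
  n_all <- nrow(scored)
  acc <- if (n_sig > 0) 100 * hits / n_sig else NA_real_
  rt_ms <- if (hits > 0) 1000 * mean(scored$rt_s[scored$outcome == "hit"]) else NA_real_
  if (n_sig > 0 && n_all > 0) {
    s <- sdt_indices(hits, n_sig, fas, n_all)
    dp <- s$dprime; cr <- s$criterion
  } else {
    dp <- NA_real_; cr <- NA_real_
  }
  data.frame(n_trials = n_all, hits = hits, misses = misses,
             false_alarms = fas, accuracy = acc, rt_ms = rt_ms,
             dprime = dp, criterion = cr)
}

#' Summarise an experiment into condition cells
#'
#' Produces the per-cell behavioural summary (accuracy in percent correct,
#' mean hit reaction time in ms, d', criterion) for each cue condition,
#' optionally crossed with target stream, per participant, plus the
#' across-participant mean and SEM per cell.
#'
#' @param design A trial table, or a list of trial tables (one per
#'   participant).
#' @param responses A response table, or a list matching `design`.
#' @param grouping `"by_condition_and_stream"` (3 x 2 cells) or
#'   `"by_condition"` (3 cells).
#' @param stream_duration_s Hit-window end, seconds.
#' @return A `condition_summary`: list with `cells` (one row per participant
#'   x cell) and `table` (per-cell mean and SEM across participants).
#' @export
summarize_experiment <- function(design, responses,
                                 grouping = c("by_condition_and_stream",
                                              "by_condition"),
                                 stream_duration_s = 5.0) {
  grouping <- match.arg(grouping)
  if (is.data.frame(design)) design <- list(design)
  if (is.data.frame(responses)) responses <- list(responses)
  if (length(design) != length(responses)) {
    stop("`design` and `responses` must have one element per participant",
         call. = FALSE)
  }
  conds <- c("valid", "neutral", "invalid")
  streams <- if (grouping == "by_condition_and_stream") c("A", "B") else "all"

  cells <- do.call(rbind, lapply(seq_along(design), function(p) {
    scored <- score_trials(design[[p]], responses[[p]], stream_duration_s)
    do.call(rbind, lapply(conds, function(cond) {
      do.call(rbind, lapply(streams, function(st) {
        sub <- scored[scored$cue_condition == cond &
                        (st == "all" | scored$target_stream == st), ,
                      drop = FALSE]
        if (nrow(sub) == 0L) return(NULL)
        cbind(data.frame(participant = sprintf("P%02d", p),
                         cue_condition = cond, target_stream = st),
              .cell_measures(sub))
      }))
    }))
  }))

  sem <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  }
  key <- interaction(cells$cue_condition, cells$target_stream, drop = TRUE)
  agg <- do.call(rbind, lapply(split(cells, key), function(g) {
    data.frame(cue_condition = g$cue_condition[1],
               target_stream = g$target_stream[1],
               n_participants = nrow(g),
               accuracy_mean = mean(g$accuracy, na.rm = TRUE),
               accuracy_sem = sem(g$accuracy),
               rt_ms_mean = mean(g$rt_ms, na.rm = TRUE),
               rt_ms_sem = sem(g$rt_ms),
               dprime_mean = mean(g$dprime, na.rm = TRUE),
               dprime_sem = sem(g$dprime),
               criterion_mean = mean(g$criterion, na.rm = TRUE),
               criterion_sem = sem(g$criterion))
  }))
  agg$cue_condition <- factor(agg$cue_condition, levels = conds)
  agg <- agg[order(agg$target_stream, agg$cue_condition), ]
  rownames(agg) <- NULL
  structure(list(cells = cells, table = agg, grouping = grouping),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("<condition_summary> grouping %s, %d participant(s)\n",
              x$grouping, length(unique(x$cells$participant))))
  t <- x$table
  fmt <- function(m, s) ifelse(is.na(s), sprintf("%.2f", m),
                               sprintf("%.2f (%.2f)", m, s))
  show <- data.frame(condition = as.character(t$cue_condition),
                     stream = t$target_stream,
                     accuracy = fmt(t$accuracy_mean, t$accuracy_sem),
                     rt_ms = fmt(t$rt_ms_mean, t$rt_ms_sem),
                     dprime = fmt(t$dprime_mean, t$dprime_sem),
                     criterion = fmt(t$criterion_mean, t$criterion_sem))
  print(show, row.names = FALSE)
  invisible(x)
}

#' Export a condition summary as CSV
#'
#' Writes the Table-style layout: one row per measure x stream, columns
#' Valid / Neutral / Invalid, cells formatted `mean (SEM)`.
#'
#' @param summary A `condition_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summary, path) {
  t <- summary$table
  fmt <- function(m, s) ifelse(is.na(s), sprintf("%.3f", m),
                               sprintf("%.3f (%.3f)", m, s))
  rows <- list()
  for (meas in c("accuracy", "rt_ms", "dprime", "criterion")) {
    for (st in unique(t$target_stream)) {
      r <- list(measure = meas, stream = st)
      for (cond in c("valid", "neutral", "invalid")) {
        sel <- t$cue_condition == cond & t$target_stream == st
        r[[cond]] <- if (any(sel)) {
          fmt(t[[paste0(meas, "_mean")]][sel], t[[paste0(meas, "_sem")]][sel])
        } else ""
      }
      rows[[length(rows) + 1L]] <- as.data.frame(r)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
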