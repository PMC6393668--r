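# One-call reproduction of a full synthetic experiment: per-participant
# designs, simulated responses, condition summaries and the inferential
# report, written to disk with a hashed manifest. Audio rendering is
# optional so the default run stays fast; design + observer + analysis run
# on annotations alone.

#' Experiment run configuration
#'
#' @param experiment `"exp1"` (two-way: cue validity x target stream,
#'   speech + environment) or `"exp2"` (one-way: cue validity, two speech
#'   streams).
#' @param n_participants Number of simulated participants (default 10, the
#'   analysed cohort size of both versions of the paradigm).
#' @param stimulus A [stimulus_config()].
#' @param design A [design_config()]; defaults to the experiment's preset.
#' @param observer An [observer_params()]; defaults to the experiment's
#'   preset.
#' @param output_dir Directory the artifact bundle is written to.
#' @param master_seed Seed from which all per-participant seeds are derived
#'   (deterministically, via one `sample.int()` stream).
#' @param render_audio If `TRUE`, also synthesise and write trial stimulus
#'   WAVs (first `n_render_trials` trials of participant 1).
#' @param n_render_trials Number of trials to render when `render_audio`.
#' @return A `run_config` list.
#' @export
run_config <- function(experiment = c("exp1", "exp2"), n_participants = 10L,
                       stimulus = stimulus_config(), design = NULL,
                       observer = NULL, output_dir = tempfile("scenecue_run_"),
                       master_seed = 1L, render_audio = FALSE,
                       n_render_trials = 2L) {
  experiment <- match.arg(experiment)
  if (is.null(design)) {
    design <- if (experiment == "exp1") exp1_design_config() else exp2_design_config()
  }
  if (is.null(observer)) observer <- observer_preset(experiment)
  if (n_participants < 2L) stop("need >= 2 participants", call. = FALSE)
  structure(list(experiment = experiment,
                 n_participants = as.integer(n_participants),
                 stimulus = stimulus, design = design, observer = observer,
                 output_dir = output_dir, master_seed = as.integer(master_seed),
                 render_audio = isTRUE(render_audio),
                 n_render_trials = as.integer(n_render_trials)),
            class = "run_config")
}

#' Run a full synthetic experiment
#'
#' Generates one trial design and one simulated response table per
#' participant, scores them, builds the condition summary (3 x 2 cells for
#' `exp1`, 3 cells for `exp2`) and the inferential report (repeated-measures
#' ANOVA plus planned contrasts for accuracy, RT, d' and criterion), writes
#' everything to `cfg$output_dir` as CSV, and finishes with `manifest.json`
#' listing every written file with its MD5 hash. Fully reproducible given
#' `master_seed`.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with `summary` (the `condition_summary`),
#'   `stats` (the [experiment_stats()] report), `designs`, `responses`, and
#'   `manifest` (the file/hash table).
#' @export
run_experiment <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  np <- cfg$n_participants
  seeds <- withr::with_seed(cfg$master_seed,
                            matrix(sample.int(.Machine$integer.max - 1L,
                                              2L * np), ncol = 2L))
  designs <- vector("list", np)
  responses <- vector("list", np)
  files <- character(0)
  for (p in seq_len(np)) {
    dcfg <- cfg$design
    dcfg$seed <- seeds[p, 1]
    designs[[p]] <- generate_design(dcfg, cfg$stimulus)
    obs <- cfg$observer
    obs$seed <- seeds[p, 2]
    responses[[p]] <- simulate_observer(designs[[p]], obs,
                                        cfg$stimulus$segment_duration)
    fd <- file.path(cfg$output_dir, sprintf("design_P%02d.csv", p))
    fr <- file.path(cfg$output_dir, sprintf("responses_P%02d.csv", p))
    write_trial_table(designs[[p]], fd)
    write_response_table(responses[[p]], fr)
    files <- c(files, fd, fr)
  }

  grouping <- if (cfg$experiment == "exp1") "by_condition_and_stream" else "by_condition"
  summ <- summarize_experiment(designs, responses, grouping,
                               cfg$stimulus$segment_duration)
  stats_rep <- experiment_stats(summ)

  f_cells <- file.path(cfg$output_dir, "summary_cells.csv")
  utils::write.csv(summ$cells, f_cells, row.names = FALSE)
  f_table <- file.path(cfg$output_dir, "summary_table.csv")
  write_summary_csv(summ, f_table)
  files <- c(files, f_cells, f_table)

  stats_rows <- do.call(rbind, lapply(names(stats_rep), function(meas) {
    a <- stats_rep[[meas]]$anova
    ct <- stats_rep[[meas]]$contrasts
    if (is.null(a)) return(NULL)
    rbind(data.frame(measure = meas, kind = "anova", term = a$effect,
                     statistic = a$f, df1 = a$df, df2 = NA_real_, p = a$p),
          data.frame(measure = meas, kind = "contrast", term = ct$contrast,
                     statistic = ct$t, df1 = ct$df, df2 = NA_real_, p = ct$p))
  }))
  f_stats <- file.path(cfg$output_dir, "stats_report.csv")
  utils::write.csv(stats_rows, f_stats, row.names = FALSE)
  files <- c(files, f_stats)

  if (cfg$render_audio) {
    n_rend <- min(cfg$n_render_trials, nrow(designs[[1]]))
    anns <- list()
    mode <- if (cfg$experiment == "exp1") "speech_env" else "speech_speech"
    src_dur <- cfg$stimulus$segment_duration +
      cfg$stimulus$repetition_duration + 0.25
    for (tr in seq_len(n_rend)) {
      row <- designs[[1]][tr, ]
      sa <- synth_speechlike(src_dur, cfg$stimulus$sample_rate,
                             seed = row$stimulus_seed)
      sb <- if (mode == "speech_env") {
        synth_envlike(src_dur, cfg$stimulus$sample_rate,
                      seed = row$stimulus_seed + 1L)
      } else {
        synth_speechlike(src_dur, cfg$stimulus$sample_rate,
                         seed = row$stimulus_seed + 1L)
      }
      ts <- build_trial_stimulus(sa, sb, row$target_stream, mode,
                                 cfg$stimulus, cut_sample = row$cut_sample)
      fw <- file.path(cfg$output_dir, sprintf("trial_%04d.wav", row$trial_id))
      write_trial_wav(ts, fw, channels = 2L)
      files <- c(files, fw)
      anns[[sprintf("trial_%04d", row$trial_id)]] <- ts$annotation
    }
    fa <- file.path(cfg$output_dir, "annotations.csv")
    write_annotation_csv(anns, fa)
    files <- c(files, fa)
  }

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)

  invisible(list(summary = summ, stats = stats_rep, designs = designs,
                 responses = responses, manifest = manifest,
                 output_dir = cfg$output_dir))
}
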