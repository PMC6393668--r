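test_that("session layouts have exact largest-remainder condition counts", {
  d1 <- generate_design(exp1_design_config(1))
  expect_equal(nrow(d1), 300)
  tab <- table(d1$cue_condition)
  expect_equal(unname(tab[c("valid", "invalid", "neutral")]), c(210, 60, 30),
               ignore_attr = TRUE)
  d2 <- generate_design(exp2_design_config(1))
  expect_equal(nrow(d2), 300)
  expect_equal(max(d2$block), 5)
  expect_equal(sum(d2$block == 1), 60)
  # odd split resolved by largest remainder, never an error
  cfg <- design_config(n_blocks = 1L, trials_per_block = 100L,
                       p_valid = 1/3, p_invalid = 1/3, p_neutral = 1/3)
  d3 <- generate_design(cfg)
  expect_equal(sort(unname(table(d3$cue_condition)), decreasing = TRUE),
               c(34, 33, 33), ignore_attr = TRUE)
  expect_error(design_config(p_valid = 0.7, p_invalid = 0.2, p_neutral = 0.2),
               "sum to 1")
})

test_that("designs are deterministic by seed and differ across seeds", {
  a <- generate_design(exp1_design_config(5))
  b <- generate_design(exp1_design_config(5))
  expect_identical(a, b)
  c <- generate_design(exp1_design_config(6))
  expect_false(identical(a$cue_condition, c$cue_condition))
  expect_equal(table(a$cue_condition), table(c$cue_condition))
})

test_that("generated tables satisfy the cue/target/balance invariants", {
  for (seed in 1:10) {
    d <- generate_design(exp1_design_config(seed))
    expect_true(validate_trial_table(d))
    with(d, {
      expect_true(all(cued_stream[cue_condition == "valid"] ==
                        target_stream[cue_condition == "valid"]))
      expect_true(all(cued_stream[cue_condition == "invalid"] !=
                        target_stream[cue_condition == "invalid"]))
      expect_true(all(cued_stream[cue_condition == "invalid"] != "none"))
      expect_true(all(cued_stream[cue_condition == "neutral"] == "none"))
    })
    for (cond in unique(d$cue_condition)) {
      sub <- d$target_stream[d$cue_condition == cond]
      expect_lte(abs(sum(sub == "A") - sum(sub == "B")), 1)
    }
  }
})

test_that("the validator reports corrupted tables", {
  d <- generate_design(exp1_design_config(2))
  d$cued_stream[d$cue_condition == "valid"][1] <- "none"
  expect_error(validate_trial_table(d), "valid trials")
  d2 <- generate_design(exp1_design_config(2))
  d2$cue_condition[1:50] <- "valid"
  expect_error(validate_trial_table(d2), "counts")
})

test_that("jitters stay inside their ranges with plausible means", {
  d <- generate_design(exp1_design_config(3))
  expect_true(all(d$fixation_interval_s >= 1.0 & d$fixation_interval_s <= 2.0))
  expect_true(all(d$cue_interval_s >= 0.5 & d$cue_interval_s <= 0.75))
  expect_lt(abs(mean(d$fixation_interval_s) - 1.5), 0.15)
  expect_lt(abs(mean(d$cue_interval_s) - 0.625), 0.0625)
  d2 <- generate_design(exp2_design_config(3))
  expect_true(all(d2$fixation_interval_s >= 1.0 & d2$fixation_interval_s <= 1.5))
  expect_true(all(d2$cue_interval_s >= 1.0 & d2$cue_interval_s <= 1.5))
})

test_that("target onsets match the embedder's admissible geometry", {
  cfg <- stimulus_config()
  d <- generate_design(exp1_design_config(4), cfg)
  expect_true(all(d$target_onset_s > 0.25))
  expect_true(all(d$target_onset_s + cfg$repetition_duration <
                    cfg$segment_duration - 0.2))
  # recorded onset agrees with an actual embedding at the recorded cut
  src <- synth_speechlike(6, seed = 1)
  row <- d[1, ]
  ts <- build_trial_stimulus(src, synth_envlike(6, seed = 2),
                             row$target_stream,
                             mode = "speech_env", cfg,
                             cut_sample = row$cut_sample)
  expect_equal(ts$annotation$onset_s, row$target_onset_s, tolerance = 1e-9)
})

test_that("trial tables round-trip through the canonical CSV", {
  d <- generate_design(exp1_design_config(7))
  p <- withr::local_tempfile(fileext = ".csv")
  write_trial_table(d, p)
  header <- readLines(p, n = 1)
  expect_equal(header,
               paste0("\"trial_id\",\"block\",\"cue_condition\",\"cued_stream\",",
                      "\"target_stream\",\"target_onset_s\",",
                      "\"fixation_interval_s\",\"cue_interval_s\",\"stimulus_seed\""))
  r <- read_trial_table(p)
  expect_equal(r$cue_condition, d$cue_condition)
  expect_equal(r$target_onset_s, d$target_onset_s, tolerance = 1e-9)
})
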