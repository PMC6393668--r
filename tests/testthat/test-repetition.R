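test_that("cross-fade conserves constants and does the splice arithmetic", {
  rate <- 44100
  a <- audio_segment(rep(0.4, 1000), rate)
  b <- audio_segment(rep(0.4, 500), rate)
  out <- crossfade_concat(a, b, 220)
  expect_equal(n_frames(out), 1280) # 1000 + 500 - 220
  expect_equal(out$samples, rep(0.4, 1280), tolerance = 1e-12)
  # verbatim copies outside the overlap
  x <- audio_segment(withr::with_seed(1, rnorm(1000)), rate)
  y <- audio_segment(withr::with_seed(2, rnorm(500)), rate)
  o2 <- crossfade_concat(x, y, 220)
  expect_identical(o2$samples[1:780], x$samples[1:780])
  expect_identical(o2$samples[1001:1280], y$samples[221:500])
  expect_error(crossfade_concat(x, y, 0), ">= 1")
  expect_error(crossfade_concat(x, y, 501), "longer")
})

test_that("embedding reproduces the reference splice geometry", {
  cfg <- stimulus_config()
  src <- audio_segment(withr::with_seed(3, rnorm(253575) * 0.1), 44100) # 5.75 s
  emb <- embed_repetition(src, cfg, cut_sample = 88200) # cut at 2.0 s
  an <- emb$annotation
  expect_equal(duration(emb$audio), 5.0)
  expect_equal(n_frames(emb$audio), 220500)
  expect_equal(an$second_onset - an$first_onset, 32855) # R - ramp
  expect_equal(an$rep_length, 33075)
  expect_equal(an$ramp_samples, 220)
  # central non-ramped regions of the two epochs are sample-identical
  y <- emb$audio$samples
  lag <- an$second_onset - an$first_onset
  idx <- (an$first_onset + an$ramp_samples):
    (an$first_onset + an$rep_length - an$ramp_samples - 1)
  expect_identical(y[idx], y[idx + lag])
})

test_that("length bookkeeping: pre-trim splice length is source + R - 2 ramp", {
  cfg <- stimulus_config()
  geo <- scenecue:::.repetition_geometry(88200, 253575, cfg)
  expect_equal(geo$pre_trim_len, 253575 + 33075 - 2 * 220)
})

test_that("sources that are too short or cuts out of range are rejected", {
  cfg <- stimulus_config()
  short <- audio_segment(withr::with_seed(4, rnorm(5 * 44100)), 44100)
  expect_error(embed_repetition(short, cfg), "too short")
  src <- audio_segment(withr::with_seed(4, rnorm(253575)), 44100)
  expect_error(embed_repetition(src, cfg, cut_sample = 100), "admissible")
  expect_error(embed_repetition(src, cfg, cut_sample = 253000), "admissible")
})

test_that("splices are click-free and the repetition stays off the stream edges", {
  cfg <- stimulus_config()
  for (seed in 1:10) {
    src <- audio_segment(withr::with_seed(seed, rnorm(253575) * 0.1), 44100)
    emb <- embed_repetition(src, cfg, seed = seed)
    an <- emb$annotation
    margin <- round(cfg$edge_margin * 44100)
    expect_gte(an$first_onset, margin)
    expect_lte(an$second_onset + an$rep_length - 1, 220500 - margin + 1)
    d_out <- abs(diff(emb$audio$samples))
    thr <- 3 * stats::quantile(abs(diff(src$samples)), 0.99)
    splice_pts <- c(an$second_onset, an$second_onset + an$ramp_samples,
                    an$second_onset + an$rep_length - an$ramp_samples,
                    an$second_onset + an$rep_length)
    for (p in splice_pts) {
      win <- max(1, p - 221):min(length(d_out), p + 221)
      expect_lte(max(d_out[win]), thr)
    }
  }
})

test_that("the lag-scan oracle recovers every seeded repetition location", {
  cfg <- stimulus_config()
  hits <- 0L
  for (seed in 1:100) {
    src <- audio_segment(withr::with_seed(1000 + seed, rnorm(253575)), 44100)
    emb <- embed_repetition(src, cfg, seed = seed)
    an <- emb$annotation
    sc <- lag_scan(emb$audio, an$second_onset - an$first_onset, 4410)
    if (abs(sc$best_start - an$first_onset) <= an$ramp_samples) hits <- hits + 1L
  }
  expect_equal(hits, 100L)
})

test_that("embedding with a seeded random cut is deterministic", {
  cfg <- stimulus_config()
  src <- audio_segment(withr::with_seed(5, rnorm(253575)), 44100)
  e1 <- embed_repetition(src, cfg, seed = 42)
  e2 <- embed_repetition(src, cfg, seed = 42)
  expect_identical(e1$audio$samples, e2$audio$samples)
  expect_identical(e1$annotation$cut_sample, e2$annotation$cut_sample)
  e3 <- embed_repetition(src, cfg, seed = 43)
  expect_false(e3$annotation$cut_sample == e1$annotation$cut_sample)
})
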