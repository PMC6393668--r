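test_that("trials are scored by the response-time windows", {
  design <- data.frame(trial_id = 1:4, cue_condition = "valid",
                       cued_stream = "A", target_stream = "A",
                       target_onset_s = 2.0)
  responses <- data.frame(trial_id = 1:4,
                          responded = c(TRUE, TRUE, FALSE, TRUE),
                          response_time_s = c(1.9, 2.3, NA, 5.5),
                          premature = c(TRUE, FALSE, FALSE, FALSE))
  sc <- score_trials(design, responses)
  expect_equal(sc$outcome, c("false_alarm", "hit", "miss", "miss"))
  expect_equal(sc$rt_s[2], 0.3)
  expect_true(all(is.na(sc$rt_s[-2])))
  expect_error(score_trials(design, responses[1:3, ]), "mismatch")
})

test_that("inverse_normal matches the standard normal quantile", {
  expect_equal(inverse_normal(0.5), 0)
  expect_equal(inverse_normal(0.975), 1.959964, tolerance = 1e-6)
  expect_equal(inverse_normal(0.05), -1.644854, tolerance = 1e-6)
  for (p in c(0.01, 0.2, 0.7, 0.999)) {
    expect_lt(abs(stats::pnorm(inverse_normal(p)) - p), 1e-10)
  }
  expect_error(inverse_normal(0), "\\(0, 1\\)")
  expect_error(inverse_normal(1), "\\(0, 1\\)")
})

test_that("SDT indices reproduce the closed-form values with 1/(2N) correction", {
  s <- sdt_indices(17, 20, 1, 20)
  expect_equal(s$dprime, 2.681287, tolerance = 1e-6)
  expect_equal(s$criterion, 0.3042101, tolerance = 1e-6)
  # equal rates: d' = 0, c = -z(0.85)
  s0 <- sdt_indices(17, 20, 17, 20)
  expect_equal(s0$dprime, 0)
  expect_equal(s0$criterion, -stats::qnorm(0.85), tolerance = 1e-9)
  # perfect observer corrected to 0.975 / 0.025
  sp <- sdt_indices(20, 20, 0, 20)
  expect_equal(sp$hit_rate, 0.975)
  expect_equal(sp$fa_rate, 0.025)
  expect_equal(sp$dprime, 2 * stats::qnorm(0.975), tolerance = 1e-9)
  expect_equal(sp$dprime, 3.919928, tolerance = 1e-6)
  expect_equal(sp$criterion, 0)
  expect_error(sdt_indices(1, 0, 0, 10), ">= 1")
  expect_error(sdt_indices(5, 4, 0, 10), "counts")
})

test_that("d' and c transform correctly under swapping signal and noise roles", {
  grid <- expand.grid(h = c(1, 5, 12, 19), f = c(0, 2, 9, 20))
  for (i in seq_len(nrow(grid))) {
    a <- sdt_indices(grid$h[i], 20, grid$f[i], 20)
    # exchanging the two count pairs negates d' and preserves c
    b <- sdt_indices(grid$f[i], 20, grid$h[i], 20)
    expect_equal(a$dprime, -b$dprime, tolerance = 1e-12)
    expect_equal(a$criterion, b$criterion, tolerance = 1e-12)
    # relabelling responses (yes <-> no) preserves d' and negates c
    d <- sdt_indices(20 - grid$f[i], 20, 20 - grid$h[i], 20)
    expect_equal(a$dprime, d$dprime, tolerance = 1e-12)
    expect_equal(a$criterion, -d$criterion, tolerance = 1e-12)
  }
})

test_that("paired t matches the closed form and its symmetries", {
  r <- paired_ttest(1:5, rep(0, 5))
  expect_equal(r$t, 4.242641, tolerance = 1e-6)
  expect_equal(r$df, 4)
  r2 <- paired_ttest(rep(0, 5), 1:5)
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
  expect_error(paired_ttest(1:5, 1:5), "degenerate")
  expect_error(paired_ttest(1:4, 1:5), "matched")
})

test_that("one-way RM ANOVA agrees with the balanced means/SS oracle", {
  for (seed in 1:30) {
    d <- random_rm_layout(seed, n_factors = 1)
    fit <- rm_anova(d, dv = "y", within = "A")
    orc <- rm_oracle_oneway(d)
    expect_equal(get_ss(fit, "A"), unname(orc$ss["A"]), tolerance = 1e-8)
    expect_equal(get_ss(fit, "Residuals(subject)"), unname(orc$ss["S"]),
                 tolerance = 1e-8)
    expect_equal(get_ss(fit, "Residuals(subject:A)"), unname(orc$ss["AS"]),
                 tolerance = 1e-8)
    expect_equal(fit$f[fit$effect == "A"], unname(orc$f["A"]),
                 tolerance = 1e-8)
    expect_equal(sum(fit$ss), unname(orc$ss["total"]), tolerance = 1e-6)
  }
})

test_that("two-way RM ANOVA agrees with the balanced means/SS oracle", {
  for (seed in 31:60) {
    d <- random_rm_layout(seed, n_factors = 2)
    fit <- rm_anova(d, dv = "y", within = c("A", "B"))
    orc <- rm_oracle_twoway(d)
    expect_equal(get_ss(fit, "A"), unname(orc$ss["A"]), tolerance = 1e-8)
    expect_equal(get_ss(fit, "B"), unname(orc$ss["B"]), tolerance = 1e-8)
    expect_equal(get_ss(fit, "A:B"), unname(orc$ss["AB"]), tolerance = 1e-8)
    expect_equal(fit$f[fit$effect == "A"], unname(orc$f["A"]), tolerance = 1e-8)
    expect_equal(fit$f[fit$effect == "B"], unname(orc$f["B"]), tolerance = 1e-8)
    expect_equal(fit$f[fit$effect == "A:B"], unname(orc$f["AB"]),
                 tolerance = 1e-8)
    expect_equal(sum(fit$ss), unname(orc$ss["total"]), tolerance = 1e-6)
  }
})

test_that("F equals t squared on two-level one-way layouts", {
  for (seed in 61:70) {
    withr::with_seed(seed, {
      x <- rnorm(6); y <- rnorm(6)
    })
    d <- data.frame(participant = rep(paste0("s", 1:6), 2),
                    A = rep(c("a1", "a2"), each = 6), y = c(x, y))
    fit <- rm_anova(d, dv = "y", within = "A")
    tt <- paired_ttest(x, y)
    expect_equal(fit$f[fit$effect == "A"], tt$t^2, tolerance = 1e-9)
    expect_equal(fit$p[fit$effect == "A"], tt$p, tolerance = 1e-9)
  }
})

test_that("incomplete layouts and degenerate inputs are rejected", {
  d <- random_rm_layout(1, n_factors = 1)
  expect_error(rm_anova(d[-1, ], dv = "y", within = "A"), "incomplete|unbalanced")
  d$y[1] <- NA
  expect_error(rm_anova(d, dv = "y", within = "A"), "missing")
  one <- d[d$participant == "s1", ]
  expect_error(rm_anova(one, dv = "y", within = "A"), "participants")
})

test_that("condition summaries have the Table schema and sensible cells", {
  # single participant, all hits with constant latency
  design <- data.frame(trial_id = 1:6, cue_condition = rep(c("valid", "neutral",
                                                             "invalid"), 2),
                       cued_stream = c("A", "none", "B", "A", "none", "B"),
                       target_stream = "A", target_onset_s = 2.0)
  responses <- data.frame(trial_id = 1:6, responded = TRUE,
                          response_time_s = 2.8, premature = FALSE)
  s <- summarize_experiment(design, responses, "by_condition")
  expect_equal(nrow(s$table), 3)
  expect_true(all(s$table$accuracy_mean == 100))
  expect_true(all(abs(s$table$rt_ms_mean - 800) < 1e-9))
  expect_true(all(is.na(s$table$accuracy_sem)))
  # exp1 grouping: 3 x 2 cells
  sim <- sim_participant(1)
  s2 <- summarize_experiment(sim$design, sim$responses)
  expect_equal(nrow(s2$table), 6)
  expect_setequal(unique(s2$table$target_stream), c("A", "B"))
  expect_true(all(s2$table$accuracy_mean >= 0 & s2$table$accuracy_mean <= 100))
  expect_true(all(s2$table$rt_ms_mean > 0))
})

test_that("a simulated cohort reproduces the qualitative attention orderings", {
  ds <- list(); rs <- list()
  for (p in 1:10) {
    sim <- sim_participant(700 + p)
    ds[[p]] <- sim$design; rs[[p]] <- sim$responses
  }
  t <- summarize_experiment(ds, rs)$table
  g <- function(meas, cond, st) t[[paste0(meas, "_mean")]][
    t$cue_condition == cond & t$target_stream == st]
  for (st in c("A", "B")) {
    expect_gt(g("accuracy", "valid", st), g("accuracy", "neutral", st))
    expect_gt(g("accuracy", "neutral", st), g("accuracy", "invalid", st))
    expect_gt(g("dprime", "valid", st), g("dprime", "invalid", st))
  }
})
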