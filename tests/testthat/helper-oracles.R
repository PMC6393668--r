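# Shared fixtures and independent oracles, built in code at test time.

# Pure tone as an audio_segment.
sine_segment <- function(freq = 440, dur = 1, rate = 44100, amp = 1) {
  t <- seq_len(round(dur * rate)) / rate
  audio_segment(amp * sin(2 * pi * freq * t), rate)
}

# Amplitude-modulated tone with a known modulator; returns signal + truth.
am_tone <- function(modulator, carrier_freq = 1000, rate = 44100) {
  t <- seq_along(modulator) / rate
  audio_segment(modulator * sin(2 * pi * carrier_freq * t), rate)
}

# Coarse modulation spectrum: rectify, average into 20-ms frames, FFT.
# Returns the peak frequency and centroid of the spectrum in `band` Hz.
modulation_spectrum <- function(x, band = c(0.5, 20)) {
  env <- abs(x$samples)
  w <- round(0.02 * x$rate)
  k <- floor(length(env) / w)
  env <- colMeans(matrix(env[seq_len(k * w)], nrow = w))
  env <- env - mean(env)
  sp <- Mod(stats::fft(env))^2
  fr <- (seq_along(sp) - 1) * (x$rate / w) / length(sp)
  sel <- fr > band[1] & fr < band[2]
  list(peak = fr[sel][which.max(sp[sel])],
       centroid = sum(fr[sel] * sp[sel]) / sum(sp[sel]))
}

# Brute-force check of the min-separation property of a peak set.
gaps_ok <- function(idx, min_sep) {
  length(idx) < 2 || all(diff(sort(idx)) >= min_sep)
}

# Self-similarity localization oracle (independent re-derivation is the
# package's internal scan; criterion tests use it on known constructions).
lag_scan <- function(x, lag, window = 4410) {
  scenecue:::.lag_scan(x, lag, window)
}

# ---- repeated-measures ANOVA oracle: balanced means/SS decomposition ----
# Long data with columns participant, A (, B), y; classical textbook sums
# of squares, independent of stats::aov.

rm_oracle_oneway <- function(data) {
  y <- data$y
  gm <- mean(y)
  ya <- tapply(y, data$A, mean)
  ys <- tapply(y, data$participant, mean)
  a <- length(ya); s <- length(ys)
  ss_a <- s * sum((ya - gm)^2)
  ss_s <- a * sum((ys - gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_as <- ss_tot - ss_a - ss_s
  f <- (ss_a / (a - 1)) / (ss_as / ((a - 1) * (s - 1)))
  list(ss = c(A = ss_a, S = ss_s, AS = ss_as, total = ss_tot),
       f = c(A = f),
       df = c(A = a - 1, AS = (a - 1) * (s - 1)))
}

rm_oracle_twoway <- function(data) {
  y <- data$y
  gm <- mean(y)
  ya <- tapply(y, data$A, mean); yb <- tapply(y, data$B, mean)
  ys <- tapply(y, data$participant, mean)
  a <- length(ya); b <- length(yb); s <- length(ys)
  yab <- tapply(y, list(data$A, data$B), mean)
  yas <- tapply(y, list(data$A, data$participant), mean)
  ybs <- tapply(y, list(data$B, data$participant), mean)
  ss_a <- b * s * sum((ya - gm)^2)
  ss_b <- a * s * sum((yb - gm)^2)
  ss_s <- a * b * sum((ys - gm)^2)
  ss_ab <- s * sum((sweep(sweep(yab, 1, ya), 2, yb) + gm)^2)
  ss_as <- b * sum((sweep(sweep(yas, 1, ya), 2, ys) + gm)^2)
  ss_bs <- a * sum((sweep(sweep(ybs, 1, yb), 2, ys) + gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_s - ss_ab - ss_as - ss_bs
  f_a <- (ss_a / (a - 1)) / (ss_as / ((a - 1) * (s - 1)))
  f_b <- (ss_b / (b - 1)) / (ss_bs / ((b - 1) * (s - 1)))
  f_ab <- (ss_ab / ((a - 1) * (b - 1))) /
    (ss_abs / ((a - 1) * (b - 1) * (s - 1)))
  list(ss = c(A = ss_a, B = ss_b, S = ss_s, AB = ss_ab, AS = ss_as,
              BS = ss_bs, ABS = ss_abs, total = ss_tot),
       f = c(A = f_a, B = f_b, AB = f_ab))
}

random_rm_layout <- function(seed, n_factors = 1) {
  withr::with_seed(seed, {
    s <- sample(3:6, 1)
    a <- sample(2:3, 1)
    b <- if (n_factors == 2) sample(2:3, 1) else 1
    grid <- expand.grid(participant = paste0("s", seq_len(s)),
                        A = paste0("a", seq_len(a)),
                        B = paste0("b", seq_len(b)),
                        stringsAsFactors = FALSE)
    grid$y <- rnorm(nrow(grid))
  })
  grid
}

# Extract one SS value from an anova_rm result by effect name.
get_ss <- function(fit, effect) fit$ss[fit$effect == effect]

# Simulated single-participant dataset with the default exp1 setup.
sim_participant <- function(seed, design_cfg = exp1_design_config(seed),
                            params = observer_preset("exp1", seed + 1L)) {
  d <- generate_design(design_cfg)
  list(design = d, responses = simulate_observer(d, params))
}
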