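test_that("PPG band-pass removes DC, keeps the pulse band, cuts 8 Hz", {
  fs <- 64
  rec_dc <- recording(matrix(5, 120 * fs, 1), "PPG", fs = fs, units = "au")
  out <- suppressWarnings(preprocess_ppg(rec_dc))
  expect_lt(max(abs(rec_matrix(out)[500:7000, 1])), 0.05)
  r12 <- preprocess_ppg(sine_rec(1.2, fs = fs, dur = 120, channels = "PPG",
                                 units = "au"))
  expect_equal(rms(rec_matrix(r12)[2000:6000, 1]), 1 / sqrt(2),
               tolerance = 0.05)
  r8 <- preprocess_ppg(sine_rec(8, fs = fs, dur = 120, channels = "PPG",
                                units = "au"))
  expect_lte(rms(rec_matrix(r8)[2000:6000, 1]), 0.1 / sqrt(2))
  rz <- preprocess_ppg(recording(matrix(0, 64 * 60, 1), "PPG", fs = 64,
                                 units = "au"))
  expect_true(all(rec_matrix(rz) == 0))
})

test_that("AMPD finds every pulse of a clean 70 bpm recording", {
  cfg <- sim_config(seed = 41, mean_hr = 70, lf_amp = 0, hf_amp = 0)
  sim <- simulate_ppg(cfg, duration = 300, seed = 41)
  beats <- detect_beats(preprocess_ppg(sim$recording))
  expect_equal(length(beats), nrow(sim$beats))
  err <- vapply(sim$beats$beat_time_s,
                function(t) min(abs(beats - t)), numeric(1))
  expect_lte(max(err), 1 / 64 + 1e-9) # within one sample
})

test_that("AMPD on a pure 1 Hz sinusoid finds one peak per cycle", {
  rec <- sine_rec(1, fs = 64, dur = 30, channels = "PPG", units = "au")
  beats <- detect_beats(rec)
  expect_gte(length(beats), 29)
  expect_lte(length(beats), 31)
})

test_that("flat PPG yields no beats with a warning", {
  rec <- recording(matrix(0, 64 * 30, 1), "PPG", fs = 64, units = "au")
  expect_warning(beats <- detect_beats(rec), "No beat")
  expect_equal(length(beats), 0)
})

test_that("IBI outlier correction flags and repairs ectopic intervals", {
  # constant 800 ms with one 1400 ms ectopic
  t <- cumsum(c(0, rep(0.8, 20)))
  t[12:21] <- t[12:21] + 0.6
  ibi <- ibi_series(t)
  out <- correct_ibi(ibi)
  expect_true(out$corrected[11])
  expect_equal(sum(out$corrected), 1)
  expect_equal(out$ibi_ms[11], 800, tolerance = 1)
  # constant series: identity (moving average of a constant is constant)
  ibi2 <- ibi_series(cumsum(c(0, rep(0.8, 20))))
  out2 <- correct_ibi(ibi2)
  expect_equal(out2$ibi_ms, ibi2$ibi_ms)
  expect_equal(out2$ibi_smooth_ms, ibi2$ibi_ms)
  expect_false(any(out2$corrected))
  expect_error(correct_ibi(ibi_series(cumsum(c(0, rep(0.8, 5))))), "10")
})

test_that("5% ectopic beats are flagged by the 2 SD rule", {
  cfg <- sim_config(seed = 42, ectopic_rate = 0.05)
  sim <- simulate_ppg(cfg, duration = 600, seed = 42)
  beats <- detect_beats(preprocess_ppg(sim$recording))
  out <- correct_ibi(ibi_series(beats))
  truth_t <- sim$ibi$t_s[sim$ibi$ectopic]
  flagged_t <- out$t_s[out$corrected]
  hit <- vapply(truth_t, function(t) any(abs(flagged_t - t) < 0.1), logical(1))
  expect_gte(mean(hit), 0.9)
  fp <- vapply(flagged_t, function(t) min(abs(truth_t - t)) > 0.1, logical(1))
  expect_lt(sum(fp) / sum(!sim$ibi$ectopic), 0.05)
})

test_that("heart rate follows 60000/mean(IBI) per window", {
  t <- seq(0, 120, by = 60000 / 70 / 1000)
  hr <- heart_rate(ibi_series(t))
  expect_equal(hr$hr_bpm[1], 70, tolerance = 1e-6)
  # window with < 3 beats is missing
  hr2 <- heart_rate(ibi_series(c(0, 0.8, 1.6, 2.4)),
                    windows = tibble::tibble(t_start_s = c(0, 60),
                                             t_end_s = c(60, 120)))
  expect_true(is.na(hr2$hr_bpm[2]))
})

test_that("generated mean heart rate is recovered within 1 bpm", {
  cfg <- sim_config(seed = 43, mean_hr = 62)
  sim <- simulate_ppg(cfg, duration = 300, seed = 43)
  beats <- detect_beats(preprocess_ppg(sim$recording))
  hr <- heart_rate(correct_ibi(ibi_series(beats)))
  expect_equal(mean(hr$hr_bpm, na.rm = TRUE), 62, tolerance = 1)
})

test_that("HR is invariant to PPG amplitude scaling (property)", {
  cfg <- sim_config(seed = 44)
  sim <- simulate_ppg(cfg, duration = 180, seed = 44)
  b1 <- detect_beats(preprocess_ppg(sim$recording))
  scaled <- rec_update(sim$recording, 7 * rec_matrix(sim$recording))
  b2 <- detect_beats(preprocess_ppg(scaled))
  expect_equal(b1, b2)
})

test_that("an LF-only modulation drives the spectral ratio far above 1", {
  t <- cumsum(c(0, rep(0.85, 350)))
  ibi <- ibi_series(t)
  ibi$ibi_ms <- ibi$ibi_ms + 30 * sin(2 * pi * 0.1 * ibi$t_s)
  hv <- hrv_spectral(ibi, windows = tibble::tibble(t_start_s = 0,
                                                   t_end_s = 300))
  expect_gt(hv$lf, hv$hf)
  expect_gt(hv$hrv, 10)
})

test_that("band fractions are normalized: lf + hf <= 1 (property)", {
  set.seed(45)
  for (i in 1:5) {
    t <- cumsum(c(0, runif(120, 0.7, 1.0)))
    ibi <- ibi_series(t)
    ibi$ibi_ms <- ibi$ibi_ms + rnorm(length(ibi$ibi_ms), sd = 20)
    hv <- hrv_spectral(ibi, windows = tibble::tibble(t_start_s = 0,
                                                     t_end_s = max(t)))
    expect_lte(hv$lf + hv$hf, 1)
    expect_gte(hv$lf, 0)
    expect_gte(hv$hf, 0)
  }
})

test_that("Lomb-Scargle matches the classical periodogram on even sampling", {
  set.seed(46)
  fs <- 1 # one "beat" per second
  n <- 300
  t <- seq_len(n) / fs
  y <- 850 + 25 * sin(2 * pi * 0.1 * t) + 12 * sin(2 * pi * 0.25 * t) +
    rnorm(n, sd = 5)
  freq <- seq(1 / n, 0.5 - 1 / n, by = 1 / n) # Fourier grid, interior
  pg_lomb <- lomb_periodogram(t, y, freq)
  # classical periodogram at the same Fourier frequencies
  Y <- fft(y - mean(y))
  p_classic <- (Mod(Y)^2 / n)[seq_along(freq) + 1]
  band <- function(p, lo, hi) sum(p[freq >= lo & freq < hi]) / sum(p)
  for (b in list(c(0.04, 0.15), c(0.15, 0.4))) {
    expect_equal(band(pg_lomb$power, b[1], b[2]),
                 band(p_classic, b[1], b[2]), tolerance = 0.05)
  }
})
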