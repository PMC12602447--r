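# Builds an fl_gfp tibble directly (epoch starts at integer seconds).
make_gfp <- function(values, t0 = 0) {
  structure(
    tibble::tibble(epoch = seq_along(values),
                   t_start_s = t0 + seq_along(values) - 1,
                   gfp = values),
    channels = c("Pz", "P3", "P4"), band = c(9, 11), epoch_len = 1,
    class = c("fl_gfp", class(tibble::tibble())))
}

test_that("IAF estimation recovers the generated alpha peak", {
  cfg <- sim_config(seed = 21, iaf = 10, noise_1f_scale = 0)
  expect_equal(estimate_iaf(simulate_rest_ec(cfg, seed = 21))$iaf, 10,
               tolerance = 0.125 + 1e-9)
  cfg2 <- sim_config(seed = 22, iaf = 11.5, noise_1f_scale = 10)
  expect_equal(estimate_iaf(simulate_rest_ec(cfg2, seed = 22))$iaf, 11.5,
               tolerance = 0.5)
})

test_that("white noise yields a 'no distinct peak' flag", {
  set.seed(23)
  rec <- recording(matrix(rnorm(60 * 125 * 3), ncol = 3),
                   c("Pz", "P3", "P4"), fs = 125)
  expect_warning(spec <- estimate_iaf(rec), "No distinct")
  expect_true(spec$no_distinct_peak)
})

test_that("alpha GFP scales with amplitude squared and averages channels", {
  spec <- structure(list(iaf = 10, band_lo = 9, band_hi = 11,
                         no_distinct_peak = FALSE), class = "fl_alpha_spec")
  recA <- sine_rec(10, dur = 20, amp = 2, channels = c("Pz", "P3", "P4"))
  rec2A <- sine_rec(10, dur = 20, amp = 4, channels = c("Pz", "P3", "P4"))
  gA <- alpha_gfp(recA, epoch_reject(recA), spec)
  g2A <- alpha_gfp(rec2A, epoch_reject(rec2A), spec)
  expect_equal(g2A$gfp / gA$gfp, rep(4, nrow(gA)), tolerance = 1e-9)
  # identical signal on all three parietal channels = single-channel power
  g1 <- alpha_gfp(recA, epoch_reject(recA), spec, channels = "Pz")
  expect_equal(gA$gfp, g1$gfp, tolerance = 1e-12)
  # missing parietal channel is named
  expect_error(alpha_gfp(sine_rec(10), epoch_reject(sine_rec(10)), spec,
                         channels = c("Pz", "P3")), "P3")
})

test_that("a x2 amplitude step in the fatigue envelope quadruples GFP", {
  cfg <- sim_config(seed = 24, noise_1f_scale = 0, blink_rate = 0,
                    alpha_task_base_amp = 5)
  sch <- short_schedule()
  # bump with tiny width ~ step-like contrast between the two segments
  traj <- fatigue_trajectory(sch, 2, base = 1, a_max = 2, width_s = 30)
  sim <- simulate_eeg(cfg, traj, sch, seed = 24)
  rec <- sim$recording
  spec <- structure(list(iaf = 10, band_lo = 9, band_hi = 11,
                         no_distinct_peak = FALSE), class = "fl_alpha_spec")
  gfp <- alpha_gfp(rec, epoch_reject(rec), spec)
  g_seg1 <- mean(gfp$gfp[gfp$t_start_s >= 60 & gfp$t_start_s < 120])
  g_seg2 <- mean(gfp$gfp[gfp$t_start_s >= 425 & gfp$t_start_s < 435])
  expect_equal(g_seg2 / g_seg1, 4, tolerance = 0.1)
})

test_that("MDrow equals 1 when task GFP matches the rest maximum", {
  task <- make_gfp(rep(7.5, 300))
  rest <- make_gfp(c(rep(5, 59), 7.5))
  md <- compute_mdrow(task, rest)
  expect_true(all(md$mdrow == 1))
  expect_equal(attr(md, "rest_denominator"), 7.5)
})

test_that("half the alpha amplitude gives MDrow about 0.25", {
  cfg_t <- sim_config(seed = 25, noise_1f_scale = 0, blink_rate = 0,
                      alpha_task_base_amp = 10, alpha_rest_amp = 20)
  sch <- short_schedule()
  traj <- fatigue_trajectory(sch, 1, base = 1, a_max = 1)
  sim <- simulate_eeg(cfg_t, traj, sch, seed = 25)
  rest <- simulate_rest_ec(cfg_t, seed = 26)
  spec <- estimate_iaf(rest)
  task_gfp <- alpha_gfp(sim$recording, epoch_reject(sim$recording), spec)
  rest_gfp <- alpha_gfp(rest, epoch_reject(rest), spec)
  md <- compute_mdrow(task_gfp, rest_gfp)
  expect_equal(mean(md$mdrow), 0.25, tolerance = 0.02)
})

test_that("window arithmetic yields 177 windows for a 45-min task", {
  task <- make_gfp(rep(1, 2700))
  md <- compute_mdrow(task, make_gfp(rep(1, 60)))
  expect_equal(nrow(md), floor((2700 - 60) / 15) + 1)
  expect_equal(nrow(md), 177)
})

test_that("windows with too few retained epochs are missing", {
  vals <- rep(1, 300)
  task <- make_gfp(vals)
  # drop most epochs of the second minute
  task <- task[!(task$t_start_s >= 60 & task$t_start_s < 100), ]
  md <- compute_mdrow(task, make_gfp(rep(1, 60)))
  expect_true(any(is.na(md$mdrow)))
  expect_false(is.na(md$mdrow[1]))
})

test_that("MDrow errors on empty or zero rest", {
  task <- make_gfp(rep(1, 120))
  expect_error(compute_mdrow(task, make_gfp(numeric())), "Empty")
  expect_error(compute_mdrow(task, make_gfp(rep(0, 60))), "zero")
})

test_that("MDrow is invariant to global rescaling and monotone in alpha", {
  task <- make_gfp(seq(1, 3, length.out = 300))
  rest <- make_gfp(rep(4, 60))
  md1 <- compute_mdrow(task, rest)
  task10 <- make_gfp(10 * task$gfp)
  rest10 <- make_gfp(10 * rest$gfp)
  md10 <- compute_mdrow(task10, rest10)
  expect_equal(md1$mdrow, md10$mdrow, tolerance = 1e-12)
  expect_true(all(diff(md1$mdrow) > 0))
})

test_that("a rising fatigue envelope yields a rising MDrow series", {
  cfg <- sim_config(seed = 27, alpha_task_base_amp = 4, noise_1f_scale = 10)
  sch <- short_schedule()
  traj <- fatigue_trajectory(sch, 2, shape = "ramp")
  sim <- simulate_eeg(cfg, traj, sch, seed = 27)
  rest <- simulate_rest_ec(cfg, seed = 28)
  spec <- estimate_iaf(rest)
  grid <- flag_blink_epochs(epoch_reject(sim$recording), sim$blinks)
  md <- compute_mdrow(alpha_gfp(sim$recording, grid, spec),
                      alpha_gfp(rest, epoch_reject(rest), spec))
  ok <- !is.na(md$mdrow)
  rho <- stats::cor(md$window_start_s[ok], md$mdrow[ok], method = "spearman")
  expect_gt(rho, 0.8)
})
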