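# Synthetic-study generator: parameter validation, forced-parameter cases,
# determinism, and the statistical structure of the injected shifts.

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(study_config(n_participants = 1), "n_participants")
  expect_error(study_config(p_shift_in_window = 1.3), "p_shift_in_window")
  expect_error(study_config(alpha_modulation_depth = 1), "alpha_modulation_depth")
  expect_error(study_config(sampling_rate = 0), "sampling_rate")
  expect_error(study_config(latency_distribution = list(
    mean = 400, sd = 50, support = c(-2000, 600))), "latency_distribution")
})

test_that("extreme shift probabilities force the ground truth", {
  st0 <- generate_study(small_config(p_shift_in_window = 0, seed = 4))
  inw <- st0$ground_truth$onset_ms >= 200 & st0$ground_truth$onset_ms <= 600
  expect_false(any(inw))

  st1 <- generate_study(small_config(p_shift_in_window = 1,
                                     p_toward_given_shift = 1, seed = 4))
  gt <- st1$ground_truth[st1$ground_truth$in_window, ]
  first <- do.call(rbind, lapply(
    split(gt, interaction(gt$participant, gt$trial, drop = TRUE)),
    function(d) d[which.min(d$onset_ms), ]))
  expect_true(all(first$direction == "toward"))
  # every trial has an in-window shift
  expect_equal(nrow(unique(first[c("participant", "trial")])),
               3 * 12)
})

test_that("generation is deterministic given the seed", {
  a <- generate_study(small_config(seed = 99))
  b <- generate_study(small_config(seed = 99))
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$participants[[2]]$trials[[3]],
                   b$participants[[2]]$trials[[3]])
  c <- generate_study(small_config(seed = 100))
  expect_false(identical(a$ground_truth, c$ground_truth))
})

test_that("cued sides are balanced within participant", {
  st <- generate_study(small_config(seed = 21))
  for (p in st$participants)
    expect_equal(as.vector(table(p$meta$cued_side)[c("left", "right")]),
                 c(6L, 6L))
})

test_that("gaze trials realize the planned displacements", {
  t <- seq(-200, 800)
  plan <- data.frame(onset_ms = 300, magnitude_pct = 10)
  set.seed(1)
  g <- generate_gaze_trial(t, plan, drift_noise_sd = 0, eye_noise_sd = 0,
                           blink_rate = 0)
  # convert back from raw units: pct = (raw - centre) / gain / ecc * 100
  pct <- (g$lx - 512) / 35 / 5.7 * 100
  expect_equal(pct[t < 300], rep(0, sum(t < 300)), tolerance = 1e-10)
  expect_equal(pct[t >= 320], rep(10, sum(t >= 320)), tolerance = 1e-10)

  g0 <- generate_gaze_trial(t, drift_noise_sd = 0, eye_noise_sd = 0,
                            blink_rate = 0)
  expect_true(all(abs(g0$rx - 512) < 1e-10))

  plan2 <- data.frame(onset_ms = c(250, 500), magnitude_pct = c(5, -5))
  g2 <- generate_gaze_trial(t, plan2, drift_noise_sd = 0, eye_noise_sd = 0,
                            blink_rate = 0)
  pct2 <- (g2$lx - 512) / 35 / 5.7 * 100
  expect_equal(pct2[length(pct2)], 0, tolerance = 1e-10)
})

test_that("invalid shift plans raise plan errors", {
  t <- seq(-200, 800)
  expect_error(generate_gaze_trial(
    t, data.frame(onset_ms = c(300, 350), magnitude_pct = c(5, 5))),
    "plan error")
  expect_error(generate_gaze_trial(
    t, data.frame(onset_ms = 300, magnitude_pct = 0.5)),
    "plan error")
})

test_that("alpha generator honours depth and onset", {
  tt <- seq(-1000, 2000)
  # depth 0: expected lateralization ~ 0 at all times
  set.seed(8)
  tcs <- replicate(30, {
    s <- generate_alpha_signals(tt, 400, depth = 0, noise_sd = 0.5)
    list(eeg_contra = s$contra, eeg_ipsi = s$ipsi, time_ms = tt)
  }, simplify = FALSE)
  tc <- condition_alpha_timecourse(tcs, freqs_hz = 8:12)
  expect_lt(max(abs(tc$lateralization_pct)), 10)

  # onset at 400: half of the plateau is reached near 400 + ramp midpoint
  s <- generate_alpha_signals(tt, 400, depth = 0.5, noise_sd = 0,
                              ramp_ms = 100)
  tc1 <- condition_alpha_timecourse(
    list(list(eeg_contra = s$contra, eeg_ipsi = s$ipsi, time_ms = tt)),
    freqs_hz = 8:12, step_ms = 1)
  plateau <- mean(tc1$lateralization_pct[tc1$time_ms >= 800])
  cross <- half_peak_latency(tc1$lateralization_pct, tc1$time_ms,
                             window_ms = c(0, 1500))
  expect_equal(cross, 450, tolerance = 60)
  expect_equal(plateau, -60, tolerance = 1)

  expect_error(generate_alpha_signals(tt, 5000), "modulation_onset_ms")
})

test_that("calibration recordings have seven labelled nominal positions", {
  set.seed(2)
  cal <- generate_calibration(cal_noise_deg = 0)
  expect_equal(sort(cal$onsets$label), sort(cal$nominal$label))
  expect_equal(nrow(cal$onsets), 7L)
  # zero noise: median gaze in each segment equals the nominal position
  for (lab in cal$nominal$label) {
    nom <- cal$nominal[cal$nominal$label == lab, ]
    s <- cal$samples[cal$samples$label == lab, ]
    expect_equal(median(s$lx), 512 + 35 * nom$x_deg)
    expect_equal(median(s$ry), 384 + 35 * nom$y_deg)
  }
  # different seeds: same nominal grid, different noise
  set.seed(3); a <- generate_calibration(cal_noise_deg = 0.1)
  set.seed(4); b <- generate_calibration(cal_noise_deg = 0.1)
  expect_identical(a$nominal, b$nominal)
  expect_false(identical(a$samples$lx, b$samples$lx))
})

test_that("first-shift direction bias matches the configured probability", {
  st <- generate_study(small_config(n_participants = 4, n_trials = 120,
                                    blink_rate = 0, seed = 17))
  gt <- st$ground_truth[st$ground_truth$in_window, ]
  first <- do.call(rbind, lapply(
    split(gt, interaction(gt$participant, gt$trial, drop = TRUE)),
    function(d) d[which.min(d$onset_ms), ]))
  n <- nrow(first)
  phat <- mean(first$direction == "toward")
  ci <- 2 / 3 + c(-1, 1) * qnorm(0.995) * sqrt(2 / 3 * 1 / 3 / n)
  expect_gt(phat, ci[1])
  expect_lt(phat, ci[2])
})

test_that("study round-trips through the CSV/JSON layout", {
  st <- generate_study(small_config(n_participants = 2, n_trials = 3,
                                    seed = 5))
  dir <- tempfile("study")
  write_study(st, dir)
  back <- read_study(dir)
  expect_equal(back$config$n_trials, st$config$n_trials)
  expect_equal(back$ground_truth$onset_ms, st$ground_truth$onset_ms)
  tr_a <- st$participants[[2]]$trials[[2]]
  tr_b <- back$participants[[2]]$trials[[2]]
  expect_equal(tr_b$lx, tr_a$lx)
  expect_equal(tr_b$eeg_contra, tr_a$eeg_contra)
  expect_equal(tr_b$cued_side, tr_a$cued_side)
  unlink(dir, recursive = TRUE)
})
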