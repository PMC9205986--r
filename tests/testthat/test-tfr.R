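# Short-time Fourier power and the lateralization contrast.

test_that("STFT power localizes a pure sinusoid at its frequency", {
  t <- seq(-1000, 2000)
  x <- 3 * sin(2 * pi * 10 * t / 1000 + 0.7)
  p <- stft_power(x, t)
  peak_freq <- p$freq_hz[apply(p$power, 1, which.max)]
  expect_true(all(peak_freq == 10))
  # stable over time
  p10 <- p$power[, p$freq_hz == 10]
  expect_lt(diff(range(p10)) / mean(p10), 1e-6)

  # quadratic amplitude scaling
  p2 <- stft_power(2 * x, t)
  expect_equal(p2$power, 4 * p$power, tolerance = 1e-10)

  expect_error(stft_power(rnorm(100), seq_len(100)), "input error")
})

test_that("white noise has a flat expected spectrum", {
  set.seed(40)
  t <- seq(0, 3000)
  acc <- 0
  for (i in 1:30) acc <- acc + stft_power(rnorm(length(t)), t)$power
  mean_pow <- colMeans(acc / 30)
  lo <- mean(mean_pow[15:30])
  hi <- mean(mean_pow[31:46])
  expect_lt(abs(lo / hi - 1), 0.1)
})

test_that("latency-mode (1-ms hop) agrees with the 50-ms hop grid", {
  set.seed(41)
  t <- seq(-500, 1500)
  x <- sin(2 * pi * 10 * t / 1000) + rnorm(length(t), 0, 0.3)
  p50 <- stft_power(x, t, freqs_hz = 8:12, step_ms = 50)
  p1 <- stft_power(x, t, freqs_hz = 8:12, step_ms = 1)
  common <- match(p50$time_ms, p1$time_ms)
  expect_equal(p1$power[common, ], p50$power, tolerance = 1e-10)
})

test_that("lateralization contrast follows its closed forms and bounds", {
  expect_equal(lateralization_contrast(1, 1), 0)
  expect_equal(lateralization_contrast(0.5, 1), -100 / 3, tolerance = 1e-10)
  expect_equal(lateralization_contrast(0, 1), -100)

  # swap antisymmetry and boundedness on random positive arrays
  set.seed(42)
  for (i in 1:10) {
    a <- matrix(rexp(60), 10, 6)
    b <- matrix(rexp(60), 10, 6)
    L <- lateralization_contrast(a, b)
    expect_equal(lateralization_contrast(b, a), -L)
    expect_true(all(abs(L) <= 100))
  }

  # zero denominator flagged invalid
  expect_true(is.na(lateralization_contrast(0, 0)))
})

test_that("band averaging selects exactly the 8-12 Hz rows", {
  ctr <- structure(list(contrast = matrix(7, 5, 50), time_ms = 1:5,
                        freq_hz = 1:50), class = "tfr_contrast")
  tc <- band_timecourse(ctr)
  expect_true(all(tc$lateralization_pct == 7))

  ctr2 <- ctr
  ctr2$contrast[] <- 0
  ctr2$contrast[, ctr2$freq_hz == 20] <- 50
  expect_true(all(band_timecourse(ctr2)$lateralization_pct == 0))

  expect_error(band_timecourse(ctr, band_hz = c(60, 70)), "input error")
})

test_that("per-trial contrast averaging is available as an alternative", {
  set.seed(43)
  t <- seq(-500, 1500)
  trials <- lapply(1:4, function(i) {
    s <- generate_alpha_signals(t, 300, depth = 0.4, noise_sd = 0.2)
    list(eeg_contra = s$contra, eeg_ipsi = s$ipsi, time_ms = t)
  })
  tc_avg <- condition_alpha_timecourse(trials)
  tc_per <- condition_alpha_timecourse(trials, per_trial_contrast = TRUE)
  # both estimate the same modulation (same sign and similar plateau)
  late_avg <- mean(tc_avg$lateralization_pct[tc_avg$time_ms > 600])
  late_per <- mean(tc_per$lateralization_pct[tc_per$time_ms > 600])
  expect_lt(late_avg, -10)
  expect_lt(late_per, -10)
  expect_false(identical(tc_avg$lateralization_pct,
                         tc_per$lateralization_pct))
})
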