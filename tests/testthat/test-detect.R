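# Velocity-threshold detector: velocity computation, event extraction with
# refractory and magnitude rules, direction labels, and trial classification.

test_that("velocity of constant and linear traces behaves analytically", {
  t <- seq(-200, 800)
  v0 <- compute_velocity(make_epoch(rep(2, length(t)), t))
  expect_true(all(v0[is.finite(v0)] == 0))

  ramp <- 0.5 * (t - t[1])
  v1 <- compute_velocity(make_epoch(ramp, t))
  interior <- v1[10:(length(t) - 10)]
  expect_equal(interior, rep(0.5, length(interior)), tolerance = 1e-10)

  # a single-sample step's smoothed velocity pulse integrates to the step
  x <- rep(0, length(t)); x[t >= 300] <- 10
  v2 <- compute_velocity(make_epoch(x, t))
  expect_equal(sum(v2[is.finite(v2)]), 10, tolerance = 1e-8)

  expect_error(compute_velocity(rep(NaN, 100)), "empty-velocity")
})

test_that("an injected step is detected at its onset with its magnitude", {
  t <- seq(-500, 1500)
  x <- step_trace(t, 300, 5)
  ep <- make_epoch(x, t)
  ev <- detect_shifts(compute_velocity(ep), ep)
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$onset_ms - 300), 10)
  expect_lt(abs(ev$magnitude_pct - 5), 0.5)
})

test_that("the 100-ms refractory rule keeps only the first of close shifts", {
  t <- seq(-500, 1500)
  x <- step_trace(t, 300, 5) + step_trace(t, 350, 5)
  ep <- make_epoch(x, t)
  ev <- detect_shifts(compute_velocity(ep), ep)
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$onset_ms - 300), 10)
})

test_that("sub-floor displacements yield no events", {
  t <- seq(-500, 1500)
  x <- step_trace(t, 300, 0.5) + cumsum(rnorm(length(t), 0, 0.01))
  ep <- make_epoch(x, t)
  ev <- detect_shifts(compute_velocity(ep), ep)
  expect_equal(nrow(ev), 0L)
})

test_that("raising the threshold multiplier never adds candidate crossings", {
  # monotonicity holds at the thresholding stage: the supra-threshold set
  # shrinks as the multiplier grows, so threshold-crossing runs can only
  # disappear (final event counts can still change either way through the
  # refractory interaction with the magnitude floor)
  set.seed(14)
  for (i in 1:25) {
    tr <- random_trace()
    ep <- make_epoch(tr$x, tr$time_ms)
    v <- compute_velocity(ep)
    if (!any(is.finite(v))) next
    med <- median(v[is.finite(v)])
    counts <- sapply(c(2, 3, 5, 8), function(m) {
      supra <- is.finite(v) & v > m * med
      sum(supra & !c(FALSE, supra[-length(supra)]))
    })
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("detector matches the brute-force reference event-for-event", {
  set.seed(15)
  for (i in 1:40) {
    tr <- random_trace(n = sample(600:2000, 1))
    ep <- make_epoch(tr$x, tr$time_ms)
    v <- tryCatch(compute_velocity(ep), error = function(e) NULL)
    if (is.null(v) || !any(is.finite(v))) next
    ev <- detect_shifts(v, ep)
    ref <- oracle_detect(tr$x, tr$time_ms)
    expect_equal(nrow(ev), nrow(ref))
    if (nrow(ev) > 0) {
      expect_equal(ev$onset_ms, ref$onset_ms)
      expect_equal(ev$magnitude_pct, ref$magnitude_pct, tolerance = 1e-10)
    }
  }
})

test_that("direction labels follow the cued-side sign convention", {
  ev <- structure(data.frame(onset_ms = c(300, 400),
                             magnitude_pct = c(-5, 5),
                             peak_velocity = c(1, 1)),
                  class = c("gaze_shifts", "data.frame"))
  left <- label_direction(ev, "left")
  expect_equal(left$direction, c("toward", "away"))
  right <- label_direction(ev, "right")
  expect_equal(right$direction, c("away", "toward"))
  # flipping the cued side flips every label
  expect_true(all(left$direction != right$direction))
})

test_that("trial classification follows the first in-window shift", {
  mk <- function(onsets, dirs) {
    structure(data.frame(onset_ms = onsets,
                         magnitude_pct = ifelse(dirs == "toward", 5, -5),
                         peak_velocity = rep(1, length(onsets)),
                         direction = dirs),
              class = c("gaze_shifts", "data.frame"))
  }
  tc <- classify_trial(mk(c(300, 500), c("toward", "away")), TRUE)
  expect_equal(tc$class, "toward")
  expect_equal(tc$first_shift_latency_ms, 300)

  expect_equal(classify_trial(mk(150, "toward"), TRUE)$class, "none")
  expect_equal(classify_trial(mk(300, "away"), FALSE)$class, "unusable")
  expect_equal(classify_trial(mk(numeric(0), character(0)), TRUE)$class,
               "none")
  # window boundaries are inclusive
  expect_equal(classify_trial(mk(600, "away"), TRUE)$class, "away")
})

test_that("events near epoch edges are skipped with a logged reason", {
  t <- seq(0, 600)
  x <- step_trace(t, 30, 5)
  ep <- gaze_epoch(t, x, "right")
  ev <- detect_shifts(compute_velocity(ep), ep)
  expect_equal(nrow(ev), 0L)
  skipped <- attr(ev, "skipped")
  expect_gt(nrow(skipped), 0L)
  expect_match(skipped$reason[1], "window")
})
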