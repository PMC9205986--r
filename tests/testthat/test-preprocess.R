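# Pre-processing: eye averaging, blink masking, calibration normalization,
# and usability flagging.

test_that("merge_eyes averages samplewise and propagates NaN", {
  expect_equal(merge_eyes(3, 5), 4)
  expect_true(is.na(merge_eyes(NaN, 2)))
  x <- rnorm(10)
  expect_equal(merge_eyes(x, x), x)
  expect_error(merge_eyes(1:3, 1:4), "input error")
})

test_that("mask_blinks widens NaN runs by 100 ms and merges overlaps", {
  t <- 0:1000
  x <- rnorm(length(t))
  x[t >= 400 & t <= 450] <- NaN
  m <- mask_blinks(x)
  expect_true(all(is.na(m[t >= 300 & t <= 550])))
  expect_false(anyNA(m[t < 300]))
  expect_false(anyNA(m[t > 550]))

  # no NaNs: values unchanged (only the processed marker is added)
  y <- rnorm(100)
  expect_identical(as.vector(mask_blinks(y)), y)

  # overlapping extensions merge into one run (vs brute-force union)
  x2 <- rnorm(length(t))
  x2[t >= 300 & t <= 320] <- NaN
  x2[t >= 450 & t <= 470] <- NaN
  m2 <- mask_blinks(x2)
  expect_equal(is.na(m2), oracle_extend_nan(is.na(x2), 100))
  r <- rle(is.na(m2))
  expect_equal(sum(r$values), 1L)
})

test_that("mask_blinks is idempotent", {
  set.seed(10)
  for (i in 1:20) {
    x <- rnorm(500)
    k <- sample(0:3, 1)
    for (j in seq_len(k)) {
      s <- sample(400, 1)
      x[s:(s + sample(10:80, 1))] <- NaN
    }
    once <- mask_blinks(x)
    expect_identical(mask_blinks(once), once)
  }
})

test_that("calibration reference maps the task geometry exactly", {
  set.seed(6)
  cal <- generate_calibration(cal_noise_deg = 0)
  ref <- build_calibration_reference(cal)
  raw_item_right <- 512 + 35 * 5.7
  raw_item_left <- 512 - 35 * 5.7
  expect_equal(normalize_gaze(raw_item_right, ref), 100, tolerance = 1e-9)
  expect_equal(normalize_gaze(raw_item_left, ref), -100, tolerance = 1e-9)
  expect_equal(normalize_gaze(512, ref), 0, tolerance = 1e-9)
  # affine linearity: midpoint maps to 50%
  expect_equal(normalize_gaze((512 + raw_item_right) / 2, ref), 50,
               tolerance = 1e-9)
  # NaN preserved
  expect_true(is.na(normalize_gaze(NaN, ref)))
})

test_that("constant offsets are absorbed and medians are noise-robust", {
  set.seed(7)
  cal <- generate_calibration(cal_noise_deg = 0)
  cal$samples$lx <- cal$samples$lx + 40
  cal$samples$rx <- cal$samples$rx + 40
  ref <- build_calibration_reference(cal)
  expect_equal(normalize_gaze(512 + 40, ref), 0, tolerance = 1e-9)
  expect_equal(normalize_gaze(512 + 40 + 35 * 5.7, ref), 100,
               tolerance = 1e-9)

  # heavy-tailed noise in one segment: median stays near nominal where the
  # mean drifts off
  cal2 <- generate_calibration(cal_noise_deg = 0)
  sel <- cal2$samples$label == "right-middle"
  n_sel <- sum(sel)
  spikes <- rt(n_sel, df = 1) * 5
  cal2$samples$lx[sel] <- cal2$samples$lx[sel] + spikes
  cal2$samples$rx[sel] <- cal2$samples$rx[sel] + spikes
  ref2 <- build_calibration_reference(cal2)
  raw_right <- 512 + 35 * 5.7
  mean_based <- mean(cal2$samples$lx[sel])   # the non-robust alternative
  expect_lt(abs(normalize_gaze(raw_right, ref2) - 100), 5)
  expect_gt(abs(mean_based - raw_right), 1)
})

test_that("missing calibration positions raise calibration errors", {
  set.seed(8)
  cal <- generate_calibration()
  cal$onsets <- cal$onsets[cal$onsets$label != "centre", ]
  expect_error(build_calibration_reference(cal), "centre")
})

test_that("normalization round-trips to raw coordinates", {
  set.seed(9)
  cal <- generate_calibration(cal_noise_deg = 0.05)
  ref <- build_calibration_reference(cal)
  raw <- runif(200, 300, 700)
  expect_equal(denormalize_gaze(normalize_gaze(raw, ref), ref), raw,
               tolerance = 1e-10)
})

test_that("mark_usable applies the closed 0-600 ms NaN rule", {
  t <- seq(-500, 1500)
  x <- rnorm(length(t))
  expect_true(mark_usable(make_epoch(x, t)))

  x1 <- x; x1[t == 599] <- NaN
  expect_false(mark_usable(make_epoch(x1, t)))

  x2 <- x; x2[t == -200] <- NaN
  expect_true(mark_usable(make_epoch(x2, t)))

  expect_error(mark_usable(gaze_epoch(seq(0, 400), rnorm(401), "left")),
               "input error")
})

test_that("usability matches the blink-overlap predicate on synthetic data", {
  st <- generate_study(small_config(n_participants = 2, n_trials = 20,
                                    blink_rate = 1.2, seed = 33))
  for (p in 1:2) {
    pp <- st$participants[[p]]
    ref <- build_calibration_reference(pp$calibration)
    for (tr in seq_along(pp$trials)) {
      t <- pp$trials[[tr]]
      cyc <- mask_blinks(merge_eyes(t$lx, t$rx))
      ep <- gaze_epoch(t$time_ms, normalize_gaze(cyc, ref), t$cued_side)
      # ground-truth predicate: a blink extended by 100 ms overlaps [0, 600]
      overlap <- nrow(t$blinks) > 0 &&
        any(t$blinks$start_ms - 100 <= 600 & t$blinks$end_ms + 100 >= 0)
      expect_identical(mark_usable(ep), !overlap)
    }
  }
})

test_that("gaze CSV and EyeLink ASC readers parse the documented layouts", {
  d <- data.frame(time_ms = 1:5, lx = rnorm(5), ly = rnorm(5),
                  rx = rnorm(5), ry = rnorm(5))
  f <- tempfile(fileext = ".csv")
  write.csv(d, f, row.names = FALSE)
  expect_equal(read_gaze_csv(f), d)
  unlink(f)

  asc <- c("** some header", "MSG 100 trial_start",
           "1001\t512.3\t380.1\t900\t514.2\t382.0\t905\t.....",
           "1002\t.\t.\t0\t514.0\t381.9\t904\t.....",
           "ESACC R  1000 1002")
  fa <- tempfile(fileext = ".asc")
  writeLines(asc, fa)
  parsed <- parse_eyelink_asc(fa)
  expect_equal(nrow(parsed), 2L)
  expect_equal(parsed$lx, c(512.3, NaN))
  expect_equal(parsed$rx, c(514.2, 514.0))
  unlink(fa)
})
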