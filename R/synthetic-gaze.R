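# Gaze-trace generator: fixational drift + injected saccadic steps + blinks,
# rendered in raw tracker units per eye so that calibration-based
# normalization is exercised end to end.

# duration of an injected saccadic displacement, ms
SACCADE_DURATION_MS <- 20

# Minimum-jerk position profile on u in [0, 1]: smooth monotone step.
minimum_jerk <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  10 * u^3 - 15 * u^4 + 6 * u^5
}

#' Generate one raw binocular gaze trial
#'
#' Simulates an epoched binocular gaze recording: Gaussian random-walk
#' fixational drift, per-eye white measurement noise, planned saccadic
#' displacements rendered as minimum-jerk steps of 20 ms duration, and
#' blinks inserted as NaN stretches. Output is in raw tracker units
#' (`raw_center + raw_gain * degrees`), the coordinate frame the calibration
#' reference maps back to % units.
#'
#' @param time_ms Epoch time axis, ms, uniform at `sampling_rate`.
#' @param shift_plan Data frame with columns `onset_ms` and `magnitude_pct`
#'   (signed, % units); onsets must be separated by more than 100 ms and
#'   magnitudes at least 1% in absolute value.
#' @param drift_noise_sd,eye_noise_sd,blink_rate,blink_duration_ms,raw_center,raw_gain,item_eccentricity_deg
#'   Generative parameters, see [study_config()].
#' @param n_blinks Optional fixed number of blinks; default draws from
#'   Poisson(`blink_rate`).
#' @return List with `time_ms`, raw per-eye channels `lx, ly, rx, ry`,
#'   `truth` (the shift plan as injected), and `blinks` (the inserted blink
#'   intervals, ms).
#' @export
generate_gaze_trial <- function(time_ms,
                                shift_plan = data.frame(onset_ms = numeric(),
                                                        magnitude_pct = numeric()),
                                drift_noise_sd = 0.03,
                                eye_noise_sd = 0.1,
                                blink_rate = 0.2,
                                blink_duration_ms = c(100, 300),
                                raw_center = c(512, 384),
                                raw_gain = 35,
                                item_eccentricity_deg = 5.7,
                                n_blinks = NULL) {
  n <- length(time_ms)
  if (n < 2L) stop("time_ms must contain at least two samples")
  if (nrow(shift_plan) > 0L &&
      (any(!is.finite(shift_plan$onset_ms)) ||
       any(!is.finite(shift_plan$magnitude_pct))))
    stop("plan error: shift onsets and magnitudes must be finite")
  if (nrow(shift_plan) > 1L) {
    ons <- sort(shift_plan$onset_ms)
    if (any(diff(ons) <= 100))
      stop("plan error: planned shift onsets must be separated by > 100 ms")
  }
  if (nrow(shift_plan) > 0L && any(abs(shift_plan$magnitude_pct) < 1))
    stop("plan error: planned shift magnitudes must be >= 1%")

  # horizontal position in % units: drift + injected steps
  x_pct <- cumsum(stats::rnorm(n, 0, drift_noise_sd))
  y_pct <- cumsum(stats::rnorm(n, 0, drift_noise_sd))
  if (nrow(shift_plan) > 0L) {
    for (k in seq_len(nrow(shift_plan))) {
      u <- (time_ms - shift_plan$onset_ms[k]) / SACCADE_DURATION_MS
      x_pct <- x_pct + shift_plan$magnitude_pct[k] * minimum_jerk(u)
    }
  }

  pct2raw_x <- function(pct, noise_sd) {
    deg <- pct / 100 * item_eccentricity_deg
    raw_center[1] + raw_gain * (deg + stats::rnorm(n, 0, noise_sd / 100 *
                                                     item_eccentricity_deg))
  }
  pct2raw_y <- function(pct, noise_sd) {
    deg <- pct / 100 * item_eccentricity_deg
    raw_center[2] + raw_gain * (deg + stats::rnorm(n, 0, noise_sd / 100 *
                                                     item_eccentricity_deg))
  }
  lx <- pct2raw_x(x_pct, eye_noise_sd)
  rx <- pct2raw_x(x_pct, eye_noise_sd)
  ly <- pct2raw_y(y_pct, eye_noise_sd)
  ry <- pct2raw_y(y_pct, eye_noise_sd)

  if (is.null(n_blinks)) n_blinks <- stats::rpois(1, blink_rate)
  blinks <- data.frame(start_ms = numeric(), end_ms = numeric())
  if (n_blinks > 0L) {
    for (b in seq_len(n_blinks)) {
      dur <- stats::runif(1, blink_duration_ms[1], blink_duration_ms[2])
      start <- stats::runif(1, time_ms[1], time_ms[n] - dur)
      idx <- time_ms >= start & time_ms <= start + dur
      lx[idx] <- NaN; ly[idx] <- NaN; rx[idx] <- NaN; ry[idx] <- NaN
      blinks <- rbind(blinks,
                      data.frame(start_ms = start, end_ms = start + dur))
    }
  }

  list(time_ms = time_ms, lx = lx, ly = ly, rx = rx, ry = ry,
       truth = shift_plan, blinks = blinks)
}

#' Generate a synthetic calibration recording
#'
#' Emulates the study's custom calibration module: a fixation point visits
#' seven positions in randomized order (left/right top/middle/bottom at the
#' item eccentricity, plus the screen centre), dwelling 1000-1500 ms at each.
#' Gaze is rendered in raw tracker units with Gaussian fixation noise.
#'
#' @inheritParams generate_gaze_trial
#' @param cal_noise_deg Fixation noise sd, degrees (0 gives noiseless data).
#' @param sampling_rate Hz.
#' @return An object of class `calibration_recording`: list with `samples`
#'   (data frame: `time_ms`, `label`, `lx`, `ly`, `rx`, `ry`), `onsets`
#'   (data frame: `label`, `onset_ms`), and `nominal` (data frame: `label`,
#'   `x_deg`, `y_deg`).
#' @export
generate_calibration <- function(item_eccentricity_deg = 5.7,
                                 raw_center = c(512, 384),
                                 raw_gain = 35,
                                 cal_noise_deg = 0.05,
                                 sampling_rate = 1000) {
  e <- item_eccentricity_deg
  nominal <- data.frame(
    label = c("left-top", "left-middle", "left-bottom",
              "right-top", "right-middle", "right-bottom", "centre"),
    x_deg = c(-e, -e, -e, e, e, e, 0),
    y_deg = c(e, 0, -e, e, 0, -e, 0),
    stringsAsFactors = FALSE)
  order_idx <- sample.int(7L)
  dwell <- stats::runif(7L, 1000, 1500)

  seg <- vector("list", 7L)
  onsets <- numeric(7L)
  t0 <- 0
  for (i in seq_len(7L)) {
    p <- nominal[order_idx[i], ]
    n <- round(dwell[i] * sampling_rate / 1000)
    tt <- t0 + seq_len(n) - 1
    noise <- function() stats::rnorm(n, 0, cal_noise_deg)
    seg[[i]] <- data.frame(
      time_ms = tt * 1000 / sampling_rate,
      label = p$label,
      lx = raw_center[1] + raw_gain * (p$x_deg + noise()),
      ly = raw_center[2] + raw_gain * (p$y_deg + noise()),
      rx = raw_center[1] + raw_gain * (p$x_deg + noise()),
      ry = raw_center[2] + raw_gain * (p$y_deg + noise()),
      stringsAsFactors = FALSE)
    onsets[i] <- tt[1] * 1000 / sampling_rate
    t0 <- t0 + n
  }
  out <- list(samples = do.call(rbind, seg),
              onsets = data.frame(label = nominal$label[order_idx],
                                  onset_ms = onsets,
                                  stringsAsFactors = FALSE),
              nominal = nominal)
  class(out) <- "calibration_recording"
  out
}
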