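# Velocity-threshold gaze-shift detector. A deliberately low, trial-based
# threshold (3 x median velocity) is used so that trials classified as
# containing no microsaccade can be trusted; displacement candidates below
# the 1% magnitude floor (0.057 deg) are discarded afterwards.

#' Compute smoothed gaze velocity
#'
#' Velocity is the absolute first temporal difference of gaze position
#' (% per ms at 1 kHz), smoothed with a Gaussian-weighted moving average over
#' a 7-ms sliding window (sd = window/5, truncated to the window, matching
#' the common Gaussian-weighted moving-average default). NaN samples yield
#' NaN velocity wherever they fall inside the kernel support.
#'
#' @param epoch A [gaze_epoch()] or numeric position trace.
#' @param window_ms Smoothing window length, ms (odd number of samples at
#'   1 kHz).
#' @return Numeric velocity trace (same length as the input; the first
#'   sample and kernel edges are NA).
#' @export
compute_velocity <- function(epoch, window_ms = 7) {
  x <- if (inherits(epoch, "gaze_epoch")) epoch$x_pct else epoch
  if (all(is.na(x)))
    stop("empty-velocity error: gaze trace contains no finite samples")
  v <- c(NA_real_, abs(diff(x)))
  n_k <- max(1L, round(window_ms))
  if (n_k %% 2L == 0L) n_k <- n_k + 1L
  half <- (n_k - 1L) / 2L
  tau <- seq(-half, half)
  sdk <- n_k / 5
  w <- exp(-tau^2 / (2 * sdk^2))
  w <- w / sum(w)
  as.numeric(stats::filter(v, w, sides = 2))
}

#' Detect gaze shifts by velocity thresholding
#'
#' Implements the trial-based detector: samples whose smoothed velocity
#' exceeds three times the trial's median velocity mark candidate shifts
#' (onset = first sample of each supra-threshold run); successive onsets
#' must be separated by more than 100 ms (candidates inside the refractory
#' period of a retained onset are dropped and do not restart it); shift
#' magnitude is the mean gaze position in the 50-100 ms window after the
#' onset minus the mean in the 50 ms window before it; candidates whose
#' absolute magnitude is below 1% are discarded.
#'
#' @param velocity Smoothed velocity trace from [compute_velocity()].
#' @param epoch The matching [gaze_epoch()].
#' @param threshold_multiplier Velocity threshold as a multiple of the
#'   trial's median (finite) velocity.
#' @param refractory_ms Minimum separation between retained onsets, ms.
#' @param min_magnitude_pct Magnitude floor, % units.
#' @param pre_window_ms,post_window_ms Magnitude estimation windows relative
#'   to the onset, ms (closed intervals; finite samples averaged).
#' @return Data frame of class `gaze_shifts` with columns `onset_ms`,
#'   `magnitude_pct`, `peak_velocity`; candidates skipped because a
#'   magnitude window fell outside the epoch are recorded in the `skipped`
#'   attribute.
#' @export
detect_shifts <- function(velocity, epoch,
                          threshold_multiplier = 3,
                          refractory_ms = 100,
                          min_magnitude_pct = 1,
                          pre_window_ms = c(-50, 0),
                          post_window_ms = c(50, 100)) {
  t <- epoch$time_ms
  x <- epoch$x_pct
  stopifnot(length(velocity) == length(x))
  fin <- is.finite(velocity)
  if (!any(fin))
    stop("empty-velocity error: no finite velocity samples")
  threshold <- threshold_multiplier * stats::median(velocity[fin])

  supra <- fin & velocity > threshold
  # run onsets: supra-threshold sample whose predecessor is not
  # supra-threshold (NaN breaks a run)
  prev <- c(FALSE, supra[-length(supra)])
  onset_idx <- which(supra & !prev)

  empty <- data.frame(onset_ms = numeric(), magnitude_pct = numeric(),
                      peak_velocity = numeric())
  skipped <- data.frame(onset_ms = numeric(), reason = character())
  if (length(onset_idx) == 0L)
    return(structure(empty, class = c("gaze_shifts", "data.frame"),
                     threshold = threshold, skipped = skipped))

  # refractory rule between retained onsets
  kept <- numeric(0)
  last <- -Inf
  for (i in onset_idx) {
    if (t[i] - last > refractory_ms) {
      kept <- c(kept, i)
      last <- t[i]
    }
  }

  rows <- vector("list", length(kept))
  for (j in seq_along(kept)) {
    i <- kept[j]
    pre_lo <- t[i] + pre_window_ms[1]; pre_hi <- t[i] + pre_window_ms[2]
    post_lo <- t[i] + post_window_ms[1]; post_hi <- t[i] + post_window_ms[2]
    if (pre_lo < t[1] || post_hi > t[length(t)]) {
      skipped <- rbind(skipped, data.frame(
        onset_ms = t[i], reason = "magnitude window outside epoch"))
      next
    }
    pre <- x[t >= pre_lo & t <= pre_hi]
    post <- x[t >= post_lo & t <= post_hi]
    if (!any(is.finite(pre)) || !any(is.finite(post))) {
      skipped <- rbind(skipped, data.frame(
        onset_ms = t[i], reason = "no finite samples in magnitude window"))
      next
    }
    mag <- mean(post[is.finite(post)]) - mean(pre[is.finite(pre)])
    if (abs(mag) < min_magnitude_pct) next
    pk_sel <- t >= t[i] & t <= t[i] + 50
    pk <- suppressWarnings(max(velocity[pk_sel][is.finite(velocity[pk_sel])]))
    rows[[j]] <- data.frame(onset_ms = t[i], magnitude_pct = mag,
                            peak_velocity = if (is.finite(pk)) pk else NA_real_)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows) > 0L) do.call(rbind, rows) else empty
  structure(out, class = c("gaze_shifts", "data.frame"),
            threshold = threshold, skipped = skipped)
}

#' Label shifts as toward or away from the cued item's side
#'
#' A shift is "toward" when its signed magnitude points to the memorised
#' side of the cued item (negative = leftward in the % convention), "away"
#' otherwise.
#'
#' @param events A `gaze_shifts` data frame.
#' @param cued_side `"left"` or `"right"`.
#' @return The events with an added `direction` column.
#' @export
label_direction <- function(events, cued_side) {
  cued_side <- match.arg(cued_side, c("left", "right"))
  if (nrow(events) == 0L) {
    events$direction <- character(0)
    return(events)
  }
  if (any(events$magnitude_pct == 0))
    stop("internal error: zero-magnitude event cannot be labelled")
  tsign <- if (cued_side == "left") -1 else 1
  events$direction <- ifelse(sign(events$magnitude_pct) == tsign,
                             "toward", "away")
  events
}

#' Classify a trial by its first in-window gaze shift
#'
#' Trials with an unusable eye trace are `"unusable"`. Otherwise the class
#' is the direction (`"toward"`/`"away"`) of the first detected shift whose
#' onset falls in the 200-600 ms post-cue window, or `"none"` if no shift
#' was detected in that window.
#'
#' @param events Direction-labelled `gaze_shifts`, sorted by onset.
#' @param usable Logical from [mark_usable()].
#' @param window_ms Classification window, ms (closed).
#' @return List of class `trial_class`: `class` and `first_shift_latency_ms`
#'   (NA unless the class is toward/away).
#' @export
classify_trial <- function(events, usable, window_ms = c(200, 600)) {
  if (!usable)
    return(structure(list(class = "unusable",
                          first_shift_latency_ms = NA_real_),
                     class = "trial_class"))
  if (nrow(events) > 0L) {
    events <- events[order(events$onset_ms), ]
    inw <- events$onset_ms >= window_ms[1] & events$onset_ms <= window_ms[2]
    if (any(inw)) {
      first <- which(inw)[1]
      return(structure(list(class = events$direction[first],
                            first_shift_latency_ms = events$onset_ms[first]),
                       class = "trial_class"))
    }
  }
  structure(list(class = "none", first_shift_latency_ms = NA_real_),
            class = "trial_class")
}
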