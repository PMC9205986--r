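# Rate summaries of detected gaze shifts: sliding-window rate time courses,
# time x magnitude rate maps, and the per-participant median latency split.

# counts of onsets per 1-ms grid step, then a centred sliding-window sum
sliding_counts <- function(onsets_ms, grid_ms, window_ms) {
  counts <- numeric(length(grid_ms))
  if (length(onsets_ms) > 0L) {
    idx <- round(onsets_ms - grid_ms[1]) + 1L
    idx <- idx[idx >= 1L & idx <= length(grid_ms)]
    counts <- tabulate(idx, nbins = length(grid_ms))
  }
  half <- window_ms / 2
  cs <- c(0, cumsum(counts))
  n <- length(grid_ms)
  # window [t - half, t + half): samples i - half .. i + half - 1
  lo <- pmax(1L, seq_len(n) - as.integer(half))
  hi <- pmin(n, seq_len(n) + as.integer(half) - 1L)
  cs[hi + 1L] - cs[lo]
}

#' Time course of gaze-shift rate
#'
#' Number of shift onsets per second in a 50-ms sliding window advanced in
#' 1-ms steps (window centred on each step, half-open `[t-25, t+25)`),
#' normalized by the number of trials.
#'
#' @param onsets_ms Numeric vector of shift onsets pooled over trials, ms
#'   (or a list of per-trial onset vectors).
#' @param n_trials Number of trials the onsets were pooled from.
#' @param time_range_ms Range of the output time axis, ms.
#' @param window_ms Sliding window length, ms.
#' @param step_ms Step of the output grid, ms.
#' @return Data frame with `time_ms` and `rate_hz` (shifts per second).
#' @export
shift_rate_timecourse <- function(onsets_ms, n_trials,
                                  time_range_ms = c(-200, 1000),
                                  window_ms = 50, step_ms = 1) {
  if (n_trials < 1L) stop("input error: need at least one trial")
  if (is.list(onsets_ms)) onsets_ms <- unlist(onsets_ms, use.names = FALSE)
  grid <- seq(time_range_ms[1], time_range_ms[2], by = step_ms)
  cnt <- sliding_counts(onsets_ms, grid, window_ms)
  data.frame(time_ms = grid,
             rate_hz = cnt / n_trials / (window_ms / 1000))
}

#' Rate map over time and gaze-shift magnitude
#'
#' Decomposes the shift-rate time course by shift magnitude using
#' overlapping 5%-wide magnitude bins with left edges 1..110% in steps of
#' 1% (bin b covers `[b, b+5)` in absolute magnitude). Each cell is the
#' rate (shifts/s) of events in that time window and magnitude bin.
#'
#' @param events Data frame with `onset_ms` and `magnitude_pct` pooled over
#'   trials.
#' @inheritParams shift_rate_timecourse
#' @param bin_edges_pct Left edges of the magnitude bins, %.
#' @param bin_width_pct Magnitude bin width, %.
#' @return List of class `rate_magnitude_map`: `time_ms`, `magnitude_pct`
#'   (left edges), and `rate` (time x bins matrix, shifts/s).
#' @export
rate_magnitude_map <- function(events, n_trials,
                               time_range_ms = c(-200, 1000),
                               window_ms = 50, step_ms = 1,
                               bin_edges_pct = 1:110,
                               bin_width_pct = 5) {
  if (n_trials < 1L) stop("input error: need at least one trial")
  grid <- seq(time_range_ms[1], time_range_ms[2], by = step_ms)
  mags <- abs(events$magnitude_pct)
  rate <- matrix(0, nrow = length(grid), ncol = length(bin_edges_pct))
  for (b in seq_along(bin_edges_pct)) {
    lo <- bin_edges_pct[b]
    sel <- mags >= lo & mags < lo + bin_width_pct
    if (any(sel))
      rate[, b] <- sliding_counts(events$onset_ms[sel], grid, window_ms) /
        n_trials / (window_ms / 1000)
  }
  structure(list(time_ms = grid, magnitude_pct = bin_edges_pct, rate = rate),
            class = "rate_magnitude_map")
}

#' Toward-minus-away difference of two rate-magnitude maps
#'
#' @param toward,away `rate_magnitude_map` objects on identical axes.
#' @return A `rate_magnitude_map` whose `rate` is the difference.
#' @export
rate_map_difference <- function(toward, away) {
  stopifnot(identical(toward$time_ms, away$time_ms),
            identical(toward$magnitude_pct, away$magnitude_pct))
  structure(list(time_ms = toward$time_ms,
                 magnitude_pct = toward$magnitude_pct,
                 rate = toward$rate - away$rate),
            class = "rate_magnitude_map")
}

#' Split toward trials into early and late by microsaccade latency
#'
#' Per participant, trials whose first toward-shift latency is strictly
#' below the participant's median latency are "early" and those above it
#' "late"; trials tied at the median are assigned alternately to whichever
#' half has fewer trials, balancing the counts. Participants with fewer
#' than two toward trials are excluded with a warning.
#'
#' @param latencies Data frame with columns `participant`, `trial`,
#'   `latency_ms` (first toward-shift latency).
#' @return The input with an added `half` column (`"early"`/`"late"`), tied
#'   rows assigned by the balancing rule; excluded participants' rows are
#'   dropped.
#' @export
split_by_latency <- function(latencies) {
  parts <- split(latencies, latencies$participant)
  out <- lapply(parts, function(d) {
    if (nrow(d) < 2L) {
      warning(sprintf(
        "participant %s excluded from latency split: fewer than 2 toward trials",
        d$participant[1]))
      return(NULL)
    }
    med <- stats::median(d$latency_ms)
    half <- rep(NA_character_, nrow(d))
    half[d$latency_ms < med] <- "early"
    half[d$latency_ms > med] <- "late"
    ties <- which(is.na(half))
    for (i in ties) {
      n_early <- sum(half == "early", na.rm = TRUE)
      n_late <- sum(half == "late", na.rm = TRUE)
      half[i] <- if (n_early <= n_late) "early" else "late"
    }
    d$half <- half
    d
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L)
    return(cbind(latencies[0, ], half = character(0)))
  do.call(rbind, out)
}
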