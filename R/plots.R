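# Advisory figures (base graphics): shift-rate time courses, the
# time x magnitude difference map, and lateralization overlays.

#' Plot toward/away gaze-shift rate time courses
#'
#' @param report An `analysis_report`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_shift_rates <- function(report, ...) {
  r <- report$rates
  if (is.null(r)) stop("report has no rate summaries")
  ylim <- range(0, r$toward$rate_hz, r$away$rate_hz)
  graphics::plot(r$toward$time_ms, r$toward$rate_hz, type = "l",
                 col = "darkgreen", ylim = ylim,
                 xlab = "time from cue (ms)", ylab = "shift rate (Hz)", ...)
  graphics::lines(r$away$time_ms, r$away$rate_hz, col = "purple")
  graphics::legend("topright", c("toward", "away"),
                   col = c("darkgreen", "purple"), lty = 1, bty = "n")
  invisible(report)
}

#' Plot the toward-minus-away rate map over time and shift magnitude
#'
#' @param report An `analysis_report`.
#' @param ... Passed to [graphics::image()].
#' @export
plot_rate_magnitude_map <- function(report, ...) {
  m <- report$rates$map_difference
  if (is.null(m)) stop("report has no rate summaries")
  graphics::image(m$time_ms, m$magnitude_pct, m$rate,
                  xlab = "time from cue (ms)",
                  ylab = "shift magnitude (% of eccentricity)", ...)
  graphics::abline(h = deg_to_pct(1), lty = 2)
  invisible(report)
}

#' Overlay per-class alpha lateralization time courses
#'
#' @param report An `analysis_report`.
#' @param classes Classes to overlay.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_lateralization <- function(report,
                                classes = c("toward", "none", "away"), ...) {
  cols <- c(toward = "darkgreen", none = "grey40", away = "purple")
  tcs <- report$timecourses[classes]
  tcs <- tcs[!vapply(tcs, is.null, logical(1))]
  if (length(tcs) == 0L) stop("report has no lateralization time courses")
  ylim <- range(0, unlist(lapply(tcs, function(tc) colMeans(tc$matrix))))
  first <- TRUE
  for (cls in names(tcs)) {
    ga <- colMeans(tcs[[cls]]$matrix)
    if (first) {
      graphics::plot(tcs[[cls]]$time_ms, ga, type = "l", col = cols[[cls]],
                     ylim = ylim, xlab = "time from cue (ms)",
                     ylab = "alpha lateralization (%)", ...)
      graphics::abline(h = 0, lty = 3)
      first <- FALSE
    } else {
      graphics::lines(tcs[[cls]]$time_ms, ga, col = cols[[cls]])
    }
  }
  graphics::legend("bottomright", names(tcs), col = cols[names(tcs)],
                   lty = 1, bty = "n")
  invisible(report)
}
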