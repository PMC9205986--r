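# Engbert-Kliegl microsaccade detector: 2-D velocity with a 5-point moving
# derivative, per-axis median-based velocity-SD thresholds combined in an
# elliptic criterion, a minimum event duration, and a binocular
# temporal-overlap requirement. Serves as the established alternative to the
# horizontal velocity-threshold detector.

ek_velocity <- function(x) {
  n <- length(x)
  v <- rep(NA_real_, n)
  if (n >= 5L)
    v[3:(n - 2)] <- (x[5:n] + x[4:(n - 1)] - x[2:(n - 3)] - x[1:(n - 4)]) / 6
  v
}

ek_sigma <- function(v) {
  v <- v[is.finite(v)]
  s2 <- stats::median(v^2) - stats::median(v)^2
  sqrt(max(s2, .Machine$double.eps))
}

# monocular episodes: runs of supra-elliptic-threshold samples >= min_dur
ek_episodes <- function(vx, vy, lambda, min_dur) {
  eta_x <- lambda * ek_sigma(vx)
  eta_y <- lambda * ek_sigma(vy)
  crit <- (vx / eta_x)^2 + (vy / eta_y)^2 > 1
  crit[!is.finite(crit)] <- FALSE
  r <- rle(crit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_dur
  data.frame(start = starts[keep], end = ends[keep])
}

#' Detect microsaccades with the Engbert-Kliegl velocity criterion
#'
#' Two-dimensional gaze velocity is estimated per eye with a 5-point moving
#' derivative; samples exceeding an elliptic threshold of `lambda`
#' median-based velocity SDs on each axis, for at least `min_duration_ms`,
#' form monocular episodes; a microsaccade requires temporal overlap of at
#' least `min_overlap` samples between the eyes (monocular data fall back to
#' single-eye detection with a warning). Detected events are mapped to the
#' same event table as [detect_shifts()]: the onset is the first overlapping
#' sample and the magnitude is estimated from the cyclopean horizontal trace
#' with the same before/after-window rule, magnitude floor, and refractory
#' separation.
#'
#' @param left_x,left_y,right_x,right_y Per-eye gaze traces in % units
#'   (either eye may be all-NA for monocular data).
#' @param epoch A [gaze_epoch()] carrying the cyclopean horizontal trace
#'   used for magnitude estimation.
#' @param lambda Threshold multiplier (median-based velocity SDs).
#' @param min_duration_ms Minimum episode duration, ms.
#' @param min_overlap Minimum binocular overlap, samples.
#' @param refractory_ms,min_magnitude_pct As in [detect_shifts()].
#' @return A `gaze_shifts` data frame (`onset_ms`, `magnitude_pct`,
#'   `peak_velocity`).
#' @export
detect_engbert_kliegl <- function(left_x, left_y, right_x, right_y, epoch,
                                  lambda = 6, min_duration_ms = 6,
                                  min_overlap = 1,
                                  refractory_ms = 100,
                                  min_magnitude_pct = 1) {
  t <- epoch$time_ms
  n <- length(t)
  mono_l <- all(is.na(left_x))
  mono_r <- all(is.na(right_x))
  if (mono_l && mono_r)
    stop("input error: no eye carries finite data")
  if (mono_l || mono_r) {
    warning("monocular data: falling back to single-eye detection")
    xs <- if (mono_l) right_x else left_x
    ys <- if (mono_l) right_y else left_y
    ep <- ek_episodes(ek_velocity(xs), ek_velocity(ys), lambda,
                      min_duration_ms)
    onset_idx <- ep$start
  } else {
    ep_l <- ek_episodes(ek_velocity(left_x), ek_velocity(left_y), lambda,
                        min_duration_ms)
    ep_r <- ek_episodes(ek_velocity(right_x), ek_velocity(right_y), lambda,
                        min_duration_ms)
    in_l <- rep(FALSE, n); in_r <- rep(FALSE, n)
    for (i in seq_len(nrow(ep_l))) in_l[ep_l$start[i]:ep_l$end[i]] <- TRUE
    for (i in seq_len(nrow(ep_r))) in_r[ep_r$start[i]:ep_r$end[i]] <- TRUE
    both <- in_l & in_r
    r <- rle(both)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_overlap
    onset_idx <- starts[keep]
  }

  empty <- structure(
    data.frame(onset_ms = numeric(), magnitude_pct = numeric(),
               peak_velocity = numeric()),
    class = c("gaze_shifts", "data.frame"))
  if (length(onset_idx) == 0L) return(empty)

  # refractory between retained onsets, then magnitude via the same
  # before/after-window rule as the primary detector
  kept <- numeric(0)
  last <- -Inf
  for (i in onset_idx) {
    if (t[i] - last > refractory_ms) {
      kept <- c(kept, i)
      last <- t[i]
    }
  }
  x <- epoch$x_pct
  vmag <- sqrt(ek_velocity(merge_eyes(left_x, right_x))^2 +
                 ek_velocity(merge_eyes(left_y, right_y))^2)
  rows <- lapply(kept, function(i) {
    pre_sel <- t >= t[i] - 50 & t <= t[i]
    post_sel <- t >= t[i] + 50 & t <= t[i] + 100
    if (t[i] - 50 < t[1] || t[i] + 100 > t[n]) return(NULL)
    pre <- x[pre_sel]; post <- x[post_sel]
    if (!any(is.finite(pre)) || !any(is.finite(post))) return(NULL)
    m <- mean(post[is.finite(post)]) - mean(pre[is.finite(pre)])
    if (abs(m) < min_magnitude_pct) return(NULL)
    pk_sel <- t >= t[i] & t <= t[i] + 50
    pk <- suppressWarnings(max(vmag[pk_sel][is.finite(vmag[pk_sel])]))
    data.frame(onset_ms = t[i], magnitude_pct = m,
               peak_velocity = if (is.finite(pk)) pk else NA_real_)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  structure(do.call(rbind, rows), class = c("gaze_shifts", "data.frame"))
}
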