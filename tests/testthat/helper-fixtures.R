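# Shared fixture builders: constructed gaze traces and a small study
# configuration sized for fast tests.

# minimum-jerk step trace in % units on a ms grid
step_trace <- function(time_ms, onset_ms, magnitude_pct, duration_ms = 20) {
  u <- pmin(pmax((time_ms - onset_ms) / duration_ms, 0), 1)
  magnitude_pct * (10 * u^3 - 15 * u^4 + 6 * u^5)
}

make_epoch <- function(x, time_ms = seq(-500, 1500), cued_side = "right") {
  gaze_epoch(time_ms, x, cued_side)
}

# random short trace mixing drift, occasional steps, and NaN stretches
random_trace <- function(n = 1500, p_step = 0.7, p_nan = 0.3) {
  t <- seq(-200, n - 201)
  x <- cumsum(rnorm(n, 0, 0.05))
  if (runif(1) < p_step) {
    grid <- seq(150, max(160, n - 500), by = 10)
    # two steps only when the grid is wide enough to separate them
    k <- if (diff(range(grid)) > 130) sample(1:2, 1) else 1L
    repeat {
      onsets <- sort(sample(grid, k))
      if (k == 1L || diff(onsets) > 120) break
    }
    for (o in onsets)
      x <- x + step_trace(t, t[o], runif(1, -8, 8))
  }
  if (runif(1) < p_nan) {
    s <- sample(seq_len(n - 120), 1)
    x[s:(s + sample(30:120, 1))] <- NaN
  }
  list(time_ms = t, x = x)
}

small_config <- function(...) {
  defaults <- list(n_participants = 3, n_trials = 12,
                   epoch_window = c(-200, 800),
                   latency_distribution = list(mean = 400, sd = 110,
                                               support = c(200, 600)),
                   seed = 123)
  args <- utils::modifyList(defaults, list(...))
  do.call(study_config, args)
}
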