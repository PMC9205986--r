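# Short-time Fourier power and alpha lateralization contrasts.
#
# The STFT uses a 300-ms Hann-tapered window zero-padded to 1 s so that the
# 1-50 Hz frequency axis in steps of 1 Hz falls on exact DFT bins. The
# windowed transform is computed as one matrix product of the window stack
# with a complex kernel, which is valid for any hop (50-ms standard mode and
# the 1-ms high-temporal-resolution latency mode) and exactly equals the
# per-window zero-padded DFT. Windows that would extend past the epoch are
# dropped, not zero-padded. Power is not normalized by taper energy: the
# lateralization contrast is scale invariant, so the normalization cancels.

hann_taper <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
}

#' Short-time Fourier power of an epoched signal
#'
#' @param signal Numeric signal sampled at `sampling_rate`.
#' @param time_ms Time axis of the signal, ms.
#' @param freqs_hz Frequencies to estimate, Hz (default 1-50 in steps of 1).
#' @param window_ms Sliding window length, ms.
#' @param step_ms Hop between window centres, ms: 50 (standard) or 1
#'   (latency-resolution mode).
#' @param sampling_rate Hz.
#' @return Object of class `tfr_power`: list with `power` (time x frequency
#'   matrix, >= 0), `time_ms` (window centres), `freq_hz`.
#' @export
stft_power <- function(signal, time_ms, freqs_hz = 1:50,
                       window_ms = 300, step_ms = 50,
                       sampling_rate = 1000) {
  n <- length(signal)
  win_n <- round(window_ms * sampling_rate / 1000)
  if (n < win_n)
    stop("input error: signal shorter than the analysis window")
  half <- window_ms / 2
  centres <- seq(time_ms[1] + half, time_ms[n] - half, by = step_ms)
  starts <- round((centres - half - time_ms[1]) * sampling_rate / 1000) + 1L
  starts <- starts[starts >= 1L & starts + win_n - 1L <= n]
  centres <- centres[seq_along(starts)]

  taper <- hann_taper(win_n)
  tau <- seq(0, win_n - 1) / sampling_rate
  kern <- vapply(freqs_hz,
                 function(f) taper * exp(-2i * pi * f * tau),
                 complex(win_n))
  idx <- outer(starts, 0:(win_n - 1L), "+")
  W <- matrix(signal[idx], nrow = length(starts))
  P <- Mod(W %*% kern)^2
  structure(list(power = P, time_ms = centres, freq_hz = freqs_hz),
            class = "tfr_power")
}

#' Average TFR power across trials
#'
#' @param tfrs List of `tfr_power` objects on identical axes.
#' @return A `tfr_power` with the elementwise mean power.
#' @export
average_power <- function(tfrs) {
  stopifnot(length(tfrs) > 0L)
  P <- Reduce(`+`, lapply(tfrs, function(t) t$power)) / length(tfrs)
  structure(list(power = P, time_ms = tfrs[[1]]$time_ms,
                 freq_hz = tfrs[[1]]$freq_hz),
            class = "tfr_power")
}

#' Normalized lateralization contrast of contralateral vs ipsilateral power
#'
#' Elementwise `((contra - ipsi) / (contra + ipsi)) * 100`, in percent and
#' bounded by +/-100. Cells with a non-positive denominator are flagged
#' invalid (NA). Power is averaged across trials within condition before the
#' contrast is formed (contrast of averages) unless the inputs are already
#' per-trial arrays handled by the caller.
#'
#' @param contra,ipsi `tfr_power` objects (or bare numeric arrays) on
#'   identical axes.
#' @return Object of class `tfr_contrast` (or numeric array if bare arrays
#'   were supplied): lateralization in %.
#' @export
lateralization_contrast <- function(contra, ipsi) {
  is_tfr <- inherits(contra, "tfr_power")
  pc <- if (is_tfr) contra$power else contra
  pi_ <- if (is_tfr) ipsi$power else ipsi
  stopifnot(identical(dim(pc), dim(pi_)) || length(pc) == length(pi_))
  denom <- pc + pi_
  L <- (pc - pi_) / denom * 100
  L[!is.finite(denom) | denom <= 0] <- NA_real_
  if (!is_tfr) return(L)
  structure(list(contrast = L, time_ms = contra$time_ms,
                 freq_hz = contra$freq_hz),
            class = "tfr_contrast")
}

#' Alpha-band lateralization time course
#'
#' Unweighted mean of the contrast over the frequency rows inside the
#' predefined band (8-12 Hz by default).
#'
#' @param contrast A `tfr_contrast`.
#' @param band_hz Frequency band limits, Hz (inclusive).
#' @return Data frame with `time_ms` and `lateralization_pct`.
#' @export
band_timecourse <- function(contrast, band_hz = c(8, 12)) {
  sel <- contrast$freq_hz >= band_hz[1] & contrast$freq_hz <= band_hz[2]
  if (!any(sel))
    stop("input error: band lies outside the frequency axis")
  vals <- contrast$contrast[, sel, drop = FALSE]
  data.frame(time_ms = contrast$time_ms,
             lateralization_pct = rowMeans(vals))
}

#' Alpha lateralization time course from per-trial cluster signals
#'
#' Convenience wrapper for one condition of one participant: computes STFT
#' power of every trial's contralateral and ipsilateral channels, averages
#' power across trials per channel, forms the lateralization contrast, and
#' averages it over the alpha band. With `per_trial_contrast = TRUE` the
#' contrast is instead computed per trial and then averaged.
#'
#' @param trials List of trials, each with `eeg_contra`, `eeg_ipsi`,
#'   `time_ms`.
#' @param freqs_hz,window_ms,step_ms,sampling_rate Passed to [stft_power()].
#' @param band_hz Alpha band, Hz.
#' @param per_trial_contrast Average per-trial contrasts instead of
#'   contrasting trial-averaged power.
#' @return Data frame with `time_ms` and `lateralization_pct`.
#' @export
condition_alpha_timecourse <- function(trials, freqs_hz = 1:50,
                                       window_ms = 300, step_ms = 50,
                                       sampling_rate = 1000,
                                       band_hz = c(8, 12),
                                       per_trial_contrast = FALSE) {
  stopifnot(length(trials) > 0L)
  pc <- lapply(trials, function(t)
    stft_power(t$eeg_contra, t$time_ms, freqs_hz, window_ms, step_ms,
               sampling_rate))
  pi_ <- lapply(trials, function(t)
    stft_power(t$eeg_ipsi, t$time_ms, freqs_hz, window_ms, step_ms,
               sampling_rate))
  if (per_trial_contrast) {
    L <- lapply(seq_along(trials), function(i)
      lateralization_contrast(pc[[i]], pi_[[i]]))
    mean_contrast <- Reduce(`+`, lapply(L, function(l) l$contrast)) /
      length(L)
    ctr <- structure(list(contrast = mean_contrast,
                          time_ms = pc[[1]]$time_ms,
                          freq_hz = pc[[1]]$freq_hz),
                     class = "tfr_contrast")
  } else {
    ctr <- lateralization_contrast(average_power(pc), average_power(pi_))
  }
  band_timecourse(ctr, band_hz)
}
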