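# Lateralized alpha EEG generator at the electrode-cluster level: two
# pre-averaged channels (contralateral and ipsilateral to the cued side)
# carrying 1/f background noise plus an alpha oscillation whose contralateral
# amplitude is attenuated after a programmed modulation onset.

# Coloured noise with power spectral density ~ 1/f^exponent, unit sd.
one_over_f_noise <- function(n, exponent = 1) {
  if (n < 2L) return(stats::rnorm(n))
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  # two-sided frequency index, DC excluded from the power law
  k <- c(0, seq_len(n - 1))
  k <- pmin(k, n - k)
  gain <- c(0, k[-1]^(-exponent / 2))
  x <- Re(stats::fft(spec * gain, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# Smooth (cosine) ramp from 0 at onset to 1 at onset + ramp_ms.
modulation_ramp <- function(time_ms, onset_ms, ramp_ms) {
  u <- (time_ms - onset_ms) / max(ramp_ms, .Machine$double.eps)
  u <- pmin(pmax(u, 0), 1)
  (1 - cos(pi * u)) / 2
}

#' Generate contralateral/ipsilateral alpha cluster signals for one trial
#'
#' Both channels contain 1/f background noise plus an alpha-frequency
#' oscillation of common amplitude. After `modulation_onset_ms` the
#' contralateral amplitude is reduced by `depth` (smooth cosine ramp of
#' `ramp_ms`), so the expected alpha-band lateralization
#' `((contra - ipsi) / (contra + ipsi)) * 100` is 0 before onset and
#' `((1-d)^2 - 1) / ((1-d)^2 + 1) * 100` on the plateau (for noiseless data).
#'
#' @param time_ms Epoch time axis, ms.
#' @param modulation_onset_ms Programmed modulation onset, ms (must lie
#'   within the epoch).
#' @param alpha_freq Oscillation frequency, Hz.
#' @param amplitude Oscillation amplitude.
#' @param depth Fractional contralateral amplitude attenuation in [0, 1).
#' @param ramp_ms Ramp duration, ms.
#' @param noise_sd Standard deviation of the background noise (0 = noiseless).
#' @param noise_exponent Spectral slope of the background noise.
#' @param sampling_rate Hz.
#' @return List with numeric vectors `contra` and `ipsi` and the `time_ms`
#'   axis.
#' @export
generate_alpha_signals <- function(time_ms,
                                   modulation_onset_ms,
                                   alpha_freq = 10,
                                   amplitude = 2,
                                   depth = 0.3,
                                   ramp_ms = 100,
                                   noise_sd = 1,
                                   noise_exponent = 1,
                                   sampling_rate = 1000) {
  if (depth < 0 || depth >= 1)
    stop("invalid parameter 'depth': must be in [0, 1)")
  if (modulation_onset_ms < time_ms[1] ||
      modulation_onset_ms > time_ms[length(time_ms)])
    stop("invalid parameter 'modulation_onset_ms': must lie within the epoch")
  n <- length(time_ms)
  phase_c <- stats::runif(1, 0, 2 * pi)
  phase_i <- stats::runif(1, 0, 2 * pi)
  osc <- function(phase) sin(2 * pi * alpha_freq * time_ms / 1000 + phase)
  a_contra <- amplitude * (1 - depth * modulation_ramp(time_ms,
                                                       modulation_onset_ms,
                                                       ramp_ms))
  contra <- a_contra * osc(phase_c)
  ipsi <- amplitude * osc(phase_i)
  if (noise_sd > 0) {
    contra <- contra + noise_sd * one_over_f_noise(n, noise_exponent)
    ipsi <- ipsi + noise_sd * one_over_f_noise(n, noise_exponent)
  }
  list(contra = contra, ipsi = ipsi, time_ms = time_ms)
}
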