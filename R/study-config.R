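#' Configuration of a synthetic attention study
#'
#' Bundles and validates every generative parameter of the synthetic-study
#' generator: task geometry, fixational-drift and blink models, the injected
#' microsaccade plan (probability, direction bias, latency and magnitude
#' distributions), the lateralized alpha EEG model, and behavioural outcomes.
#' All downstream analysis stages can be validated against a study generated
#' from a known configuration.
#'
#' Defaults emulate the statistical structure of a covert spatial attention
#' study in working memory: 23 participants with 1200 trials each, items at
#' 5.7 degrees eccentricity, about two thirds of trials containing a gaze
#' shift in the 200-600 ms post-cue window, of which two thirds are directed
#' toward the cued item's memorised side, shift magnitudes concentrated below
#' 1 degree, and a contralateral attenuation of 8-12 Hz power whose onset
#' co-varies with microsaccade latency.
#'
#' @param n_participants Number of participants (>= 2).
#' @param n_trials Trials per participant; cued side is balanced across trials.
#' @param sampling_rate Sampling rate of gaze and EEG, Hz.
#' @param epoch_window Epoch limits relative to cue onset, ms (length 2).
#' @param item_eccentricity_deg Eccentricity of the memory-item centres, degrees.
#' @param p_shift_in_window Probability that a trial contains at least one
#'   injected gaze shift in the 200-600 ms window.
#' @param p_toward_given_shift Probability that the first in-window shift is
#'   directed toward the cued item's memorised side.
#' @param p_extra_shift Probability of one additional shift later in the epoch
#'   (after 650 ms), emulating multi-shift trials.
#' @param latency_distribution List with fields `mean`, `sd`, `support`:
#'   truncated-normal latency (ms) of the first in-window shift; support must
#'   lie within the epoch.
#' @param magnitude_distribution List with fields `meanlog`, `sdlog`,
#'   `min_pct`: lognormal shift magnitude in % units, floored at `min_pct`.
#' @param drift_noise_sd Per-sample standard deviation of the Gaussian
#'   random-walk fixational drift, % units.
#' @param eye_noise_sd Per-eye white measurement noise, % units.
#' @param blink_rate Expected blinks per trial (Poisson).
#' @param blink_duration_ms Range of blink durations, ms (uniform).
#' @param alpha_freq Alpha oscillation frequency, Hz.
#' @param alpha_amplitude Alpha oscillation amplitude (arbitrary units).
#' @param alpha_modulation_depth Fractional contralateral amplitude attenuation
#'   after modulation onset, in [0, 1).
#' @param alpha_away_factor Multiplier on the modulation depth in away-class
#'   trials (attenuated modulation when attention initially goes to the wrong
#'   side), in [0, 1].
#' @param alpha_onset_lag Lag (ms) from the first in-window shift onset (or,
#'   for no-shift trials, from the mean shift latency) to modulation onset.
#' @param alpha_ramp_ms Duration of the smooth ramp from unmodulated to fully
#'   modulated alpha amplitude, ms.
#' @param eeg_noise_sd Standard deviation of the 1/f background EEG noise.
#' @param noise_exponent Spectral slope of the background noise (power ~
#'   1/f^exponent).
#' @param behaviour List with per-class mean reproduction error
#'   (`error_mean`, named vector toward/none/away, degrees), common
#'   `error_sd`, and class-independent `rt_mean`/`rt_sd` (ms).
#' @param raw_center Raw tracker coordinates of the screen centre (x, y).
#' @param raw_gain Raw tracker units per degree of visual angle.
#' @param cal_noise_deg Fixation noise during calibration, degrees (sd).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   seed, with sub-streams split per participant and per trial.
#'
#' @return An object of class `study_config` (a validated list).
#' @seealso [generate_study()]
#' @export
study_config <- function(n_participants = 23,
                         n_trials = 1200,
                         sampling_rate = 1000,
                         epoch_window = c(-1000, 2000),
                         item_eccentricity_deg = 5.7,
                         p_shift_in_window = 0.66,
                         p_toward_given_shift = 2 / 3,
                         p_extra_shift = 0.25,
                         latency_distribution = list(mean = 400, sd = 110,
                                                     support = c(200, 600)),
                         magnitude_distribution = list(meanlog = log(5),
                                                       sdlog = 0.6,
                                                       min_pct = 1),
                         drift_noise_sd = 0.03,
                         eye_noise_sd = 0.1,
                         blink_rate = 0.2,
                         blink_duration_ms = c(100, 300),
                         alpha_freq = 10,
                         alpha_amplitude = 2,
                         alpha_modulation_depth = 0.3,
                         alpha_away_factor = 0.5,
                         alpha_onset_lag = 50,
                         alpha_ramp_ms = 100,
                         eeg_noise_sd = 1,
                         noise_exponent = 1,
                         behaviour = list(error_mean = c(toward = 13.65,
                                                         none = 14.2,
                                                         away = 14.72),
                                          error_sd = 6,
                                          rt_mean = 900, rt_sd = 250),
                         raw_center = c(512, 384),
                         raw_gain = 35,
                         cal_noise_deg = 0.05,
                         seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              n_trials = as.integer(n_trials),
              sampling_rate = sampling_rate,
              epoch_window = epoch_window,
              item_eccentricity_deg = item_eccentricity_deg,
              p_shift_in_window = p_shift_in_window,
              p_toward_given_shift = p_toward_given_shift,
              p_extra_shift = p_extra_shift,
              latency_distribution = latency_distribution,
              magnitude_distribution = magnitude_distribution,
              drift_noise_sd = drift_noise_sd,
              eye_noise_sd = eye_noise_sd,
              blink_rate = blink_rate,
              blink_duration_ms = blink_duration_ms,
              alpha_freq = alpha_freq,
              alpha_amplitude = alpha_amplitude,
              alpha_modulation_depth = alpha_modulation_depth,
              alpha_away_factor = alpha_away_factor,
              alpha_onset_lag = alpha_onset_lag,
              alpha_ramp_ms = alpha_ramp_ms,
              eeg_noise_sd = eeg_noise_sd,
              noise_exponent = noise_exponent,
              behaviour = behaviour,
              raw_center = raw_center,
              raw_gain = raw_gain,
              cal_noise_deg = cal_noise_deg,
              seed = as.integer(seed))
  validate_study_config(cfg)
  class(cfg) <- "study_config"
  cfg
}

# Parameter errors name the offending field.
validate_study_config <- function(cfg) {
  stop_field <- function(field, msg) {
    stop(sprintf("invalid study_config field '%s': %s", field, msg),
         call. = FALSE)
  }
  if (is.na(cfg$n_participants) || cfg$n_participants < 2L)
    stop_field("n_participants", "must be >= 2")
  if (is.na(cfg$n_trials) || cfg$n_trials < 1L)
    stop_field("n_trials", "must be >= 1")
  if (!is.numeric(cfg$sampling_rate) || cfg$sampling_rate <= 0)
    stop_field("sampling_rate", "must be > 0")
  if (length(cfg$epoch_window) != 2L || diff(cfg$epoch_window) <= 0)
    stop_field("epoch_window", "must be an increasing (start, end) pair in ms")
  for (p in c("p_shift_in_window", "p_toward_given_shift", "p_extra_shift")) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop_field(p, "must be a probability in [0, 1]")
  }
  lat <- cfg$latency_distribution
  if (is.null(lat$support) || length(lat$support) != 2L)
    stop_field("latency_distribution", "needs a (lo, hi) support in ms")
  if (lat$support[1] < cfg$epoch_window[1] ||
      lat$support[2] > cfg$epoch_window[2])
    stop_field("latency_distribution", "support must lie within the epoch")
  if (is.null(lat$sd) || lat$sd < 0)
    stop_field("latency_distribution", "sd must be >= 0")
  mag <- cfg$magnitude_distribution
  if (is.null(mag$min_pct) || mag$min_pct < 0)
    stop_field("magnitude_distribution", "min_pct must be >= 0")
  if (cfg$alpha_modulation_depth < 0 || cfg$alpha_modulation_depth >= 1)
    stop_field("alpha_modulation_depth", "must be in [0, 1)")
  if (cfg$alpha_away_factor < 0 || cfg$alpha_away_factor > 1)
    stop_field("alpha_away_factor", "must be in [0, 1]")
  if (cfg$drift_noise_sd < 0) stop_field("drift_noise_sd", "must be >= 0")
  if (cfg$eye_noise_sd < 0) stop_field("eye_noise_sd", "must be >= 0")
  if (cfg$blink_rate < 0) stop_field("blink_rate", "must be >= 0")
  if (cfg$raw_gain == 0) stop_field("raw_gain", "must be nonzero")
  invisible(cfg)
}

#' @export
print.study_config <- function(x, ...) {
  cat("Synthetic attention-study configuration\n")
  cat(sprintf("  %d participants x %d trials, %g Hz, epoch %d..%d ms\n",
              x$n_participants, x$n_trials, x$sampling_rate,
              x$epoch_window[1], x$epoch_window[2]))
  cat(sprintf("  shifts: P(in-window) = %.2f, P(toward | shift) = %.2f\n",
              x$p_shift_in_window, x$p_toward_given_shift))
  cat(sprintf("  alpha: %g Hz, depth %.2f (away x %.2f), lag %g ms\n",
              x$alpha_freq, x$alpha_modulation_depth, x$alpha_away_factor,
              x$alpha_onset_lag))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
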