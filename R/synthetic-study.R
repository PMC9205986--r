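# Multi-participant synthetic study generator with known ground truth.
# Random streams are split per participant and per trial (each trial is
# generated under its own derived seed), so regenerating a subset of the
# study reproduces the same data.

MAX_SEED <- 2147483646L

derive_seeds <- function(n) sample.int(MAX_SEED, n)

# truncated-normal draw by inverse-CDF restriction
rtruncnorm1 <- function(mean, sd, lo, hi) {
  if (sd == 0) return(min(max(mean, lo), hi))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(1, plo, phi), mean, sd)
}

# sign pointing toward the cued item's memorised side
toward_sign <- function(cued_side) ifelse(cued_side == "left", -1, 1)

#' Generate a complete synthetic study
#'
#' Builds a multi-participant study with all generative parameters known:
#' per-trial raw binocular gaze traces with injected gaze shifts and blink
#' NaN stretches, a calibration recording per participant, contralateral and
#' ipsilateral alpha-band EEG cluster channels whose modulation onset
#' co-varies with the injected microsaccade latency, behavioural outcomes
#' with class-dependent reproduction error, and a ground-truth table with one
#' row per injected shift. Cued sides are balanced across trials. The output
#' is deterministic given `config$seed`.
#'
#' @param config A [study_config()].
#' @return An object of class `synthetic_study`: list with `config`,
#'   `participants` (each a list with `trials`, `calibration`, `meta`), and
#'   `ground_truth` (data frame: participant, trial, onset_ms, magnitude_pct,
#'   direction, in_window).
#' @export
generate_study <- function(config) {
  if (!inherits(config, "study_config")) config <- do.call(study_config, config)
  validate_study_config(config)
  set.seed(config$seed)
  p_seeds <- derive_seeds(config$n_participants)
  participants <- vector("list", config$n_participants)
  gt_all <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    pp <- generate_participant(config, p_seeds[p], p)
    participants[[p]] <- pp$participant
    gt_all[[p]] <- pp$ground_truth
  }
  out <- list(config = config,
              participants = participants,
              ground_truth = do.call(rbind, gt_all))
  class(out) <- "synthetic_study"
  out
}

generate_participant <- function(config, seed, participant_id) {
  set.seed(seed)
  n_tr <- config$n_trials
  # balanced cued sides, randomized order
  sides <- rep(c("left", "right"), length.out = n_tr)
  sides <- sides[sample.int(n_tr)]
  trial_seeds <- derive_seeds(n_tr)
  cal_seed <- derive_seeds(1L)

  fs <- config$sampling_rate
  time_ms <- seq(config$epoch_window[1], config$epoch_window[2],
                 by = 1000 / fs)
  lat <- config$latency_distribution
  mag <- config$magnitude_distribution

  trials <- vector("list", n_tr)
  meta <- vector("list", n_tr)
  gt <- vector("list", n_tr)
  for (tr in seq_len(n_tr)) {
    set.seed(trial_seeds[tr])
    cued <- sides[tr]
    tsign <- toward_sign(cued)

    # --- shift plan ------------------------------------------------------
    plan <- data.frame(onset_ms = numeric(), magnitude_pct = numeric())
    first_onset <- NA_real_
    first_dir <- NA_character_
    if (stats::runif(1) < config$p_shift_in_window) {
      first_onset <- rtruncnorm1(lat$mean, lat$sd, lat$support[1],
                                 lat$support[2])
      is_toward <- stats::runif(1) < config$p_toward_given_shift
      first_dir <- if (is_toward) "toward" else "away"
      m <- max(mag$min_pct, stats::rlnorm(1, mag$meanlog, mag$sdlog))
      plan <- rbind(plan, data.frame(
        onset_ms = first_onset,
        magnitude_pct = m * tsign * (if (is_toward) 1 else -1)))
    }
    if (stats::runif(1) < config$p_extra_shift &&
        config$epoch_window[2] - 150 > 720) {
      # late extra shift, outside the classification window and > 100 ms
      # after any in-window shift; only when the epoch accommodates it
      eo <- stats::runif(1, 720, config$epoch_window[2] - 150)
      em <- max(mag$min_pct, stats::rlnorm(1, mag$meanlog, mag$sdlog))
      plan <- rbind(plan, data.frame(
        onset_ms = eo, magnitude_pct = em * sample(c(-1, 1), 1)))
    }
    class_true <- if (is.na(first_onset)) "none" else first_dir

    # --- gaze ------------------------------------------------------------
    gz <- generate_gaze_trial(
      time_ms, plan,
      drift_noise_sd = config$drift_noise_sd,
      eye_noise_sd = config$eye_noise_sd,
      blink_rate = config$blink_rate,
      blink_duration_ms = config$blink_duration_ms,
      raw_center = config$raw_center,
      raw_gain = config$raw_gain,
      item_eccentricity_deg = config$item_eccentricity_deg)

    # --- EEG -------------------------------------------------------------
    # modulation onset co-varies with the injected shift latency; for
    # no-shift trials it sits at the mean latency, emulating modulation
    # equivalent to shift trials
    mod_onset <- if (!is.na(first_onset)) first_onset + config$alpha_onset_lag
                 else lat$mean + config$alpha_onset_lag
    depth <- config$alpha_modulation_depth *
      (if (identical(class_true, "away")) config$alpha_away_factor else 1)
    eeg <- generate_alpha_signals(
      time_ms, mod_onset,
      alpha_freq = config$alpha_freq,
      amplitude = config$alpha_amplitude,
      depth = depth,
      ramp_ms = config$alpha_ramp_ms,
      noise_sd = config$eeg_noise_sd,
      noise_exponent = config$noise_exponent,
      sampling_rate = fs)

    # --- behaviour -------------------------------------------------------
    beh <- config$behaviour
    err <- max(0, stats::rnorm(1, beh$error_mean[[class_true]], beh$error_sd))
    rt <- max(150, stats::rnorm(1, beh$rt_mean, beh$rt_sd))

    trials[[tr]] <- list(time_ms = time_ms,
                         lx = gz$lx, ly = gz$ly, rx = gz$rx, ry = gz$ry,
                         eeg_contra = eeg$contra, eeg_ipsi = eeg$ipsi,
                         cued_side = cued, blinks = gz$blinks)
    meta[[tr]] <- data.frame(participant = participant_id, trial = tr,
                             cued_side = cued, class_true = class_true,
                             first_onset_ms = first_onset,
                             modulation_onset_ms = mod_onset,
                             error_deg = err, rt_ms = rt,
                             stringsAsFactors = FALSE)
    if (nrow(plan) > 0L) {
      dir_lab <- ifelse(sign(plan$magnitude_pct) == tsign, "toward", "away")
      gt[[tr]] <- data.frame(participant = participant_id, trial = tr,
                             onset_ms = plan$onset_ms,
                             magnitude_pct = plan$magnitude_pct,
                             direction = dir_lab,
                             in_window = plan$onset_ms >= lat$support[1] &
                               plan$onset_ms <= lat$support[2],
                             stringsAsFactors = FALSE)
    }
  }

  set.seed(cal_seed)
  calibration <- generate_calibration(
    item_eccentricity_deg = config$item_eccentricity_deg,
    raw_center = config$raw_center,
    raw_gain = config$raw_gain,
    cal_noise_deg = config$cal_noise_deg,
    sampling_rate = fs)

  gt <- do.call(rbind, gt[!vapply(gt, is.null, logical(1))])
  if (is.null(gt))
    gt <- data.frame(participant = integer(), trial = integer(),
                     onset_ms = numeric(), magnitude_pct = numeric(),
                     direction = character(), in_window = logical())
  list(participant = list(trials = trials, calibration = calibration,
                          meta = do.call(rbind, meta)),
       ground_truth = gt)
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d participants x %d trials (seed %d)\n",
              length(x$participants), x$config$n_trials, x$config$seed))
  cat(sprintf("  %d injected gaze shifts (%d in the 200-600 ms window)\n",
              nrow(x$ground_truth), sum(x$ground_truth$in_window)))
  invisible(x)
}

#' Collect per-trial metadata of a study
#'
#' @param study A `synthetic_study`.
#' @return Data frame with one row per trial (participant, trial, cued side,
#'   true class, behavioural outcomes, programmed modulation onset).
#' @export
study_meta <- function(study) {
  do.call(rbind, lapply(study$participants, function(p) p$meta))
}

#' Write a synthetic study to a directory of plain-text files
#'
#' Layout: `config.json`, `ground_truth.csv`, and per participant
#' `p<i>_meta.csv`, `p<i>_calibration.csv`, `p<i>_trials.csv` (long format:
#' trial, time_ms, lx, ly, rx, ry, eeg_contra, eeg_ipsi).
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- study$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  data.table::fwrite(study$ground_truth, file.path(dir, "ground_truth.csv"))
  for (p in seq_along(study$participants)) {
    pp <- study$participants[[p]]
    data.table::fwrite(pp$meta, file.path(dir, sprintf("p%d_meta.csv", p)))
    cal <- cbind(pp$calibration$samples,
                 onset_ms_of_label = pp$calibration$onsets$onset_ms[
                   match(pp$calibration$samples$label,
                         pp$calibration$onsets$label)])
    data.table::fwrite(cal, file.path(dir, sprintf("p%d_calibration.csv", p)))
    long <- data.table::rbindlist(lapply(seq_along(pp$trials), function(tr) {
      t <- pp$trials[[tr]]
      data.table::data.table(trial = tr, time_ms = t$time_ms,
                             lx = t$lx, ly = t$ly, rx = t$rx, ry = t$ry,
                             eeg_contra = t$eeg_contra,
                             eeg_ipsi = t$eeg_ipsi)
    }))
    data.table::fwrite(long, file.path(dir, sprintf("p%d_trials.csv", p)))
  }
  invisible(dir)
}

#' Read a study written by [write_study()]
#'
#' @param dir Directory containing the study files.
#' @return A `synthetic_study` (without ground-truth-free trials' regenerated
#'   randomness: the data are read back exactly as written).
#' @export
read_study <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  cfg$behaviour$error_mean <- unlist(cfg$behaviour$error_mean)
  class(cfg) <- "study_config"
  gt <- as.data.frame(data.table::fread(file.path(dir, "ground_truth.csv")))
  n_p <- cfg$n_participants
  participants <- vector("list", n_p)
  for (p in seq_len(n_p)) {
    meta <- as.data.frame(data.table::fread(
      file.path(dir, sprintf("p%d_meta.csv", p))))
    calsamp <- as.data.frame(data.table::fread(
      file.path(dir, sprintf("p%d_calibration.csv", p))))
    onsets <- unique(calsamp[, c("label", "onset_ms_of_label")])
    names(onsets) <- c("label", "onset_ms")
    cal <- list(samples = calsamp[, c("time_ms", "label", "lx", "ly",
                                      "rx", "ry")],
                onsets = onsets, nominal = NULL)
    class(cal) <- "calibration_recording"
    long <- data.table::fread(file.path(dir, sprintf("p%d_trials.csv", p)))
    trials <- lapply(split(long, long$trial), function(d) {
      list(time_ms = d$time_ms, lx = d$lx, ly = d$ly, rx = d$rx, ry = d$ry,
           eeg_contra = d$eeg_contra, eeg_ipsi = d$eeg_ipsi,
           cued_side = meta$cued_side[meta$trial == d$trial[1]])
    })
    trials <- trials[order(as.integer(names(trials)))]
    participants[[p]] <- list(trials = trials, calibration = cal, meta = meta)
  }
  out <- list(config = cfg, participants = participants, ground_truth = gt)
  class(out) <- "synthetic_study"
  out
}
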