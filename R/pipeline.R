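# End-to-end analysis: preprocess -> detect -> classify -> lateralize per
# class -> permutation statistics, mirroring the study's analysis graph on
# synthetic or user data. Analysis never reads the generator's ground truth.

preprocess_and_classify <- function(participant, participant_id,
                                    classify_window_ms, extended_window) {
  ref <- build_calibration_reference(participant$calibration)
  trials <- participant$trials
  rows <- vector("list", length(trials))
  events_by_trial <- vector("list", length(trials))
  for (tr in seq_along(trials)) {
    t <- trials[[tr]]
    cyc <- merge_eyes(t$lx, t$rx)
    cyc <- mask_blinks(cyc)
    xn <- normalize_gaze(cyc, ref, "x")
    ep <- gaze_epoch(t$time_ms, xn, t$cued_side)
    usable <- mark_usable(ep)
    cls <- "unusable"; lat <- NA_real_
    ev <- NULL
    if (usable) {
      v <- compute_velocity(ep)
      ev <- detect_shifts(v, ep)
      ev <- label_direction(ev, t$cued_side)
      tc <- classify_trial(ev, usable, classify_window_ms)
      cls <- tc$class
      lat <- tc$first_shift_latency_ms
      if (extended_window && cls == "none" && nrow(ev) > 0L &&
          any(ev$onset_ms >= 0 & ev$onset_ms <= classify_window_ms[2]))
        cls <- "unusable"
    }
    events_by_trial[[tr]] <- ev
    rows[[tr]] <- data.frame(participant = participant_id, trial = tr,
                             cued_side = t$cued_side, usable = usable,
                             class = cls, first_shift_latency_ms = lat,
                             stringsAsFactors = FALSE)
  }
  list(trials_df = do.call(rbind, rows), events = events_by_trial)
}

class_timecourse_matrix <- function(study, trials_df, class_name,
                                    step_ms, band_hz, freqs_hz) {
  n_p <- length(study$participants)
  rows <- vector("list", n_p)
  time_ms <- NULL
  for (p in seq_len(n_p)) {
    ids <- trials_df$trial[trials_df$participant == p &
                             trials_df$class == class_name]
    if (length(ids) == 0L) next
    tc <- condition_alpha_timecourse(study$participants[[p]]$trials[ids],
                                     freqs_hz = freqs_hz,
                                     step_ms = step_ms, band_hz = band_hz)
    time_ms <- tc$time_ms
    rows[[p]] <- tc$lateralization_pct
  }
  present <- which(!vapply(rows, is.null, logical(1)))
  if (length(present) == 0L) return(NULL)
  mat <- do.call(rbind, rows[present])
  rownames(mat) <- present
  list(time_ms = time_ms, matrix = mat, participants = present)
}

#' Run the full study analysis
#'
#' Executes every stage on a synthetic study (or a [study_config()], which
#' is generated first): calibration-based normalization, blink masking,
#' velocity-threshold shift detection, trial classification by the first
#' in-window shift, behavioural trimming and class comparisons, per-class
#' alpha lateralization time courses with cluster-based permutation tests
#' against zero, paired toward-vs-none and toward-vs-away comparisons, the
#' per-participant early/late median latency split with the half-peak
#' latency permutation test, and shift-rate summaries. Deterministic given
#' the study's seed. Ground truth is never consulted.
#'
#' @param study A `synthetic_study` or `study_config`.
#' @param n_permutations Permutations for all permutation tests.
#' @param band_hz Alpha band, Hz.
#' @param freqs_hz Frequency axis of the TFR, Hz.
#' @param tfr_step_ms STFT hop for the standard time courses, ms.
#' @param latency_step_ms STFT hop for the latency analysis, ms.
#' @param classify_window_ms Classification window, ms.
#' @param extended_window Also exclude from the no-microsaccade class any
#'   trial with a detected shift anywhere in 0-600 ms (robustness check).
#' @param half_peak_window_ms Search window for half-peak latencies, ms.
#' @return Object of class `analysis_report`.
#' @export
run_study_analysis <- function(study,
                               n_permutations = 1000,
                               band_hz = c(8, 12),
                               freqs_hz = 1:50,
                               tfr_step_ms = 50,
                               latency_step_ms = 1,
                               classify_window_ms = c(200, 600),
                               extended_window = FALSE,
                               half_peak_window_ms = c(0, 1000)) {
  if (inherits(study, "study_config")) study <- generate_study(study)
  stopifnot(inherits(study, "synthetic_study"))
  set.seed(study$config$seed)

  # --- stage: preprocess + detect + classify -----------------------------
  prep <- lapply(seq_along(study$participants), function(p)
    tryCatch(
      preprocess_and_classify(study$participants[[p]], p,
                              classify_window_ms, extended_window),
      error = function(e) stop(sprintf("preprocessing stage failed for participant %d: %s",
                                       p, conditionMessage(e)), call. = FALSE)))
  trials_df <- do.call(rbind, lapply(prep, function(x) x$trials_df))
  events <- lapply(prep, function(x) x$events)

  usable_df <- trials_df[trials_df$usable & trials_df$class != "unusable", ]
  counts <- table(factor(usable_df$class,
                         levels = c("toward", "away", "none")))
  proportions <- as.numeric(counts) / max(1L, nrow(usable_df))
  names(proportions) <- names(counts)

  # --- stage: behaviour --------------------------------------------------
  meta <- study_meta(study)
  beh <- merge(usable_df[, c("participant", "trial", "class")],
               meta[, c("participant", "trial", "error_deg", "rt_ms")],
               by = c("participant", "trial"))
  beh_trim <- trim_behaviour(beh)
  behaviour <- tryCatch(behaviour_class_stats(beh_trim),
                        error = function(e) {
                          warning("behaviour stage skipped: ",
                                  conditionMessage(e))
                          NULL
                        })

  # --- stage: per-class lateralization + cluster tests -------------------
  timecourses <- list()
  cluster_tests <- list()
  for (cls in c("toward", "none", "away")) {
    tcm <- class_timecourse_matrix(study, usable_df, cls,
                                   tfr_step_ms, band_hz, freqs_hz)
    timecourses[[cls]] <- tcm
    cluster_tests[[cls]] <- if (!is.null(tcm) && nrow(tcm$matrix) >= 2L)
      suppressMessages(cluster_permutation_test(tcm$matrix,
                                                n_permutations = n_permutations))
    else NULL
  }

  report <- structure(list(
    trials = trials_df,
    class_counts = counts,
    class_proportions = proportions,
    behaviour = behaviour,
    timecourses = timecourses,
    cluster_tests = cluster_tests,
    band_hz = band_hz,
    n_permutations = n_permutations,
    provenance = list(seed = study$config$seed,
                      config_hash = config_hash(study$config),
                      package_version = as.character(
                        utils::packageVersion("gazealpha")),
                      n_participants = length(study$participants))),
    class = "analysis_report")

  # --- stage: condition overlays -----------------------------------------
  report$comparisons <- list(
    toward_vs_none = tryCatch(
      compare_conditions(report, c("toward", "none"), n_permutations),
      error = function(e) NULL),
    toward_vs_away = tryCatch(
      compare_conditions(report, c("toward", "away"), n_permutations),
      error = function(e) NULL))

  # --- stage: early/late latency analysis --------------------------------
  report$latency <- tryCatch(
    latency_analysis(study, usable_df, band_hz, freqs_hz, latency_step_ms,
                     half_peak_window_ms, n_permutations),
    error = function(e) {
      warning("latency stage skipped: ", conditionMessage(e))
      NULL
    })

  # --- stage: rate summaries ---------------------------------------------
  report$rates <- rate_summaries(trials_df, events)
  report
}

latency_analysis <- function(study, usable_df, band_hz, freqs_hz,
                             step_ms, half_peak_window_ms, n_permutations) {
  tow <- usable_df[usable_df$class == "toward", ]
  lat <- data.frame(participant = tow$participant, trial = tow$trial,
                    latency_ms = tow$first_shift_latency_ms)
  split <- split_by_latency(lat)
  parts <- sort(unique(split$participant))
  early <- list(); late <- list(); time_ms <- NULL
  keep <- integer(0)
  for (p in parts) {
    ids_e <- split$trial[split$participant == p & split$half == "early"]
    ids_l <- split$trial[split$participant == p & split$half == "late"]
    if (length(ids_e) == 0L || length(ids_l) == 0L) next
    tc_e <- condition_alpha_timecourse(
      study$participants[[p]]$trials[ids_e], freqs_hz = band_freqs(band_hz),
      step_ms = step_ms, band_hz = band_hz)
    tc_l <- condition_alpha_timecourse(
      study$participants[[p]]$trials[ids_l], freqs_hz = band_freqs(band_hz),
      step_ms = step_ms, band_hz = band_hz)
    time_ms <- tc_e$time_ms
    early[[length(early) + 1L]] <- tc_e$lateralization_pct
    late[[length(late) + 1L]] <- tc_l$lateralization_pct
    keep <- c(keep, p)
  }
  if (length(keep) < 2L)
    stop("fewer than 2 participants with both early and late toward trials")
  early <- do.call(rbind, early)
  late <- do.call(rbind, late)
  test <- latency_permutation_test(early, late, time_ms,
                                   n_permutations = n_permutations,
                                   window_ms = half_peak_window_ms)
  list(split = split, participants = keep, time_ms = time_ms,
       early = early, late = late, test = test)
}

# frequency rows needed when only the band time course is required
band_freqs <- function(band_hz) seq(band_hz[1], band_hz[2])

rate_summaries <- function(trials_df, events, time_range_ms = c(-200, 1000)) {
  usable <- trials_df$usable
  n_usable <- sum(usable)
  if (n_usable == 0L) return(NULL)
  ev_all <- list()
  for (p in seq_along(events)) {
    sel <- trials_df$participant == p & trials_df$usable
    ids <- trials_df$trial[sel]
    for (tr in ids) {
      e <- events[[p]][[tr]]
      if (!is.null(e) && nrow(e) > 0L) ev_all[[length(ev_all) + 1L]] <- e
    }
  }
  ev <- if (length(ev_all) > 0L) do.call(rbind, ev_all)
  else data.frame(onset_ms = numeric(), magnitude_pct = numeric(),
                  direction = character())
  tw <- ev[ev$direction == "toward", ]
  aw <- ev[ev$direction == "away", ]
  map_t <- rate_magnitude_map(tw, n_usable, time_range_ms)
  map_a <- rate_magnitude_map(aw, n_usable, time_range_ms)
  list(
    toward = shift_rate_timecourse(tw$onset_ms, n_usable, time_range_ms),
    away = shift_rate_timecourse(aw$onset_ms, n_usable, time_range_ms),
    map_toward = map_t, map_away = map_a,
    map_difference = rate_map_difference(map_t, map_a))
}

#' Paired comparison of two condition time courses
#'
#' Runs a paired cluster-based permutation test on the difference of the
#' alpha lateralization time courses of two trial classes, using the
#' participants for which both classes are present (others are dropped with
#' a warning).
#'
#' @param report An `analysis_report`.
#' @param pair Character vector of two class names (toward / none / away).
#' @param n_permutations Permutations.
#' @return List with `pair`, `participants`, `time_ms`, the two
#'   participant x time matrices, and `test` (a `cluster_test`).
#' @export
compare_conditions <- function(report, pair = c("toward", "none"),
                               n_permutations = 1000) {
  a <- report$timecourses[[pair[1]]]
  b <- report$timecourses[[pair[2]]]
  if (is.null(a) || is.null(b))
    stop("input error: both conditions need at least one participant")
  common <- intersect(a$participants, b$participants)
  dropped <- setdiff(union(a$participants, b$participants), common)
  if (length(dropped) > 0L)
    warning(sprintf("%d unpaired participant(s) dropped from %s vs %s",
                    length(dropped), pair[1], pair[2]))
  if (length(common) < 2L)
    stop("input error: fewer than 2 paired participants")
  ma <- a$matrix[match(common, a$participants), , drop = FALSE]
  mb <- b$matrix[match(common, b$participants), , drop = FALSE]
  test <- suppressMessages(
    cluster_permutation_test(ma, mb, n_permutations = n_permutations))
  list(pair = pair, participants = common, time_ms = a$time_ms,
       matrix_a = ma, matrix_b = mb, test = test)
}

config_hash <- function(config) {
  cfg <- config
  class(cfg) <- NULL
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Attention-study analysis report\n")
  cat(sprintf("  %d participants, %d trials (%d usable)\n",
              x$provenance$n_participants, nrow(x$trials),
              sum(x$trials$usable)))
  pr <- x$class_proportions * 100
  cat(sprintf("  classes: toward %.1f%%, away %.1f%%, none %.1f%% of usable\n",
              pr[["toward"]], pr[["away"]], pr[["none"]]))
  for (cls in names(x$cluster_tests)) {
    ct <- x$cluster_tests[[cls]]
    if (is.null(ct)) next
    p <- if (nrow(ct$clusters) > 0L) sprintf("min cluster p = %.4g",
                                             min(ct$clusters$p))
    else "no clusters"
    cat(sprintf("  %s lateralization: %s\n", cls, p))
  }
  if (!is.null(x$latency))
    cat(sprintf("  latency: early %.0f ms, late %.0f ms, diff %.0f ms, p = %.4g\n",
                x$latency$test$half_peak_early, x$latency$test$half_peak_late,
                x$latency$test$observed_diff_ms, x$latency$test$p))
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' Writes the report's scalar results (class counts and proportions,
#' behavioural statistics, cluster masses and p-values, latency test, and
#' provenance) as a JSON file; matrices and trial tables are omitted.
#'
#' @param report An `analysis_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  ct_json <- function(ct) {
    if (is.null(ct)) return(NULL)
    list(clusters = ct$clusters, n_permutations = ct$n_permutations,
         exhaustive = ct$exhaustive)
  }
  out <- list(
    class_counts = as.list(report$class_counts),
    class_proportions = as.list(report$class_proportions),
    behaviour = if (!is.null(report$behaviour)) list(
      error = list(class_means = as.list(report$behaviour$error$class_means),
                   anova = report$behaviour$error$anova[
                     c("F", "df1", "df2", "p", "partial_eta_sq")],
                   pairwise = report$behaviour$error$pairwise),
      rt = list(class_means = as.list(report$behaviour$rt$class_means),
                anova = report$behaviour$rt$anova[
                  c("F", "df1", "df2", "p", "partial_eta_sq")],
                pairwise = report$behaviour$rt$pairwise)),
    cluster_tests = lapply(report$cluster_tests, ct_json),
    comparisons = lapply(report$comparisons, function(cc)
      if (!is.null(cc)) ct_json(cc$test)),
    latency = if (!is.null(report$latency)) report$latency$test[
      c("half_peak_early", "half_peak_late", "observed_diff_ms", "p",
        "n_permutations")],
    provenance = report$provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
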