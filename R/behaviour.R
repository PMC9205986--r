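# Behavioural trimming and per-class comparisons: two-step RT trimming,
# one-way repeated-measures ANOVA with partial eta squared, and
# Bonferroni-corrected paired t-tests with Cohen's d.

#' Trim behavioural trials
#'
#' Two-step procedure: first, trials with reaction times longer than
#' `rt_cutoff_ms` (3000 ms) are excluded; second, trials whose RT lies more
#' than `sd_cutoff` (2.5) standard deviations from the participant's mean RT
#' -- mean and SD computed on the first step's survivors -- are excluded.
#' The procedure is order-dependent by construction (absolute cutoff first,
#' SD trim second). The returned data frame carries a `behaviour_trimmed`
#' attribute and re-applying the procedure returns it unchanged: the SD trim
#' is defined on the untrimmed sample, so re-estimating it on already
#' trimmed data would silently tighten the criterion.
#'
#' @param trials Data frame with columns `participant` and `rt_ms`.
#' @param rt_cutoff_ms Absolute RT cutoff, ms.
#' @param sd_cutoff SD multiple for the per-participant trim.
#' @return The retained rows of `trials`.
#' @export
trim_behaviour <- function(trials, rt_cutoff_ms = 3000, sd_cutoff = 2.5) {
  if (isTRUE(attr(trials, "behaviour_trimmed"))) return(trials)
  step1 <- trials[trials$rt_ms <= rt_cutoff_ms, , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(step1)), step1$participant),
                        function(idx) {
    rt <- step1$rt_ms[idx]
    m <- mean(rt)
    s <- stats::sd(rt)
    if (!is.finite(s) || s == 0) return(idx)
    idx[abs(rt - m) <= sd_cutoff * s]
  }), use.names = FALSE)
  out <- step1[sort(keep), , drop = FALSE]
  attr(out, "behaviour_trimmed") <- TRUE
  out
}

# one-way repeated-measures ANOVA on participant x condition cell means
rm_anova <- function(d, value_col) {
  cell <- stats::aggregate(d[[value_col]],
                           list(participant = d$participant,
                                class = d$class), mean)
  names(cell)[3] <- "value"
  wide <- stats::reshape(cell, idvar = "participant", timevar = "class",
                         direction = "wide")
  classes <- sort(unique(cell$class))
  k <- length(classes)
  n <- nrow(wide)
  m <- as.matrix(wide[, paste0("value.", classes)])
  grand <- mean(m)
  ss_class <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_class - ss_subj
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  ms_class <- ss_class / df1
  ms_err <- ss_err / df2
  # no between-class variation at all carries no evidence against the null
  f <- if (ms_class <= .Machine$double.eps) 0 else ms_class / ms_err
  if (!is.finite(f)) f <- 0
  eta <- if (ss_class + ss_err <= .Machine$double.eps) 0
         else ss_class / (ss_class + ss_err)
  list(F = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE),
       partial_eta_sq = eta,
       cell_means = stats::setNames(colMeans(m), classes))
}

#' Per-class behavioural statistics
#'
#' Computes per-class means of reproduction error and reaction time over
#' participant cell means, a one-way repeated-measures ANOVA across the
#' classes toward / none / away (with partial eta squared), and
#' Bonferroni-corrected two-sided paired t-tests with Cohen's d for paired
#' samples for every class pair. Participants missing any class after
#' trimming are dropped with a warning.
#'
#' @param trials Data frame with columns `participant`, `class` (toward /
#'   none / away), `error_deg`, `rt_ms`; typically the output of
#'   [trim_behaviour()] restricted to classified trials.
#' @return Object of class `behaviour_stats`: per-measure list with
#'   `class_means`, `anova` (F, dfs, p, partial_eta_sq), and `pairwise`
#'   (data frame with t, df, raw and Bonferroni p, Cohen's d).
#' @export
behaviour_class_stats <- function(trials) {
  classes <- intersect(c("toward", "none", "away"), unique(trials$class))
  trials <- trials[trials$class %in% classes, , drop = FALSE]
  have <- table(trials$participant, trials$class) > 0
  complete <- rownames(have)[rowSums(have) == length(classes)]
  if (length(complete) < length(unique(trials$participant)))
    warning(sprintf("%d participant(s) dropped: missing a trial class",
                    length(unique(trials$participant)) - length(complete)))
  trials <- trials[trials$participant %in% complete, , drop = FALSE]
  if (length(complete) < 2L)
    stop("input error: need at least 2 participants with all classes")

  one_measure <- function(value_col) {
    an <- rm_anova(trials, value_col)
    cell <- stats::aggregate(trials[[value_col]],
                             list(participant = trials$participant,
                                  class = trials$class), mean)
    names(cell)[3] <- "value"
    pairs <- utils::combn(classes, 2, simplify = FALSE)
    n_comp <- length(pairs)
    pw <- do.call(rbind, lapply(pairs, function(pr) {
      a <- cell$value[cell$class == pr[1]][order(cell$participant[cell$class == pr[1]])]
      b <- cell$value[cell$class == pr[2]][order(cell$participant[cell$class == pr[2]])]
      d <- a - b
      if (stats::sd(d) <= .Machine$double.eps) {
        # identical conditions: no paired evidence
        return(data.frame(pair = paste(pr, collapse = " vs "),
                          t = 0, df = length(d) - 1, p = 1,
                          p_bonferroni = 1, cohens_d = 0))
      }
      tt <- stats::t.test(a, b, paired = TRUE)
      data.frame(pair = paste(pr, collapse = " vs "),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value,
                 p_bonferroni = min(1, tt$p.value * n_comp),
                 cohens_d = mean(d) / stats::sd(d))
    }))
    list(class_means = an$cell_means, anova = an, pairwise = pw)
  }

  structure(list(error = one_measure("error_deg"),
                 rt = one_measure("rt_ms"),
                 n_participants = length(complete)),
            class = "behaviour_stats")
}

#' @export
print.behaviour_stats <- function(x, ...) {
  cat(sprintf("Behavioural class statistics (%d participants)\n",
              x$n_participants))
  for (m in c("error", "rt")) {
    s <- x[[m]]
    lab <- if (m == "error") "reproduction error (deg)" else "reaction time (ms)"
    cat(sprintf("  %s: %s\n", lab,
                paste(sprintf("%s %.2f", names(s$class_means),
                              s$class_means), collapse = ", ")))
    cat(sprintf("    F(%d, %d) = %.2f, p = %.3g, partial eta^2 = %.3f\n",
                s$anova$df1, s$anova$df2, s$anova$F, s$anova$p,
                s$anova$partial_eta_sq))
  }
  invisible(x)
}
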