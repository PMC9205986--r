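# Independent reference implementations used as oracles: a naive
# sample-by-sample gaze-shift detector and an exhaustive sign-flip cluster
# test, both written as plain loops with no code shared with the package.

oracle_detect <- function(x, time_ms, multiplier = 3, refractory = 100,
                          floor_pct = 1) {
  n <- length(x)
  # velocity: |first difference|, then Gaussian weights over 7 samples
  v <- rep(NA_real_, n)
  for (i in 2:n) v[i] <- abs(x[i] - x[i - 1])
  w <- exp(-(-3:3)^2 / (2 * 1.4^2))
  w <- w / sum(w)
  sv <- rep(NA_real_, n)
  for (i in 4:(n - 3)) sv[i] <- sum(w * v[(i - 3):(i + 3)])
  thr <- multiplier * median(sv[is.finite(sv)])

  above <- function(j) is.finite(sv[j]) && sv[j] > thr
  events <- data.frame(onset_ms = numeric(), magnitude_pct = numeric())
  last_kept <- -Inf
  for (j in seq_len(n)) {
    if (!above(j)) next
    if (j > 1 && above(j - 1)) next          # not a run start
    if (time_ms[j] - last_kept <= refractory) next
    last_kept <- time_ms[j]
    if (time_ms[j] - 50 < time_ms[1] || time_ms[j] + 100 > time_ms[n]) next
    pre <- x[time_ms >= time_ms[j] - 50 & time_ms <= time_ms[j]]
    post <- x[time_ms >= time_ms[j] + 50 & time_ms <= time_ms[j] + 100]
    pre <- pre[is.finite(pre)]
    post <- post[is.finite(post)]
    if (length(pre) == 0 || length(post) == 0) next
    mag <- mean(post) - mean(pre)
    if (abs(mag) < floor_pct) next
    events <- rbind(events,
                    data.frame(onset_ms = time_ms[j], magnitude_pct = mag))
  }
  events
}

# exhaustive sign-flip cluster test by brute force (1-D adjacency)
oracle_cluster_test <- function(x, alpha = 0.05) {
  n <- nrow(x)
  P <- ncol(x)
  thr <- qt(1 - alpha / 2, n - 1)
  tstat <- function(m) {
    sapply(seq_len(ncol(m)), function(j) {
      tt <- t.test(m[, j])
      unname(tt$statistic)
    })
  }
  clusters_of <- function(tv) {
    out <- list()
    j <- 1
    while (j <= P) {
      if (is.finite(tv[j]) && abs(tv[j]) > thr) {
        s <- sign(tv[j])
        k <- j
        while (k < P && is.finite(tv[k + 1]) && abs(tv[k + 1]) > thr &&
               sign(tv[k + 1]) == s) k <- k + 1
        out[[length(out) + 1]] <- list(members = j:k, mass = sum(tv[j:k]))
        j <- k + 1
      } else j <- j + 1
    }
    out
  }
  t_obs <- tstat(x)
  obs <- clusters_of(t_obs)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  maxs <- apply(signs, 1, function(s) {
    cl <- clusters_of(tstat(x * s))
    if (length(cl) == 0) 0 else max(sapply(cl, function(c) abs(c$mass)))
  })
  list(clusters = obs,
       p = sapply(obs, function(c) mean(maxs >= abs(c$mass) - 1e-8)))
}

# brute-force union of intervals extended by pad on each side (sample index)
oracle_extend_nan <- function(isna, pad) {
  out <- rep(FALSE, length(isna))
  for (i in which(isna)) {
    lo <- max(1, i - pad)
    hi <- min(length(isna), i + pad)
    out[lo:hi] <- TRUE
  }
  out
}
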