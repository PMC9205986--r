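# Cluster-based permutation test for participant x time (or time x
# frequency) data: mass-univariate t-tests, clusters of adjacent same-signed
# supra-threshold points (4-neighbour adjacency on 2-D grids, no diagonals),
# cluster mass = sum of t-values, and a permutation distribution of the
# largest absolute cluster mass built from participant-level sign flips
# (one-sample) or condition-label swaps (paired; equivalent to sign flips of
# the paired differences).

col_t_stats <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  v <- (colSums(m^2) - n * mu^2) / (n - 1)
  t <- mu / sqrt(v / n)
  # degenerate columns (zero variance, e.g. all-zero data) carry no evidence
  t[!is.finite(t)] <- 0
  t
}

# clusters of a t-vector/grid: list(mass, members) per cluster
find_clusters <- function(tvec, thr, dims = NULL) {
  if (is.null(dims) || length(dims) == 1L) {
    code <- integer(length(tvec))
    code[tvec > thr] <- 1L
    code[tvec < -thr] <- -1L
    r <- rle(code)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values != 0L)
    lapply(keep, function(i) {
      mem <- starts[i]:ends[i]
      list(mass = sum(tvec[mem]), members = mem)
    })
  } else {
    out <- list()
    for (sgn in c(1, -1)) {
      mask <- if (sgn > 0) tvec > thr else tvec < -thr
      if (!any(mask)) next
      lab <- label_components(mask, dims)
      for (l in unique(lab[lab > 0])) {
        mem <- which(lab == l)
        out[[length(out) + 1L]] <- list(mass = sum(tvec[mem]), members = mem)
      }
    }
    out
  }
}

# connected components (4-neighbour) of a logical grid stored column-major
# in a vector; returns integer labels (0 outside the mask)
label_components <- function(mask, dims) {
  nr <- dims[1]; nc <- dims[2]
  m <- matrix(mask, nr, nc)
  L <- matrix(Inf, nr, nc)
  L[m] <- seq_len(sum(m))
  shift <- function(M, dr, dc) {
    out <- matrix(Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- M[rs - dr, cs - dc, drop = FALSE]
    out
  }
  repeat {
    cand <- pmin(L, shift(L, 1, 0), shift(L, -1, 0),
                 shift(L, 0, 1), shift(L, 0, -1))
    cand[!m] <- Inf
    if (identical(cand, L)) break
    L <- cand
  }
  lab <- matrix(0L, nr, nc)
  lab[m] <- as.integer(as.factor(L[m]))
  as.vector(lab)
}

# largest |cluster mass| of each row of a B x P t-matrix (1-D adjacency)
row_max_cluster_mass_1d <- function(tmat, thr) {
  B <- nrow(tmat); P <- ncol(tmat)
  curp <- numeric(B); curn <- numeric(B); best <- numeric(B)
  for (j in seq_len(P)) {
    tj <- tmat[, j]
    pos <- tj > thr
    neg <- tj < -thr
    curp <- ifelse(pos, curp + tj, 0)
    curn <- ifelse(neg, curn + tj, 0)
    best <- pmax(best, curp, -curn)
  }
  best
}

max_cluster_mass <- function(tvec, thr, dims) {
  cl <- find_clusters(tvec, thr, dims)
  if (length(cl) == 0L) return(0)
  max(abs(vapply(cl, function(c) c$mass, numeric(1))))
}

#' Cluster-based permutation test
#'
#' Tests a participants x points data matrix against zero (`y = NULL`) or
#' against a paired condition (`y` of the same shape; the test is then run
#' on the paired differences, label swaps being equivalent to sign flips of
#' the differences). Points may be a 1-D time axis (matrix input) or a 2-D
#' time x frequency grid (3-D array input, participants x time x frequency).
#'
#' Points significant in a mass-univariate two-sided t-test at
#' `cluster_alpha` are grouped into clusters of adjacent same-signed points;
#' cluster mass is the sum of t-values. The permutation distribution
#' collects the largest absolute cluster mass under participant-level sign
#' flips; each observed cluster's p-value is the proportion of permutations
#' whose largest mass reaches the cluster's absolute mass. When the
#' requested number of permutations is at least the number of distinct
#' relabellings (2^n), all relabellings are enumerated instead (with a
#' message) and the p-value is the exact proportion; otherwise random flips
#' are drawn and the (b+1)/(B+1) convention keeps p-values positive.
#'
#' @param x Numeric matrix (participants x points) or 3-D array
#'   (participants x time x frequency).
#' @param y Optional paired data of the same shape.
#' @param n_permutations Requested number of permutations.
#' @param cluster_alpha Two-sided alpha of the cluster-forming t-threshold.
#' @return Object of class `cluster_test`: `clusters` (data frame with
#'   `mass`, `n_points`, `p`, and 1-D extents `start`/`end` in point
#'   indices), `members` (list of member indices), `t` (observed t-values),
#'   `threshold`, `n_permutations`, `exhaustive`, `perm_max` (the
#'   permutation distribution).
#' @export
cluster_permutation_test <- function(x, y = NULL, n_permutations = 10000,
                                     cluster_alpha = 0.05) {
  dims <- NULL
  if (length(dim(x)) == 3L) {
    dims <- dim(x)[2:3]
    x <- matrix(x, nrow = dim(x)[1])
    if (!is.null(y)) y <- matrix(y, nrow = dim(y)[1])
  }
  x <- as.matrix(x)
  if (!is.null(y)) {
    stopifnot(identical(dim(as.matrix(y)), dim(x)))
    x <- x - as.matrix(y)
  }
  n <- nrow(x)
  if (n < 2L) stop("input error: need at least 2 participants")
  P <- ncol(x)
  thr <- stats::qt(1 - cluster_alpha / 2, df = n - 1)

  t_obs <- col_t_stats(x)
  clusters <- find_clusters(t_obs, thr, dims)

  exhaustive <- 2^n <= n_permutations
  if (exhaustive) {
    message(sprintf(
      "enumerating all %d sign flips exhaustively (requested %d permutations)",
      2^n, n_permutations))
    S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    dimnames(S) <- NULL
  } else {
    S <- matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
                nrow = n_permutations)
  }
  B <- nrow(S)

  ssq <- colSums(x^2)
  perm_max <- numeric(B)
  chunk <- max(1L, floor(2e6 / P))
  for (lo in seq(1L, B, by = chunk)) {
    hi <- min(B, lo + chunk - 1L)
    M <- S[lo:hi, , drop = FALSE] %*% x / n
    V <- sweep(-n * M^2, 2, ssq, "+") / (n - 1)
    Tm <- M / sqrt(V / n)
    Tm[!is.finite(Tm)] <- 0
    if (is.null(dims)) {
      perm_max[lo:hi] <- row_max_cluster_mass_1d(Tm, thr)
    } else {
      for (b in seq_len(nrow(Tm)))
        perm_max[lo + b - 1L] <- max_cluster_mass(Tm[b, ], thr, dims)
    }
  }

  if (length(clusters) > 0L) {
    ord <- order(-abs(vapply(clusters, function(c) c$mass, numeric(1))))
    clusters <- clusters[ord]
    masses <- vapply(clusters, function(c) c$mass, numeric(1))
    pvals <- vapply(masses, function(m) {
      # tolerance guards against summation-order rounding between the
      # permutation sweep and the observed cluster sums
      tol <- 1e-8 * max(1, abs(m))
      b <- sum(perm_max >= abs(m) - tol)
      if (exhaustive) b / B else (b + 1) / (B + 1)
    }, numeric(1))
    cl_df <- data.frame(
      mass = masses,
      n_points = vapply(clusters, function(c) length(c$members), integer(1)),
      start = vapply(clusters, function(c) min(c$members), numeric(1)),
      end = vapply(clusters, function(c) max(c$members), numeric(1)),
      p = pvals)
    members <- lapply(clusters, function(c) c$members)
  } else {
    cl_df <- data.frame(mass = numeric(), n_points = integer(),
                        start = numeric(), end = numeric(), p = numeric())
    members <- list()
  }
  structure(list(clusters = cl_df, members = members, t = t_obs,
                 threshold = thr, n_permutations = B,
                 exhaustive = exhaustive, dims = dims,
                 perm_max = perm_max),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf(
    "Cluster-based permutation test (%d permutations%s, |t| > %.2f)\n",
    x$n_permutations, if (x$exhaustive) ", exhaustive" else "", x$threshold))
  if (nrow(x$clusters) == 0L) {
    cat("  no supra-threshold clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters)))
      cat(sprintf("  cluster %d: mass %.1f over %d points, p = %.4g\n",
                  i, x$clusters$mass[i], x$clusters$n_points[i],
                  x$clusters$p[i]))
  }
  invisible(x)
}
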