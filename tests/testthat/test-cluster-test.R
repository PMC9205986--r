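# Cluster-based permutation test: degenerate inputs, forced effects,
# exhaustive-oracle equivalence, paired mode, and 2-D adjacency.

test_that("all-zero data yield no supra-threshold clusters", {
  x <- matrix(0, 8, 20)
  ct <- suppressMessages(cluster_permutation_test(x, n_permutations = 300))
  expect_equal(nrow(ct$clusters), 0L)
})

test_that("a constant strong effect forms one axis-spanning cluster at the
          minimal attainable p", {
  set.seed(50)
  x <- matrix(5 + rnorm(6 * 15, 0, 0.1), 6, 15)
  ct <- suppressMessages(cluster_permutation_test(x, n_permutations = 100))
  expect_true(ct$exhaustive)
  expect_equal(nrow(ct$clusters), 1L)
  expect_equal(ct$clusters$n_points, 15L)
  # sign symmetry: the identity and the all-flipped relabelling both reach
  # the observed mass, so the exact p is 2 / 2^n
  expect_equal(ct$clusters$p, 2 / 2^6)
})

test_that("results match the brute-force exhaustive oracle", {
  set.seed(51)
  for (i in 1:5) {
    n <- sample(5:7, 1)
    x <- matrix(rnorm(n * 12, mean = rep(c(0, 0.9, 0), each = 4)),
                n, 12, byrow = TRUE)
    ct <- suppressMessages(cluster_permutation_test(x, n_permutations = 200))
    ref <- oracle_cluster_test(x)
    expect_equal(nrow(ct$clusters), length(ref$clusters))
    if (length(ref$clusters) > 0) {
      ord <- order(-abs(sapply(ref$clusters, function(c) c$mass)))
      expect_equal(ct$clusters$mass,
                   sapply(ref$clusters, function(c) c$mass)[ord],
                   tolerance = 1e-10)
      expect_equal(ct$clusters$p, ref$p[ord], tolerance = 1e-10)
    }
  }
})

test_that("paired mode equals the one-sample test on differences", {
  set.seed(52)
  a <- matrix(rnorm(8 * 10, 0.5), 8, 10)
  b <- matrix(rnorm(8 * 10), 8, 10)
  ct_paired <- suppressMessages(
    cluster_permutation_test(a, b, n_permutations = 300))
  ct_diff <- suppressMessages(
    cluster_permutation_test(a - b, n_permutations = 300))
  expect_equal(ct_paired$t, ct_diff$t)
  expect_equal(ct_paired$clusters$mass, ct_diff$clusters$mass)
  expect_equal(ct_paired$clusters$p, ct_diff$clusters$p)
})

test_that("2-D clusters respect 4-neighbour adjacency without diagonals", {
  n <- 8
  # off-block cells alternate sign across participants: mean (and t) exactly
  # zero, so only the two blocks can be supra-threshold
  arr <- array(rep(c(-1, 1), length.out = n), c(n, 6, 6))
  jitter <- 0.01 * seq_len(n)  # gives block cells a nonzero, finite t
  # two blocks touching only at a corner must stay separate clusters
  for (p in seq_len(n)) {
    arr[p, 1:2, 1:2] <- 5 + jitter[p]
    arr[p, 3:4, 3:4] <- 5 + jitter[p]
  }
  ct <- suppressMessages(cluster_permutation_test(arr, n_permutations = 200))
  expect_equal(nrow(ct$clusters), 2L)
  expect_true(all(ct$clusters$n_points == 4L))
})

test_that("permutation p-values are always positive and at most 1", {
  set.seed(54)
  for (i in 1:10) {
    x <- matrix(rnorm(6 * 30), 6, 30)
    ct <- suppressMessages(cluster_permutation_test(x, n_permutations = 100))
    if (nrow(ct$clusters) > 0) {
      expect_true(all(ct$clusters$p > 0))
      expect_true(all(ct$clusters$p <= 1))
    }
  }
})

test_that("random (non-exhaustive) mode uses the (b+1)/(B+1) convention", {
  set.seed(55)
  x <- matrix(5 + rnorm(15 * 10, 0, 0.1), 15, 10)
  ct <- cluster_permutation_test(x, n_permutations = 99)
  expect_false(ct$exhaustive)
  expect_equal(ct$clusters$p[1], 1 / 100)
})
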