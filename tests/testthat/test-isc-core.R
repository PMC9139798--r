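test_that("pairwise ISC matches a naive per-voxel Pearson oracle", {
  set.seed(42)
  run_data <- lapply(1:3, function(i) matrix(rnorm(10 * 25), 10, 25))
  got <- pairwise_isc_run(run_data)
  expect_equal(got, naive_pairwise_isc(run_data), tolerance = 1e-10)
})

test_that("hand-computed correlations come out exactly", {
  a <- matrix(c(1, 2, 3, 4, 5), 1)
  b <- matrix(c(2, 4, 6, 8, 10), 1)
  c <- matrix(c(5, 4, 3, 2, 1), 1)
  r <- pairwise_isc_run(list(a, b, c))
  expect_equal(as.numeric(r), c(1, -1, -1), tolerance = 1e-12)
})

test_that("a subject against an identical copy correlates perfectly", {
  set.seed(1)
  m <- matrix(rnorm(8 * 30), 8, 30)
  r <- pairwise_isc_run(list(m, m))
  expect_equal(as.numeric(r), rep(1, 8), tolerance = 1e-12)
})

test_that("24 subjects enumerate 276 lexicographic pairs", {
  p <- pair_index(sprintf("s%02d", 1:24))
  expect_equal(nrow(p), 276)
  expect_true(all(p$i < p$j))
  expect_equal(p$i[1:23], rep(1L, 23))
})

test_that("zero-variance voxels are flagged undefined, not propagated", {
  set.seed(2)
  a <- matrix(rnorm(3 * 20), 3, 20); a[2, ] <- 5
  b <- matrix(rnorm(3 * 20), 3, 20)
  r <- pairwise_isc_run(list(a, b))
  expect_true(is.na(r[2, 1]))
  expect_false(anyNA(r[-2, 1]))
  agg <- aggregate_runs(array(r, c(3, 1, 1)), 20)
  expect_true(is.na(agg$aggregated_r[2, 1]))
})

test_that("Fisher transform: closed forms, round trip, clamping, errors", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5), tolerance = 1e-12)
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(inverse_fisher(fisher_z(r)), r, tolerance = 1e-10)
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_error(fisher_z(1.01), "exceeds 1")
})

test_that("run aggregation is the run-length-weighted z mean", {
  # two runs, lengths 100 and 300, z-values 0.2 and 0.6 -> z = 0.5
  r <- array(tanh(c(0.2, 0.6)), c(1, 1, 2))
  agg <- aggregate_runs(r, c(100, 300))
  expect_equal(as.numeric(agg$aggregated_z), 0.5, tolerance = 1e-12)
  expect_equal(agg$aggregated_r, tanh(agg$aggregated_z), tolerance = 1e-12)

  # equal-length equal-r runs reproduce r; run order is irrelevant
  r2 <- array(0.37, c(4, 3, 2))
  expect_equal(as.numeric(aggregate_runs(r2, c(50, 50))$aggregated_r),
               rep(0.37, 12), tolerance = 1e-10)
  set.seed(3)
  rr <- array(runif(4 * 2 * 3, -0.5, 0.5), c(4, 2, 3))
  w <- c(120, 80, 200)
  perm <- c(3, 1, 2)
  expect_equal(aggregate_runs(rr, w)$aggregated_z,
               aggregate_runs(rr[, , perm], w[perm])$aggregated_z,
               tolerance = 1e-12)
  # against the naive scalar oracle, including an undefined run
  rr[1, 1, 2] <- NA
  agg <- aggregate_runs(rr, w)
  expect_equal(agg$aggregated_r[1, 1],
               naive_weighted_fisher(rr[1, 1, ], w), tolerance = 1e-12)
})

test_that("ISC is invariant to per-voxel standardization of the input", {
  set.seed(4)
  run_data <- lapply(1:3, function(i) matrix(rnorm(6 * 40), 6, 40))
  zd <- lapply(run_data, function(m) t(scale(t(m))))
  expect_equal(pairwise_isc_run(run_data), pairwise_isc_run(zd),
               tolerance = 1e-10)
})

test_that("compute_isc bookkeeping holds together", {
  gd <- tiny_bold(seed = 6)
  isc <- compute_isc(gd, "A")
  expect_equal(nrow(isc$pair_index), 3)
  expect_true(all(abs(isc$per_run_r) <= 1, na.rm = TRUE))
  expect_equal(isc$aggregated_r, tanh(isc$aggregated_z), tolerance = 1e-12)
})

test_that("group_mean_map reports per-voxel mean and max over pairs", {
  isc <- list(aggregated_r = rbind(c(0.14, 0.14, 0.14), c(0.1, 0.2, 0.3)))
  class(isc) <- "isc_result"
  m <- group_mean_map(isc)
  expect_equal(m$mean_isc, c(0.14, 0.2), tolerance = 1e-12)
  expect_equal(m$max_isc, c(0.14, 0.3), tolerance = 1e-12)
})
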