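test_that("circular shifting preserves circular autocorrelation exactly", {
  set.seed(20)
  x <- as.numeric(arima.sim(list(ar = 0.5), 100))
  circ_ac1 <- function(v) cor(v, v[c(2:length(v), 1)])
  for (k in c(0, 1, 17, 99)) {
    y <- circular_shift(x, k)
    expect_equal(circ_ac1(y), circ_ac1(x), tolerance = 1e-10)
    expect_equal(sort(y), sort(x))
  }
  expect_identical(circular_shift(x, 0), x)
  expect_identical(circular_shift(x, 100), x)
})

test_that("the circular-shift null is centred under pure noise", {
  gd <- tiny_bold(n_per_group = 4, T = 300, seed = 21)
  null <- circular_shift_null(gd, "A", n_realizations = 5000, seed = 22)
  expect_length(null$samples, 5000)
  expect_true(all(is.finite(null$samples)))
  expect_lt(abs(mean(null$samples)), 0.02)
})

test_that("identical seeds reproduce the null bit for bit", {
  gd <- tiny_bold(n_per_group = 3, T = 100, seed = 23)
  a <- circular_shift_null(gd, "A", 1000, seed = 5)
  b <- circular_shift_null(gd, "A", 1000, seed = 5)
  expect_identical(a$samples, b$samples)
})

test_that("empirical p-values count exceedances with +1 smoothing", {
  # hand null {0.1, 0.2, 0.3, 0.4}, observed 0.25 -> (2+1)/5
  expect_equal(voxelwise_pvalues(0.25, c(0.1, 0.2, 0.3, 0.4)), 0.6)
  null <- seq(0, 1, length.out = 999)
  expect_equal(voxelwise_pvalues(2, null), 1 / 1000)       # above all samples
  expect_equal(voxelwise_pvalues(median(null), null), 0.5, tolerance = 5e-3)
  # vectorized path against the naive counting oracle, ties included
  set.seed(24)
  ns <- round(rnorm(500), 1)
  obs <- round(rnorm(40), 1)
  expect_equal(voxelwise_pvalues(obs, ns),
               vapply(obs, naive_perm_pvalue, numeric(1), null_samples = ns))
  expect_true(is.na(voxelwise_pvalues(NA, ns)))
})

test_that("BH correction matches the step-up definition", {
  p <- c(0.01, 0.02, 0.03, 0.5)
  out <- fdr_correct(p, q = 0.05)
  expect_equal(out$mask, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(out$mask, naive_bh_reject(p, 0.05))
  expect_false(any(fdr_correct(rep(1, 10), 0.05)$mask))
  expect_true(all(fdr_correct(rep(0.05 / 8, 8), 0.05)$mask))
  set.seed(25)
  p <- runif(200)^2
  for (q in c(0.001, 0.05, 0.2))
    expect_equal(fdr_correct(p, q)$mask, naive_bh_reject(p, q))
  expect_error(fdr_correct(numeric(0)), "empty")
})

test_that("identical groups give a flat t-map and no clusters", {
  set.seed(26)
  z <- matrix(rnorm(27 * 6), 27, 6)
  ct <- cluster_permutation_contrast(z, z, dims = c(3, 3, 3),
                                     voxel_index = 1:27,
                                     n_permutations = 100, cdt_p = 0.01,
                                     seed = 1)
  expect_equal(nrow(ct), 0)
  expect_lt(max(abs(attr(ct, "t_map"))), 1e-8)
})

test_that("connected-component labelling agrees with a hand-built case", {
  # the bridge voxel touches blob1 only diagonally in-plane (an
  # 18-neighbour) and blob2 face-on (a 6-neighbour)
  dims <- c(4, 4, 4)
  blob1 <- c(ind(1,1,1,dims), ind(2,1,1,dims), ind(2,2,1,dims))
  blob2 <- c(ind(3,3,2,dims), ind(4,3,2,dims))
  bridge <- ind(3, 3, 1, dims)
  vox <- as.integer(c(blob1, blob2, bridge))
  lab26 <- label_clusters_cpp(vox, as.integer(dims), 26L)
  expect_equal(length(unique(lab26)), 1)    # all one component
  lab18 <- label_clusters_cpp(vox, as.integer(dims), 18L)
  expect_equal(length(unique(lab18)), 1)
  lab6 <- label_clusters_cpp(vox, as.integer(dims), 6L)
  expect_equal(length(unique(lab6)), 2)     # bridge joins blob2 only
  expect_equal(sort(tabulate(lab6)), c(3, 3))
})

test_that("an injected group difference is found where it was put", {
  set.seed(27)
  dims <- c(8, 8, 8)
  V <- prod(dims)
  block <- as.vector(outer(outer(3:5, (3:5 - 1) * 8, `+`),
                           (3:5 - 1) * 64, `+`))
  nP <- 20
  zA <- matrix(rnorm(V * nP, 0, 0.2), V, nP)
  zB <- matrix(rnorm(V * nP, 0, 0.2), V, nP)
  zA[block, ] <- zA[block, ] + 0.5
  ct <- cluster_permutation_contrast(zA, zB, dims = dims, voxel_index = 1:V,
                                     n_permutations = 500, cdt_p = 0.001,
                                     seed = 2)
  expect_gte(nrow(ct), 1)
  top <- ct[1, ]
  expect_equal(top$direction, "A>B")
  expect_lt(top$p_corrected, 0.05)
  expect_gte(top$size, 20)   # most of the 27-voxel block survives the CDT
  # determinism: same seed, same table
  ct2 <- cluster_permutation_contrast(zA, zB, dims = dims, voxel_index = 1:V,
                                      n_permutations = 500, cdt_p = 0.001,
                                      seed = 2)
  expect_identical(as.data.frame(ct), as.data.frame(ct2))
  expect_true(all(ct$p_corrected >= 1 / 501))
})

test_that("small groups fall back to exhaustive enumeration", {
  set.seed(28)
  z <- matrix(rnorm(8 * 3), 8, 3)
  z2 <- matrix(rnorm(8 * 3), 8, 3)
  ct <- cluster_permutation_contrast(z, z2, dims = c(2, 2, 2),
                                     voxel_index = 1:8,
                                     n_permutations = 5000, cdt_p = 0.05,
                                     seed = 3)
  expect_true(attr(ct, "exhaustive"))
  expect_equal(attr(ct, "n_permutations"), choose(6, 3))
})
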