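#' Circularly shift a time series
#'
#' Rotates a series by `k` samples (the last `k` samples wrap to the
#' front). Circular shifting preserves the series' circular
#' autocorrelation structure exactly, which is what makes it a suitable
#' resampling null for autocorrelated BOLD data: shifted series keep their
#' temporal dependence but lose their alignment across subjects.
#'
#' @param x numeric vector.
#' @param k shift in samples (any integer; reduced modulo `length(x)`).
#' @return the rotated vector.
#' @export
circular_shift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(x)
  c(x[(n - k + 1):n], x[1:(n - k)])
}

#' Circular-shift resampling null for within-group ISC maps
#'
#' Builds an empirical null for the per-voxel pair-mean ISC statistic.
#' Each realization draws an independent circular shift (uniform on
#' `{1, ..., T-1}`; 0 is excluded so a realization never reproduces the
#' observed statistic) for every participant and run, picks a voxel at
#' random (with replacement) from the analysis set, computes all pairwise
#' correlations of the shifted series for every run, Fisher z-transforms
#' them, averages z over runs with run-length weights, transforms back,
#' and averages over pairs -- exactly the statistic computed on the
#' unshifted data. Samples are pooled across voxels and time shifts into a
#' single null distribution.
#'
#' @param gd a [group_dataset()].
#' @param group group label.
#' @param n_realizations number of null samples (>= 1000).
#' @param seed RNG seed.
#' @param voxel_rows analysis voxel rows (defaults to [analysis_voxels()]).
#' @return A `null_distribution`: `samples`, `n_realizations`,
#'   `pooling_scope`, `rng_seed`, `run_lengths`.
#' @export
circular_shift_null <- function(gd, group, n_realizations = 500000, seed = 1L,
                                voxel_rows = analysis_voxels(gd)) {
  if (n_realizations < 1000) stop("n_realizations must be >= 1000")
  if (any(gd$run_lengths < 3)) stop("runs must have at least 3 samples")
  ids <- subjects_in_group(gd, group)
  n <- length(ids)
  if (n < 2) stop("ISC needs at least 2 subjects per group")
  R <- length(gd$run_lengths)
  w <- gd$run_lengths / sum(gd$run_lengths)
  pairs_upper <- upper.tri(matrix(0, n, n))
  set.seed(seed)
  vox_draw <- voxel_rows[sample.int(length(voxel_rows), n_realizations, replace = TRUE)]
  samples <- numeric(n_realizations)
  for (i in seq_len(n_realizations)) {
    v <- vox_draw[i]
    zsum <- matrix(0, n, n)
    for (r in seq_len(R)) {
      Tt <- gd$run_lengths[r]
      shifts <- sample.int(Tt - 1, n, replace = TRUE)
      m <- matrix(0, Tt, n)
      for (s in seq_len(n))
        m[, s] <- circular_shift(gd$data[[ids[s]]][[r]][v, ], shifts[s])
      m <- m - rep(colMeans(m), each = Tt)
      nrm <- sqrt(colSums(m^2))
      nrm[nrm == 0] <- Inf
      m <- m / rep(nrm, each = Tt)
      rr <- crossprod(m)
      zsum <- zsum + w[r] * fisher_z(pmin(pmax(rr, -1), 1))
    }
    samples[i] <- mean(tanh(zsum[pairs_upper]))
  }
  structure(
    list(samples = samples, n_realizations = n_realizations,
         pooling_scope = "across_voxels_and_timepoints",
         rng_seed = seed, run_lengths = gd$run_lengths),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %d realizations (seed %d), mean %.4f, sd %.4f\n",
              x$n_realizations, x$rng_seed, mean(x$samples), sd(x$samples)))
  invisible(x)
}

#' One-sided empirical p-values against a resampling null
#'
#' `p(v) = (#\{null >= observed(v)\} + 1) / (N + 1)` (one-sided for
#' positive ISC; the +1 smoothing keeps p-values off zero). Undefined
#' observed values give `NA`.
#'
#' @param observed numeric vector of per-voxel observed statistics.
#' @param null a `null_distribution` (or numeric vector of null samples).
#' @return numeric vector of p-values in `[1/(N+1), 1]`.
#' @export
voxelwise_pvalues <- function(observed, null) {
  samples <- if (inherits(null, "null_distribution")) null$samples else null
  if (length(samples) == 0) stop("null distribution is empty")
  srt <- sort(samples)
  N <- length(srt)
  n_lt <- findInterval(observed, srt, left.open = TRUE)
  p <- (N - n_lt + 1) / (N + 1)
  p[is.na(observed)] <- NA_real_
  p
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up control of the false discovery rate at level `q` via
#' [stats::p.adjust()]. `NA` p-values are excluded from the procedure and
#' stay `NA` in the output.
#'
#' @param pvalues numeric vector of p-values.
#' @param q FDR level (0.001 is used for within-group ISC maps, 0.05 for
#'   narrative segments).
#' @return list with `mask` (logical; `NA` input stays `NA`) and
#'   `p_adjusted`.
#' @export
fdr_correct <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0) stop("empty p-value vector")
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- p.adjust(pvalues, method = "BH")
  mask <- adj <= q
  list(mask = mask, p_adjusted = adj)
}

#' Cluster-based two-sample permutation contrast of group ISC maps
#'
#' Compares two groups' pair-level Fisher z-values voxel by voxel with a
#' pooled-variance two-sample t statistic. Voxels exceeding the
#' cluster-defining threshold (CDT, uncorrected `p < cdt_p` per tail) form
#' connected clusters; family-wise error across both directions is
#' controlled by comparing each observed cluster's size against the
#' permutation distribution of the maximum suprathreshold cluster size
#' over both tails, obtained by exchanging pair-level z-values between the
#' groups. When the number of distinct assignments does not exceed
#' `n_permutations` the enumeration is exhaustive.
#'
#' The exchange unit is the subject pair, mirroring the permutation of
#' "z-values between the groups"; pairs sharing a subject are dependent,
#' so the test inherits the usual pair-level exchangeability caveat (see
#' the methods vignette).
#'
#' @param zA,zB voxel x pair matrices of aggregated Fisher z-values for
#'   groups A and B (same voxel set, e.g. `aggregated_z` from
#'   [compute_isc()]).
#' @param dims 3D grid dimensions.
#' @param voxel_index 1-based grid linear index of each voxel row.
#' @param n_permutations number of permutations (default 5000).
#' @param cdt_p cluster-defining threshold as an uncorrected one-tail p
#'   (default 0.001).
#' @param seed RNG seed.
#' @param connectivity 6, 18 or 26 (default 26).
#' @param affine optional 4x4 voxel-to-mm affine for peak coordinates;
#'   default scales 0-based voxel indices by `voxel_size_mm`.
#' @param voxel_size_mm voxel size used when `affine` is `NULL`.
#' @return A `cluster_table`: data.frame with one row per suprathreshold
#'   cluster (`cluster`, `direction`, `size`, `peak_x`, `peak_y`,
#'   `peak_z`, `peak_t`, `p_corrected`), with the permutation null and
#'   parameters in attributes.
#' @export
cluster_permutation_contrast <- function(zA, zB, dims, voxel_index,
                                         n_permutations = 5000,
                                         cdt_p = 0.001, seed = 1L,
                                         connectivity = 26, affine = NULL,
                                         voxel_size_mm = 1) {
  if (nrow(zA) != nrow(zB)) stop("zA and zB must share the voxel set")
  if (nrow(zA) != length(voxel_index)) stop("voxel_index length mismatch")
  nA <- ncol(zA); nB <- ncol(zB)
  if (nA < 2 || nB < 2) stop("need at least 2 pairs per group")
  n <- nA + nB
  Z <- rbind(t(zA), t(zB))
  df <- n - 2
  tthr <- qt(1 - cdt_p, df)

  t_obs <- tmap_pooled_cpp(Z, seq_len(nA), nA + seq_len(nB))

  set.seed(seed)
  n_distinct <- choose(n, nA)
  if (is.finite(n_distinct) && n_distinct <= n_permutations) {
    permA <- t(combn(n, nA))
  } else {
    permA <- t(vapply(seq_len(n_permutations),
                      function(i) sample.int(n, nA), integer(nA)))
  }
  P <- nrow(permA)
  null_sizes <- cluster_perm_null_cpp(Z, permA, as.integer(dims),
                                      as.integer(voxel_index), tthr,
                                      as.integer(connectivity))

  ijk_mm <- function(vox) {
    ijk <- arrayInd(vox, dims) - 1L
    if (is.null(affine)) {
      ijk * voxel_size_mm
    } else {
      mm <- cbind(ijk, 1) %*% t(affine)
      mm[, 1:3, drop = FALSE]
    }
  }

  rows <- list()
  for (tail in c("A>B", "B>A")) {
    keep <- if (tail == "A>B") which(!is.na(t_obs) & t_obs > tthr)
            else which(!is.na(t_obs) & t_obs < -tthr)
    if (length(keep) == 0) next
    lab <- label_clusters_cpp(as.integer(voxel_index[keep]),
                              as.integer(dims), as.integer(connectivity))
    for (cl in seq_len(max(lab))) {
      members <- keep[lab == cl]
      size <- length(members)
      peak <- members[which.max(abs(t_obs[members]))]
      mm <- ijk_mm(voxel_index[peak])
      rows[[length(rows) + 1L]] <- data.frame(
        direction = tail, size = size,
        peak_x = mm[1], peak_y = mm[2], peak_z = mm[3],
        peak_t = t_obs[peak],
        p_corrected = (sum(null_sizes >= size) + 1) / (P + 1),
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows)
         else data.frame(direction = character(), size = integer(),
                         peak_x = numeric(), peak_y = numeric(),
                         peak_z = numeric(), peak_t = numeric(),
                         p_corrected = numeric(), stringsAsFactors = FALSE)
  if (nrow(tab)) {
    tab <- tab[order(tab$p_corrected, -tab$size), , drop = FALSE]
    tab <- cbind(cluster = seq_len(nrow(tab)), tab)
    rownames(tab) <- NULL
  }
  structure(tab, class = c("cluster_table", "data.frame"),
            cdt_p = cdt_p, t_threshold = tthr, n_permutations = P,
            exhaustive = is.finite(n_distinct) && n_distinct <= n_permutations,
            null_max_cluster = null_sizes, connectivity = connectivity,
            t_map = t_obs, seed = seed)
}
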