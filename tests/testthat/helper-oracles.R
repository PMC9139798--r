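# Independent brute-force oracles used for dual-route checks. These stay
# deliberately naive (double loops, stats::cor, direct formulas) so they
# share no code with the implementation paths they validate.

naive_pairwise_isc <- function(run_data) {
  n <- length(run_data)
  V <- nrow(run_data[[1]])
  pairs <- combn(n, 2)
  out <- matrix(NA_real_, V, ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    for (v in seq_len(V)) {
      out[v, p] <- suppressWarnings(
        cor(run_data[[pairs[1, p]]][v, ], run_data[[pairs[2, p]]][v, ]))
    }
  }
  out
}

naive_weighted_fisher <- function(r_by_run, weights) {
  z <- atanh(pmin(pmax(r_by_run, -1 + 1e-7), 1 - 1e-7))
  keep <- !is.na(z)
  if (!any(keep)) return(NA_real_)
  tanh(sum(weights[keep] * z[keep]) / sum(weights[keep]))
}

# Benjamini-Hochberg step-up, straight from the definition.
naive_bh_reject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k <- 0
  for (i in seq_len(m)) if (p[ord[i]] <= q * i / m) k <- i
  rejected <- rep(FALSE, m)
  if (k > 0) rejected[ord[seq_len(k)]] <- TRUE
  rejected
}

naive_cosine <- function(a, b) sum(a * b) / (sqrt(sum(a * a)) * sqrt(sum(b * b)))

naive_perm_pvalue <- function(observed, null_samples) {
  (sum(null_samples >= observed) + 1) / (length(null_samples) + 1)
}

# Dense 3D Gaussian convolution with zero padding; kernel truncated at
# ceiling(4 sigma) voxels and normalized to unit mass over its support.
naive_gaussian_smooth3 <- function(a, fwhm_mm, voxel_size_mm) {
  sigma <- (fwhm_mm / voxel_size_mm) / (2 * sqrt(2 * log(2)))
  half <- max(1L, as.integer(ceiling(4 * sigma)))
  off <- -half:half
  w1 <- exp(-off^2 / (2 * sigma^2)); w1 <- w1 / sum(w1)
  kern <- outer(outer(w1, w1), w1)
  d <- dim(a)
  out <- array(0, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    acc <- 0
    for (i in seq_along(off)) for (j in seq_along(off)) for (k in seq_along(off)) {
      xx <- x + off[i]; yy <- y + off[j]; zz <- z + off[k]
      if (xx >= 1 && xx <= d[1] && yy >= 1 && yy <= d[2] && zz >= 1 && zz <= d[3])
        acc <- acc + kern[i, j, k] * a[xx, yy, zz]
    }
    out[x, y, z] <- acc
  }
  out
}

# Small standard fixtures -------------------------------------------------

tiny_bold <- function(n_per_group = 3, T = 60, grid = c(5, 4, 4), seed = 1,
                      shared = 0, groupA = 0, groupB = 0, ...) {
  generate_group_bold(bold_sim_config(
    n_per_group = n_per_group, n_runs = 2, run_lengths = c(T, T + 10),
    grid_shape = grid, tr_s = 0.1, shared_var_frac = shared,
    group_var_frac = list(A = groupA, B = groupB), seed = seed, ...))
}

toy_embeddings <- function() {
  v <- rbind(koira = c(1, 0, 0), kissa = c(0, 1, 0), talo = c(0, 0, 1),
             lumi = c(1, 1, 0) / sqrt(2))
  embedding_table(v)
}

ind <- function(x, y, z, dims) x + dims[1] * ((y - 1) + dims[2] * (z - 1))

label_clusters_cpp <- function(...) naturalisc:::label_clusters_cpp(...)
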