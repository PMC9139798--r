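#' Fisher z-transform of a correlation
#'
#' `fisher_z()` maps r to atanh(r); `inverse_fisher()` maps back with tanh.
#' Correlations of magnitude exactly 1 are clamped to `1 - 1e-7` before the
#' transform so aggregation never produces infinities; magnitudes beyond 1
#' (outside numerical round-off) are an error. `NA` propagates.
#'
#' @param r correlation value(s) in `[-1, 1]`.
#' @return numeric vector of z-values.
#' @export
fisher_z <- function(r) {
  bad <- !is.na(r) & abs(r) > 1 + 1e-8
  if (any(bad)) stop("correlation magnitude exceeds 1")
  r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  atanh(r)
}

#' @rdname fisher_z
#' @param z Fisher z-value(s).
#' @export
inverse_fisher <- function(z) tanh(z)

#' Enumerate unordered subject pairs in lexicographic order
#'
#' @param ids character vector of subject identifiers.
#' @return data.frame with columns `i`, `j` (indices, i < j), `id_i`, `id_j`.
#' @export
pair_index <- function(ids) {
  n <- length(ids)
  if (n < 2) stop("at least 2 subjects are required")
  cmb <- combn(n, 2)
  data.frame(i = cmb[1, ], j = cmb[2, ],
             id_i = ids[cmb[1, ]], id_j = ids[cmb[2, ]],
             stringsAsFactors = FALSE)
}

# Center and scale each row to unit L2 norm; zero-variance rows become NaN
# rows, which propagate to an NA correlation downstream.
unit_rows <- function(m) {
  m <- m - rowMeans(m)
  nrm <- sqrt(rowSums(m^2))
  m / nrm
}

#' Pairwise voxelwise ISC for one run
#'
#' Pearson correlation of every unordered subject pair's time courses,
#' voxel by voxel. Zero-variance time courses yield `NA` for every pair
#' involving them; these are excluded from aggregation and nulls rather
#' than propagated as numbers.
#'
#' @param run_data list of voxel x time matrices, one per subject, all with
#'   identical voxel sets and run length.
#' @return voxel x pair matrix of correlations; columns ordered as
#'   [pair_index()] over the subjects.
#' @export
pairwise_isc_run <- function(run_data) {
  n <- length(run_data)
  if (n < 2) stop("at least 2 subjects are required")
  V <- nrow(run_data[[1]]); Tt <- ncol(run_data[[1]])
  for (m in run_data) {
    if (nrow(m) != V) stop("subjects have mismatched voxel counts")
    if (ncol(m) != Tt) stop("subjects have mismatched run lengths")
  }
  pairwise_isc_cpp(lapply(run_data, function(m) {
    storage.mode(m) <- "double"
    m
  }))
}

#' Aggregate per-run correlations across runs with run-length weights
#'
#' Each correlation is Fisher z-transformed; z-values are averaged over
#' runs with weights equal to the run length in time points, and the
#' weighted mean is transformed back to a correlation. Runs where the
#' correlation is undefined (`NA`) at a voxel drop out of that voxel's
#' weighted mean; if all runs are undefined the aggregate is `NA`.
#'
#' @param per_run_r voxel x pair x run array (or voxel x run matrix when a
#'   single "pair" is aggregated) of Pearson correlations.
#' @param run_lengths positive integer vector, one entry per run.
#' @return list with `aggregated_z` and `aggregated_r` (voxel x pair).
#' @export
aggregate_runs <- function(per_run_r, run_lengths) {
  if (any(run_lengths <= 0)) stop("run_lengths must be strictly positive")
  if (is.matrix(per_run_r)) dim(per_run_r) <- c(nrow(per_run_r), 1L, ncol(per_run_r))
  R <- dim(per_run_r)[3]
  if (R != length(run_lengths))
    stop("number of runs does not match run_lengths")
  znum <- array(0, dim(per_run_r)[1:2])
  wden <- array(0, dim(per_run_r)[1:2])
  for (k in seq_len(R)) {
    zk <- fisher_z(per_run_r[, , k])
    ok <- !is.na(zk)
    zk[!ok] <- 0
    znum <- znum + run_lengths[k] * zk
    wden <- wden + run_lengths[k] * ok
  }
  z <- znum / wden          # all-NA voxels: 0/0 -> NaN
  z[wden == 0] <- NA_real_
  list(aggregated_z = z, aggregated_r = tanh(z))
}

#' Compute an ISC result for one group
#'
#' Runs [pairwise_isc_run()] for every run over the analysis voxels of one
#' group's subjects and aggregates across runs via [aggregate_runs()].
#'
#' @param gd a [group_dataset()].
#' @param group group label to analyse.
#' @param voxel_rows optional row indices to restrict to; defaults to
#'   [analysis_voxels()].
#' @return An `isc_result`: pair bookkeeping, per-run correlations,
#'   run lengths, aggregated z and r matrices (voxel x pair).
#' @export
compute_isc <- function(gd, group, voxel_rows = analysis_voxels(gd)) {
  ids <- subjects_in_group(gd, group)
  if (length(ids) < 2) stop("ISC needs at least 2 subjects per group")
  pairs <- pair_index(ids)
  R <- length(gd$run_lengths)
  per_run <- array(NA_real_, c(length(voxel_rows), nrow(pairs), R))
  for (r in seq_len(R)) {
    run_data <- lapply(ids, function(s) gd$data[[s]][[r]][voxel_rows, , drop = FALSE])
    per_run[, , r] <- pairwise_isc_run(run_data)
  }
  agg <- aggregate_runs(per_run, gd$run_lengths)
  structure(
    list(pair_index = pairs, per_run_r = per_run,
         run_lengths = gd$run_lengths,
         aggregated_z = agg$aggregated_z, aggregated_r = agg$aggregated_r,
         group_label = group, voxel_rows = voxel_rows),
    class = "isc_result"
  )
}

#' @export
print.isc_result <- function(x, ...) {
  cat(sprintf("<isc_result> group %s: %d voxels, %d pairs, %d runs; mean ISC %.4f\n",
              x$group_label, nrow(x$aggregated_r), nrow(x$pair_index),
              length(x$run_lengths), mean(x$aggregated_r, na.rm = TRUE)))
  invisible(x)
}

#' Per-voxel mean and maximum ISC over pairs
#'
#' @param isc an `isc_result` from [compute_isc()].
#' @return data.frame with per-voxel `mean_isc` and `max_isc`
#'   (NA where every pair is undefined).
#' @export
group_mean_map <- function(isc) {
  r <- isc$aggregated_r
  if (ncol(r) < 1) stop("isc_result has no pairs")
  mean_isc <- rowMeans(r, na.rm = TRUE)
  max_isc <- suppressWarnings(apply(r, 1, max, na.rm = TRUE))
  all_na <- apply(is.na(r), 1, all)
  mean_isc[all_na] <- NA_real_
  max_isc[all_na | !is.finite(max_isc)] <- NA_real_
  data.frame(voxel = seq_len(nrow(r)), mean_isc = mean_isc, max_isc = max_isc)
}
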