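# Operators accept either a subject_run_series or a bare voxel x time
# matrix (with tr_s supplied); they return the same shape they were given.
series_input <- function(x, tr_s = NULL) {
  if (inherits(x, "subject_run_series")) {
    list(data = x$data, tr_s = x$tr_s, wrap = x)
  } else {
    if (is.null(tr_s)) stop("`tr_s` is required for matrix input")
    list(data = as.matrix(x), tr_s = tr_s, wrap = NULL)
  }
}

series_output <- function(parsed, data) {
  if (is.null(parsed$wrap)) return(data)
  out <- parsed$wrap
  out$data <- data
  out$n_timepoints <- ncol(data)
  out
}

# Savitzky-Golay linear smoother as an explicit T x T matrix built from the
# sgolay projection matrix; edge rows fit the polynomial on asymmetric
# windows at the boundaries (same convention as signal::sgolayfilt).
sg_smoother_matrix <- function(n_time, order, frame) {
  S <- unclass(signal::sgolay(p = order, n = frame))
  half <- (frame - 1L) %/% 2L
  L <- matrix(0, n_time, n_time)
  for (i in seq_len(half)) L[i, 1:frame] <- S[i, ]
  mid <- S[half + 1L, ]
  for (i in seq.int(half + 1L, n_time - half))
    L[i, (i - half):(i + half)] <- mid
  for (i in seq_len(half))
    L[n_time - half + i, (n_time - frame + 1L):n_time] <- S[half + 1L + i, ]
  L
}

#' Savitzky-Golay detrending
#'
#' Removes slow scanner drift by subtracting, voxelwise, the
#' Savitzky-Golay smoothed trend: a least-squares polynomial of the given
#' order fitted in a sliding window. The frame length is specified in
#' seconds and converted to the nearest odd number of samples. Boundary
#' samples use polynomial fits on asymmetric windows so no data are
#' discarded. Defaults: order 3, frame 240 s.
#'
#' @param x a [subject_run_series()] or voxel x time matrix.
#' @param order polynomial order.
#' @param frame_length_s window length in seconds.
#' @param tr_s sampling interval, required for matrix input.
#' @return the detrended series, same type as the input.
#' @export
savgol_detrend <- function(x, order = 3, frame_length_s = 240, tr_s = NULL) {
  p <- series_input(x, tr_s)
  f <- frame_length_s / p$tr_s
  frame <- as.integer(2 * round((f - 1) / 2) + 1)   # nearest odd sample count
  if (frame <= order)
    stop("frame length in samples must exceed the polynomial order")
  n_time <- ncol(p$data)
  if (n_time < frame)
    stop(sprintf("series too short for detrending: %d samples, need at least %d",
                 n_time, frame))
  L <- sg_smoother_matrix(n_time, order, frame)
  trend <- p$data %*% t(L)
  series_output(p, p$data - trend)
}

#' DVARS: spatial standard deviation of successive difference images
#'
#' For t >= 2, `DVARS(t)` is the sample standard deviation (divisor N-1)
#' over voxels of the difference image `data[, t] - data[, t-1]`; a large
#' value flags a sudden whole-volume intensity change, typically head
#' motion. DVARS-based scrubbing is not applied here; the per-run values
#' and their mean are exported so groups can be compared.
#'
#' @param x a [subject_run_series()] or voxel x time matrix.
#' @return list with `dvars` (length T-1, for t = 2..T) and `mean_dvars`.
#' @export
compute_dvars <- function(x) {
  data <- if (inherits(x, "subject_run_series")) x$data else as.matrix(x)
  Tt <- ncol(data)
  if (Tt < 2) stop("DVARS needs at least 2 timepoints")
  d <- data[, -1, drop = FALSE] - data[, -Tt, drop = FALSE]
  dvars <- apply(d, 2, sd)
  list(dvars = as.numeric(dvars), mean_dvars = mean(dvars))
}

#' Zero-phase temporal band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' ([signal::filtfilt()]), giving zero phase shift. Defaults 0.08-4 Hz,
#' the band used for fast-TR BOLD data sampled at 10 Hz.
#'
#' @param x a [subject_run_series()] or voxel x time matrix.
#' @param low_hz,high_hz band edges; must satisfy
#'   `0 < low_hz < high_hz < Nyquist`.
#' @param tr_s sampling interval, required for matrix input.
#' @return the filtered series, same type as the input.
#' @export
bandpass_filter <- function(x, low_hz = 0.08, high_hz = 4, tr_s = NULL) {
  p <- series_input(x, tr_s)
  nyq <- 1 / (2 * p$tr_s)
  if (!(low_hz > 0 && low_hz < high_hz)) stop("need 0 < low_hz < high_hz")
  if (high_hz >= nyq)
    stop(sprintf("high_hz (%g) must be below the Nyquist frequency (%g Hz)",
                 high_hz, nyq))
  bf <- signal::butter(4, c(low_hz, high_hz) / nyq, type = "pass")
  out <- t(apply(p$data, 1, function(row) signal::filtfilt(bf, row)))
  if (nrow(p$data) == 1) out <- matrix(out, 1)
  series_output(p, out)
}

#' Isotropic Gaussian spatial smoothing
#'
#' Convolves each 3D volume with an isotropic Gaussian kernel of the given
#' full width at half maximum, `sigma = (fwhm_mm / voxel_size_mm) /
#' (2 sqrt(2 log 2))` voxels. The kernel is truncated at `ceiling(4 sigma)`
#' voxels and normalized to unit mass over its support. Convolution runs
#' over the full grid with zero padding; when a `mask` is given the result
#' is re-masked afterwards, or -- with `normalize_mask = TRUE` -- divided
#' by the smoothed mask so edge voxels are not dragged toward zero.
#'
#' @param vol a 3D array or 4D array (x, y, z, time).
#' @param fwhm_mm kernel FWHM in millimetres (0 is the identity).
#' @param voxel_size_mm voxel edge length in millimetres.
#' @param mask optional logical 3D array.
#' @param normalize_mask divide by the smoothed mask inside the mask.
#' @return smoothed array, same dimensions as the input.
#' @export
gaussian_smooth <- function(vol, fwhm_mm = 6, voxel_size_mm = 3,
                            mask = NULL, normalize_mask = FALSE) {
  if (fwhm_mm < 0) stop("fwhm_mm must be non-negative")
  if (fwhm_mm == 0) return(vol)
  nd <- length(dim(vol))
  if (nd != 3 && nd != 4) stop("expected a 3D or 4D array")
  sigma <- (fwhm_mm / voxel_size_mm) / (2 * sqrt(2 * log(2)))
  half <- max(1L, as.integer(ceiling(4 * sigma)))
  w <- exp(-((-half:half)^2) / (2 * sigma^2))
  w <- w / sum(w)

  out <- smooth_sep_cpp(as.double(vol), as.integer(dim(vol)), w)
  if (!is.null(mask)) {
    mfac <- as.double(mask)
    if (normalize_mask) {
      mw <- smooth_sep_cpp(mfac, as.integer(dim(mask)), w)
      mfac <- ifelse(mw > 0, mfac / as.double(mw), 0)
    }
    out <- out * as.vector(mfac)   # recycles over the time dimension
  }
  dim(out) <- dim(vol)
  out
}

# Top generalized eigenvectors of A c = lambda B c via Cholesky whitening.
top_gen_eigvecs <- function(A, B, k) {
  Rch <- chol(B)
  Rinv <- backsolve(Rch, diag(nrow(B)))
  M <- t(Rinv) %*% A %*% Rinv
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  Rinv %*% e$vectors[, seq_len(k), drop = FALSE]
}

#' Subject-specific nuisance-component regression
#'
#' For each subject, finds `k` temporal components that explain maximal
#' variance in that subject's own white-matter and CSF voxel time series
#' relative to the variance they explain in the other subjects' nuisance
#' series, and regresses them out of the subject's full data by ordinary
#' least squares. The contrast is solved as a generalized eigenvalue
#' problem on the two T x T covariance structures (own-nuisance versus
#' others'-nuisance). Because a stimulus-locked signal present in
#' everyone's data loads on both covariances, it scores a Rayleigh
#' quotient near 1 and is not selected: only subject-specific structure
#' -- physiological and movement artifacts -- is removed. Components are
#' computed per run by default (`scope = "concatenated"` pools runs).
#'
#' The denominator covariance is ridge-regularized with `ridge` times its
#' mean diagonal. When the pooled nuisance series of the other subjects
#' have fewer dimensions than time points, their covariance is rank
#' deficient and a vanishing ridge would let the maximizer escape into
#' its null space (directions penalized by nobody); a ridge on the scale
#' of the typical eigenvalue keeps the quotient honest there, at the cost
#' of some shrinkage.
#'
#' @param gd a [group_dataset()] (nuisance masks are taken from it).
#' @param k components to remove per subject (default 10; 0 is a no-op).
#' @param scope `"run"` or `"concatenated"`.
#' @param ridge denominator regularization, relative to the mean diagonal
#'   of the others'-nuisance covariance (default 1).
#' @return the cleaned [group_dataset()].
#' @export
maxcorr_denoise <- function(gd, k = 10, scope = c("run", "concatenated"),
                            ridge = 1) {
  scope <- match.arg(scope)
  if (k < 0) stop("k must be >= 0")
  if (k == 0) return(gd)
  ids <- names(gd$data)
  if (length(ids) < 2) stop("nuisance contrast needs at least 2 subjects")
  nuis <- nuisance_voxels(gd)
  if (length(nuis) == 0) stop("nuisance masks are empty")
  R <- length(gd$run_lengths)

  regress_out <- function(X, C) {
    Ct <- cbind(1, C)
    X - (X %*% Ct) %*% solve(crossprod(Ct), t(Ct))
  }

  run_blocks <- if (scope == "run") as.list(seq_len(R)) else list(seq_len(R))
  out <- gd
  for (blk in run_blocks) {
    Tt <- sum(gd$run_lengths[blk])
    if (k > min(Tt - 1, length(nuis)))
      stop("k exceeds the rank of the nuisance series")
    nuis_mats <- lapply(ids, function(s) {
      m <- do.call(cbind, lapply(blk, function(r) gd$data[[s]][[r]][nuis, , drop = FALSE]))
      m - rowMeans(m)
    })
    names(nuis_mats) <- ids
    covs <- lapply(nuis_mats, crossprod)          # T x T each
    tot <- Reduce(`+`, covs)
    for (s in ids) {
      A <- covs[[s]]
      B <- tot - A
      B <- B + diag(ridge * sum(diag(B)) / nrow(B), nrow(B))
      C <- top_gen_eigvecs(A, B, k)
      full <- do.call(cbind, lapply(blk, function(r) out$data[[s]][[r]]))
      cleaned <- regress_out(full, C)
      off <- 0
      for (r in blk) {
        out$data[[s]][[r]] <- cleaned[, off + seq_len(gd$run_lengths[r]), drop = FALSE]
        off <- off + gd$run_lengths[r]
      }
    }
  }
  out
}

#' Full preprocessing chain for a group dataset
#'
#' Applies, in order: Savitzky-Golay detrending, nuisance-component
#' regression, DVARS computation (recorded, not used for scrubbing),
#' zero-phase band-pass filtering and spatial Gaussian smoothing. Any
#' stage can be switched off. Returns the processed dataset together with
#' a per-subject, per-run DVARS summary table.
#'
#' @param gd a [group_dataset()].
#' @param detrend logical; run Savitzky-Golay detrending.
#' @param sg_order,sg_frame_s detrending parameters.
#' @param maxcorr_k nuisance components per subject (0 skips).
#' @param band numeric length-2 band in Hz, or `NULL` to skip.
#' @param fwhm_mm smoothing kernel FWHM in mm (0 skips).
#' @return list with `dataset` (processed [group_dataset()]) and `dvars`
#'   (data.frame: subject, group, run, mean_dvars).
#' @export
preprocess_dataset <- function(gd, detrend = TRUE, sg_order = 3,
                               sg_frame_s = 240, maxcorr_k = 10,
                               band = c(0.08, 4), fwhm_mm = 6) {
  ids <- names(gd$data)
  R <- length(gd$run_lengths)
  if (detrend) {
    for (s in ids) for (r in seq_len(R))
      gd$data[[s]][[r]] <- savgol_detrend(gd$data[[s]][[r]], order = sg_order,
                                          frame_length_s = sg_frame_s,
                                          tr_s = gd$tr_s)
  }
  if (maxcorr_k > 0) gd <- maxcorr_denoise(gd, k = maxcorr_k)
  dv <- do.call(rbind, lapply(ids, function(s) {
    data.frame(subject = s, group = unname(gd$group_labels[s]),
               run = seq_len(R),
               mean_dvars = vapply(seq_len(R), function(r)
                 compute_dvars(gd$data[[s]][[r]])$mean_dvars, numeric(1)),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(band)) {
    for (s in ids) for (r in seq_len(R))
      gd$data[[s]][[r]] <- bandpass_filter(gd$data[[s]][[r]], band[1], band[2],
                                           tr_s = gd$tr_s)
  }
  if (fwhm_mm > 0) {
    for (s in ids) for (r in seq_len(R)) {
      m <- gd$data[[s]][[r]]
      flat <- matrix(0, prod(gd$dims), ncol(m))
      flat[gd$voxel_index, ] <- m
      dim(flat) <- c(gd$dims, ncol(m))
      sm <- gaussian_smooth(flat, fwhm_mm = fwhm_mm,
                            voxel_size_mm = gd$voxel_size_mm,
                            mask = gd$masks$brain)
      dim(sm) <- c(prod(gd$dims), ncol(m))
      gd$data[[s]][[r]] <- sm[gd$voxel_index, , drop = FALSE]
    }
  }
  list(dataset = gd, dvars = dv)
}
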