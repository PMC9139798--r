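#' Per-subject, per-run masked time-series container
#'
#' Holds one subject's voxel-by-time matrix for a single functional run
#' together with its sampling interval. Rows are masked voxels in a fixed
#' order shared across subjects; columns are time points.
#'
#' @param data numeric matrix, voxels in rows, time points in columns.
#' @param tr_s sampling interval (repetition time) in seconds.
#' @param run_id integer run index.
#' @param subject_id subject identifier.
#' @return An object of class `subject_run_series`.
#' @export
subject_run_series <- function(data, tr_s, run_id = 1L, subject_id = "s1") {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be a numeric matrix")
  if (any(!is.finite(data))) stop("time series contains non-finite values")
  if (!is.numeric(tr_s) || length(tr_s) != 1L || tr_s <= 0)
    stop("`tr_s` must be a single positive number")
  structure(
    list(data = data, tr_s = tr_s, run_id = as.integer(run_id),
         subject_id = subject_id, n_timepoints = ncol(data)),
    class = "subject_run_series"
  )
}

#' @export
print.subject_run_series <- function(x, ...) {
  cat(sprintf("<subject_run_series> subject %s, run %d: %d voxels x %d timepoints (TR %.3g s)\n",
              x$subject_id, x$run_id, nrow(x$data), x$n_timepoints, x$tr_s))
  invisible(x)
}

#' Group dataset: subjects x runs of masked BOLD matrices
#'
#' The unit consumed by the ISC pipeline. `data` is a named list (one entry
#' per subject) of lists of voxel-by-time matrices (one per run); all
#' matrices share the same row (voxel) order, recorded in `voxel_index` as
#' linear indices into the 3D grid (column-major). `masks` carries logical
#' 3D arrays for brain, white matter and CSF; voxels overlapping the
#' nuisance masks are excluded from the ISC analysis set (see
#' [analysis_voxels()]).
#'
#' @param data named list of per-subject lists of voxel x time matrices.
#' @param group_labels named character vector mapping subject id to group.
#' @param masks list with logical 3D arrays `brain`, `wm`, `csf`.
#' @param tr_s repetition time in seconds.
#' @param run_lengths integer vector of time points per run.
#' @param voxel_index linear grid indices of the matrix rows.
#' @param dims 3D grid dimensions.
#' @param voxel_size_mm voxel edge length in millimetres.
#' @param ground_truth optional list of generating signals (simulations only).
#' @return An object of class `group_dataset`.
#' @export
group_dataset <- function(data, group_labels, masks, tr_s, run_lengths,
                          voxel_index, dims, voxel_size_mm = 3,
                          ground_truth = NULL) {
  if (is.null(names(data)) || !all(names(data) %in% names(group_labels)))
    stop("`data` must be a named list with labels for every subject")
  n_runs <- length(run_lengths)
  for (s in names(data)) {
    if (length(data[[s]]) != n_runs)
      stop(sprintf("subject %s: expected %d runs, found %d", s, n_runs,
                   length(data[[s]])))
    for (r in seq_len(n_runs)) {
      m <- data[[s]][[r]]
      if (nrow(m) != length(voxel_index))
        stop(sprintf("subject %s run %d: voxel count mismatch", s, r))
      if (ncol(m) != run_lengths[r])
        stop(sprintf("subject %s run %d: expected %d timepoints, found %d",
                     s, r, run_lengths[r], ncol(m)))
    }
  }
  structure(
    list(data = data, group_labels = group_labels, masks = masks,
         tr_s = tr_s, run_lengths = as.integer(run_lengths),
         voxel_index = as.integer(voxel_index), dims = as.integer(dims),
         voxel_size_mm = voxel_size_mm, ground_truth = ground_truth),
    class = "group_dataset"
  )
}

#' @export
print.group_dataset <- function(x, ...) {
  tab <- table(x$group_labels[names(x$data)])
  cat(sprintf("<group_dataset> %d subjects (%s), %d runs, %d masked voxels, grid %s\n",
              length(x$data),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              length(x$run_lengths), length(x$voxel_index),
              paste(x$dims, collapse = "x")))
  invisible(x)
}

#' Subjects belonging to one group
#' @param gd a `group_dataset`.
#' @param group group label.
#' @return character vector of subject ids, in dataset order.
#' @export
subjects_in_group <- function(gd, group) {
  ids <- names(gd$data)
  ids[gd$group_labels[ids] == group]
}

#' Row indices of ISC analysis voxels
#'
#' Analysis voxels are brain-mask voxels outside the white-matter and CSF
#' nuisance masks, indexed into the rows of the dataset matrices.
#'
#' @param gd a `group_dataset`.
#' @return integer vector of row indices.
#' @export
analysis_voxels <- function(gd) {
  nuis <- gd$masks$wm | gd$masks$csf
  which(!nuis[gd$voxel_index])
}

#' Row indices of nuisance (WM + CSF) voxels
#' @param gd a `group_dataset`.
#' @return integer vector of row indices into the dataset matrices.
#' @export
nuisance_voxels <- function(gd) {
  nuis <- gd$masks$wm | gd$masks$csf
  which(nuis[gd$voxel_index])
}
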