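#' Write a group dataset to NIfTI files plus a JSON manifest
#'
#' One 4D NIfTI per subject per run, 3D mask volumes (brain, white matter,
#' CSF) and `manifest.json` describing subjects, groups, runs, grid and
#' timing -- the layout [load_group_dataset()] reads back.
#'
#' @param gd a [group_dataset()].
#' @param dir output directory (created if needed).
#' @param gzip write `.nii.gz` instead of `.nii`.
#' @return the manifest path, invisibly.
#' @export
write_group_dataset <- function(gd, dir, gzip = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  pix <- rep(gd$voxel_size_mm, 3)
  as_img <- function(arr, time = FALSE) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- if (time) c(pix, gd$tr_s) else pix
    img
  }
  files <- list()
  for (s in names(gd$data)) {
    for (r in seq_along(gd$run_lengths)) {
      m <- gd$data[[s]][[r]]
      vol <- matrix(0, prod(gd$dims), ncol(m))
      vol[gd$voxel_index, ] <- m
      dim(vol) <- c(gd$dims, ncol(m))
      f <- file.path(dir, sprintf("%s_run%02d%s", s, r, ext))
      RNifti::writeNifti(as_img(vol, time = TRUE), f)
      files[[length(files) + 1L]] <- list(subject = s,
                                          group = unname(gd$group_labels[s]),
                                          run = r, path = basename(f))
    }
  }
  for (mk in c("brain", "wm", "csf")) {
    f <- file.path(dir, paste0("mask_", mk, ext))
    RNifti::writeNifti(as_img(array(as.numeric(gd$masks[[mk]]), gd$dims)), f)
  }
  manifest <- list(tr_s = gd$tr_s, voxel_size_mm = gd$voxel_size_mm,
                   dims = gd$dims, run_lengths = gd$run_lengths,
                   masks = as.list(setNames(paste0("mask_", c("brain", "wm", "csf"), ext),
                                            c("brain", "wm", "csf"))),
                   files = files)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

read_mask <- function(path, what) {
  arr <- as.array(RNifti::readNifti(path))
  vals <- unique(as.vector(arr))
  if (!all(vals %in% c(0, 1)))
    stop(sprintf("%s mask at %s is not binary", what, path))
  array(arr > 0, dim(arr))
}

#' Load a group dataset from a NIfTI manifest
#'
#' Reads the per-subject, per-run volumes listed in a `manifest.json`
#' (see [write_group_dataset()]), masks them with the brain mask in a
#' consistent voxel order shared across subjects, and optionally drops a
#' leading pre-stimulus period (`round(drop_initial_s / tr_s)` samples
#' per run; the study design removes 12.3 s measured before the
#' narrative starts).
#'
#' @param manifest path to `manifest.json` or an equivalent list.
#' @param drop_initial_s leading seconds to discard from every run
#'   (default 0; set to 12.3 to reproduce the study convention).
#' @return a [group_dataset()].
#' @export
load_group_dataset <- function(manifest, drop_initial_s = 0) {
  if (is.character(manifest)) {
    dir <- dirname(manifest)
    manifest <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  } else dir <- "."
  tr_s <- manifest$tr_s
  dims <- as.integer(unlist(manifest$dims))
  run_lengths <- as.integer(unlist(manifest$run_lengths))
  masks <- list(brain = read_mask(file.path(dir, manifest$masks$brain), "brain"),
                wm = read_mask(file.path(dir, manifest$masks$wm), "white-matter"),
                csf = read_mask(file.path(dir, manifest$masks$csf), "CSF"))
  for (mk in c("brain", "wm", "csf"))
    if (!identical(as.integer(dim(masks[[mk]])), dims))
      stop(sprintf("%s mask does not match the grid dimensions", mk))
  voxel_index <- which(masks$brain)
  drop_n <- as.integer(round(drop_initial_s / tr_s))

  entries <- manifest$files
  subjects <- unique(vapply(entries, function(e) e$subject, character(1)))
  labels <- setNames(
    vapply(subjects, function(s)
      entries[[which(vapply(entries, function(e) e$subject, character(1)) == s)[1]]]$group,
      character(1)), subjects)
  data <- setNames(lapply(subjects, function(s) vector("list", length(run_lengths))),
                   subjects)
  for (s in subjects) {
    for (r in seq_along(run_lengths)) {
      hit <- Filter(function(e) e$subject == s && e$run == r, entries)
      if (length(hit) == 0)
        stop(sprintf("manifest is missing subject %s run %d", s, r))
      f <- file.path(dir, hit[[1]]$path)
      if (!file.exists(f))
        stop(sprintf("file for subject %s run %d not found: %s", s, r, f))
      arr <- as.array(RNifti::readNifti(f))
      if (!identical(as.integer(dim(arr)[1:3]), dims))
        stop(sprintf("subject %s run %d: grid shape mismatch", s, r))
      Tt <- dim(arr)[4]
      dim(arr) <- c(prod(dims), Tt)
      m <- arr[voxel_index, , drop = FALSE]
      if (drop_n > 0) {
        if (drop_n >= ncol(m))
          stop(sprintf("subject %s run %d: drop of %d samples leaves no data",
                       s, r, drop_n))
        m <- m[, -(seq_len(drop_n)), drop = FALSE]
      }
      if (ncol(m) != run_lengths[r] - drop_n)
        stop(sprintf("subject %s run %d: expected %d timepoints, found %d",
                     s, r, run_lengths[r] - drop_n, ncol(m)))
      data[[s]][[r]] <- m
    }
  }
  group_dataset(data = data, group_labels = labels, masks = masks,
                tr_s = tr_s, run_lengths = run_lengths - drop_n,
                voxel_index = voxel_index, dims = dims,
                voxel_size_mm = manifest$voxel_size_mm)
}

#' Write a per-voxel statistic map as NIfTI
#'
#' @param values numeric vector, one value per analysis voxel row.
#' @param gd the [group_dataset()] the rows refer to.
#' @param voxel_rows row indices the values correspond to.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_stat_map <- function(values, gd, voxel_rows, path) {
  vol <- array(NA_real_, gd$dims)
  vol[gd$voxel_index[voxel_rows]] <- values
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep(gd$voxel_size_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a cluster table as TSV
#' @param tab a `cluster_table`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cluster_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full imaging pipeline on a dataset
#'
#' Orchestrates preprocessing, per-group ISC with run aggregation, the
#' circular-shift null with FDR thresholding, and the cluster-based
#' group contrast; writes NIfTI maps, TSV tables and a JSON manifest
#' (parameters, seed, output hashes) sufficient to reproduce the run.
#'
#' @param gd a [group_dataset()] (e.g. from [generate_group_bold()] or
#'   [load_group_dataset()]).
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param preprocess list of arguments for [preprocess_dataset()], or
#'   `NULL` to analyse the data as given.
#' @param n_realizations circular-shift null size per group.
#' @param n_permutations cluster-contrast permutations.
#' @param cdt_p cluster-defining threshold.
#' @param fdr_q FDR level for within-group maps.
#' @param connectivity cluster connectivity (6/18/26).
#' @param seed RNG seed for all resampling.
#' @return list with per-group `isc`, `maps` (mean/max, p, FDR mask),
#'   `null`, the `clusters` table, `dvars` (if preprocessing ran) and
#'   `manifest`.
#' @export
run_full_pipeline <- function(gd, out_dir = NULL, preprocess = list(),
                              n_realizations = 500000,
                              n_permutations = 5000, cdt_p = 0.001,
                              fdr_q = 0.001, connectivity = 26,
                              seed = 1L) {
  for (g in c("A", "B"))
    if (length(subjects_in_group(gd, g)) < 2)
      stop(sprintf("group %s has fewer than 2 subjects; ISC needs at least 2", g))
  dvars <- NULL
  if (!is.null(preprocess)) {
    pp <- do.call(preprocess_dataset, c(list(gd), preprocess))
    gd <- pp$dataset
    dvars <- pp$dvars
  }
  vox <- analysis_voxels(gd)
  res <- list()
  for (g in c("A", "B")) {
    isc <- compute_isc(gd, g, vox)
    map <- group_mean_map(isc)
    null <- circular_shift_null(gd, g, n_realizations,
                                seed = seed + match(g, c("A", "B")),
                                voxel_rows = vox)
    p <- voxelwise_pvalues(map$mean_isc, null)
    fdr <- fdr_correct(p, fdr_q)
    res[[g]] <- list(isc = isc, map = map, null = null, p = p,
                     fdr_mask = fdr$mask, p_adjusted = fdr$p_adjusted)
  }
  clusters <- cluster_permutation_contrast(
    res$A$isc$aggregated_z, res$B$isc$aggregated_z,
    dims = gd$dims, voxel_index = gd$voxel_index[vox],
    n_permutations = n_permutations, cdt_p = cdt_p,
    seed = seed + 10L, connectivity = connectivity,
    voxel_size_mm = gd$voxel_size_mm)

  manifest <- list(seed = seed, n_realizations = n_realizations,
                   n_permutations = n_permutations, cdt_p = cdt_p,
                   fdr_q = fdr_q, connectivity = connectivity,
                   n_voxels = length(vox),
                   n_pairs = nrow(res$A$isc$pair_index),
                   run_lengths = gd$run_lengths,
                   package_version = as.character(utils::packageVersion("naturalisc")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character()
    for (g in c("A", "B")) {
      paths <- c(paths,
        write_stat_map(res[[g]]$map$mean_isc, gd, vox,
                       file.path(out_dir, sprintf("isc_mean_%s.nii.gz", g))),
        write_stat_map(res[[g]]$map$max_isc, gd, vox,
                       file.path(out_dir, sprintf("isc_max_%s.nii.gz", g))),
        write_stat_map(res[[g]]$p, gd, vox,
                       file.path(out_dir, sprintf("isc_p_%s.nii.gz", g))),
        write_stat_map(as.numeric(res[[g]]$fdr_mask), gd, vox,
                       file.path(out_dir, sprintf("isc_fdrmask_%s.nii.gz", g))))
    }
    paths <- c(paths, write_cluster_table(clusters,
                                          file.path(out_dir, "clusters.tsv")))
    if (!is.null(dvars)) {
      f <- file.path(out_dir, "dvars.tsv")
      utils::write.table(dvars, f, sep = "\t", row.names = FALSE, quote = FALSE)
      paths <- c(paths, f)
    }
    manifest$output_md5 <- as.list(tools::md5sum(paths))
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(groups = res, clusters = clusters, dvars = dvars, manifest = manifest)
}
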