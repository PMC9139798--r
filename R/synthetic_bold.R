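#' Configuration for the group-structured BOLD simulator
#'
#' Describes a two-group naturalistic-stimulation experiment: every subject
#' receives a stimulus-locked signal common to all subjects, a signal shared
#' only within their group, and private noise, mixed voxelwise according to
#' variance fractions. All latent signals are unit-variance Gaussian AR(1)
#' processes so that resampling nulls are exercised under temporal
#' autocorrelation. Defaults mirror the study design this simulator
#' emulates: 24 subjects per group, 10 runs of 4.8 to 8.4 minutes at
#' TR = 100 ms on a 3 mm grid.
#'
#' @param n_per_group subjects per group.
#' @param n_runs number of functional runs.
#' @param run_lengths integer vector of time points per run; default spreads
#'   run durations evenly between 4.8 and 8.4 minutes at `tr_s`.
#' @param grid_shape 3D voxel grid dimensions.
#' @param voxel_size_mm voxel edge length in millimetres.
#' @param tr_s sampling interval in seconds.
#' @param shared_var_frac fraction of voxel variance carried by the
#'   all-subject stimulus signal; scalar or 3D array over the grid.
#' @param group_var_frac per-group fraction carried by the group-specific
#'   signal; a list with elements `A` and `B`, each scalar or 3D array.
#' @param artifact_amplitude scale of the subject-specific artifact course
#'   added inside that subject's nuisance-mask voxels (0 disables).
#' @param artifact_gray_bleed fraction of the artifact amplitude leaking
#'   into analysis voxels (used to exercise nuisance regression).
#' @param ar_phi lag-1 autoregression coefficient of all latent signals.
#' @param seed RNG seed.
#' @return An object of class `bold_sim_config`.
#' @export
bold_sim_config <- function(n_per_group = 24, n_runs = 10,
                            run_lengths = NULL,
                            grid_shape = c(12, 12, 12), voxel_size_mm = 3,
                            tr_s = 0.1,
                            shared_var_frac = 0,
                            group_var_frac = list(A = 0, B = 0),
                            artifact_amplitude = 0,
                            artifact_gray_bleed = 0,
                            ar_phi = 0.3, seed = 1L) {
  if (is.null(run_lengths)) {
    mins <- seq(4.8, 8.4, length.out = n_runs)
    run_lengths <- as.integer(round(mins * 60 / tr_s))
  }
  if (length(run_lengths) != n_runs)
    stop("configuration error: length(run_lengths) must equal n_runs")
  if (any(run_lengths < 2)) stop("configuration error: run_lengths must all be >= 2")
  if (length(grid_shape) != 3L || any(grid_shape < 1))
    stop("configuration error: grid_shape must be three positive integers")
  if (n_per_group < 1) stop("configuration error: n_per_group must be >= 1")
  if (abs(ar_phi) >= 1) stop("configuration error: |ar_phi| must be < 1")
  if (!is.list(group_var_frac) || !all(c("A", "B") %in% names(group_var_frac)))
    stop("configuration error: group_var_frac must be list(A = , B = )")
  chk_frac <- function(x, nm) {
    if (any(x < 0 | x > 1))
      stop(sprintf("configuration error: %s must lie in [0, 1]", nm))
  }
  chk_frac(shared_var_frac, "shared_var_frac")
  chk_frac(group_var_frac$A, "group_var_frac$A")
  chk_frac(group_var_frac$B, "group_var_frac$B")
  for (g in c("A", "B"))
    if (any(shared_var_frac + group_var_frac[[g]] > 1 + 1e-12))
      stop("configuration error: shared_var_frac + group_var_frac must be <= 1 everywhere")
  structure(
    list(n_per_group = as.integer(n_per_group), n_runs = as.integer(n_runs),
         run_lengths = as.integer(run_lengths),
         grid_shape = as.integer(grid_shape), voxel_size_mm = voxel_size_mm,
         tr_s = tr_s, shared_var_frac = shared_var_frac,
         group_var_frac = group_var_frac,
         artifact_amplitude = artifact_amplitude,
         artifact_gray_bleed = artifact_gray_bleed,
         ar_phi = ar_phi, seed = as.integer(seed)),
    class = "bold_sim_config"
  )
}

# Stationary unit-variance Gaussian AR(1) sample paths, one per row.
ar1_matrix <- function(n_series, n_time, phi) {
  ar1_matrix_cpp(as.integer(n_series), as.integer(n_time), phi)
}

# Expand a scalar or grid-shaped array of variance fractions to the masked
# voxel vector.
expand_frac <- function(frac, dims, voxel_index) {
  if (length(frac) == 1L) return(rep(as.numeric(frac), length(voxel_index)))
  frac <- as.array(frac)
  if (!identical(as.integer(dim(frac)), as.integer(dims)))
    stop("variance-fraction array does not match grid_shape")
  as.numeric(frac[voxel_index])
}

#' Simulate a two-group BOLD dataset with known ground truth
#'
#' Generates masked voxel-by-time matrices for two groups of subjects. At a
#' voxel with shared variance fraction `s` and group fraction `g`, the
#' expected pairwise Pearson correlation is `s + g` within a group and `s`
#' between groups, which is the construction the ISC recovery tests lean
#' on. Brain, white-matter and CSF masks are emitted; the WM and CSF masks
#' occupy the two opposite faces of the grid and contain pure noise plus
#' any subject-specific artifact. Every emitted voxel time series is
#' standardized to sample mean 0 and variance 1 (standardization leaves
#' Pearson correlations untouched). Generating signals are returned in
#' `$ground_truth` for recovery assertions only.
#'
#' @param config a [bold_sim_config()].
#' @return A [group_dataset()] with subjects `A1..An, B1..Bn`.
#' @export
generate_group_bold <- function(config) {
  stopifnot(inherits(config, "bold_sim_config"))
  set.seed(config$seed)
  dims <- config$grid_shape
  grid <- array(FALSE, dims)
  brain <- !grid
  wm <- grid; wm[1, , ] <- TRUE
  csf <- grid; csf[dims[1], , ] <- TRUE
  if (dims[1] < 3)
    stop("configuration error: grid_shape[1] must be >= 3 to fit nuisance slabs")
  voxel_index <- which(brain)
  V <- length(voxel_index)
  nuis_rows <- which((wm | csf)[voxel_index])

  s_frac <- expand_frac(config$shared_var_frac, dims, voxel_index)
  g_frac <- list(A = expand_frac(config$group_var_frac$A, dims, voxel_index),
                 B = expand_frac(config$group_var_frac$B, dims, voxel_index))
  # nuisance voxels carry no stimulus- or group-locked signal
  s_frac[nuis_rows] <- 0
  g_frac$A[nuis_rows] <- 0
  g_frac$B[nuis_rows] <- 0

  ids <- c(paste0("A", seq_len(config$n_per_group)),
           paste0("B", seq_len(config$n_per_group)))
  labels <- setNames(rep(c("A", "B"), each = config$n_per_group), ids)
  data <- setNames(vector("list", length(ids)), ids)
  for (s in ids) data[[s]] <- vector("list", config$n_runs)
  truth <- list(shared = vector("list", config$n_runs),
                group_sig = vector("list", config$n_runs),
                artifact = vector("list", config$n_runs))

  sq_s <- sqrt(s_frac)
  sq_g <- lapply(g_frac, sqrt)
  sq_n <- list(A = sqrt(pmax(0, 1 - s_frac - g_frac$A)),
               B = sqrt(pmax(0, 1 - s_frac - g_frac$B)))

  any_s <- any(s_frac > 0)
  any_g <- c(A = any(g_frac$A > 0), B = any(g_frac$B > 0))
  for (r in seq_len(config$n_runs)) {
    Tt <- config$run_lengths[r]
    shared <- if (any_s) ar1_matrix(V, Tt, config$ar_phi) else NULL
    gsig <- list(A = if (any_g["A"]) ar1_matrix(V, Tt, config$ar_phi) else NULL,
                 B = if (any_g["B"]) ar1_matrix(V, Tt, config$ar_phi) else NULL)
    truth$shared[[r]] <- shared
    truth$group_sig[[r]] <- gsig
    art_run <- list()
    for (s in ids) {
      g <- labels[[s]]
      x <- sq_n[[g]] * ar1_matrix(V, Tt, config$ar_phi)
      if (any_s) x <- x + sq_s * shared
      if (any_g[g]) x <- x + sq_g[[g]] * gsig[[g]]
      if (config$artifact_amplitude > 0) {
        a <- drop(ar1_matrix(1, Tt, config$ar_phi))
        art_run[[s]] <- a
        x[nuis_rows, ] <- x[nuis_rows, ] +
          config$artifact_amplitude * rep(a, each = length(nuis_rows))
        if (config$artifact_gray_bleed > 0) {
          gray <- setdiff(seq_len(V), nuis_rows)
          x[gray, ] <- x[gray, ] +
            config$artifact_amplitude * config$artifact_gray_bleed *
            rep(a, each = length(gray))
        }
      }
      data[[s]][[r]] <- standardize_rows_cpp(x)
    }
    truth$artifact[[r]] <- art_run
  }

  group_dataset(data = data, group_labels = labels,
                masks = list(brain = brain, wm = wm, csf = csf),
                tr_s = config$tr_s, run_lengths = config$run_lengths,
                voxel_index = voxel_index, dims = dims,
                voxel_size_mm = config$voxel_size_mm,
                ground_truth = c(truth,
                                 list(shared_var_frac = s_frac,
                                      group_var_frac = g_frac)))
}
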