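#' Moments of the reference clinical cohort
#'
#' Published summary statistics (mean, SD, or male/female counts) for a
#' cohort of 20 HBV-related cirrhotic patients and 20 healthy controls,
#' used as the default targets of [generate_clinical_table()].
#'
#' @format A list with per-variable entries; laboratory indices are
#'   available for patients only.
#' @export
clinical_reference <- list(
  age      = list(patient = c(mean = 51.65, sd = 11.25),
                  control = c(mean = 51.00, sd = 10.13)),
  sex_male = list(patient = c(male = 11, female = 9),
                  control = c(male = 14, female = 6)),
  ammonia          = c(mean = 51.60, sd = 33.34),  # umol/L, patients only
  albumin          = c(mean = 34.30, sd = 4.75),
  bilirubin        = c(mean = 20.73, sd = 9.84),
  prothrombin_time = c(mean = 38.78, sd = 9.24)
)

#' Default network-level connectivity targets (Fisher z scale)
#'
#' Symmetric 3x3 matrices indexed by (PVN, HVN, PVN) giving the target
#' intra-network (diagonal) and inter-network (off-diagonal) functional
#' connectivity on the Fisher z scale, one per group. Defaults reproduce
#' the group-mean connectivity pattern reported for cirrhotic patients and
#' healthy controls: patients show reduced HVN--PVN and HVN--VSN coupling.
#'
#' @param group `"patient"` or `"control"`.
#' @return A symmetric 3x3 numeric matrix with dimnames
#'   `c("PVN","HVN","VSN")`.
#' @export
default_target_z <- function(group = c("control", "patient")) {
  group <- match.arg(group)
  nets <- c("PVN", "HVN", "VSN")
  m <- if (group == "control") {
    matrix(c(0.9567, 0.3021, 0.0996,
             0.3021, 0.4479, 0.1292,
             0.0996, 0.1292, 0.3293), 3, 3, byrow = TRUE)
  } else {
    matrix(c(0.8102, 0.1108, 0.0294,
             0.1108, 0.3950, 0.0499,
             0.0294, 0.0499, 0.3092), 3, 3, byrow = TRUE)
  }
  dimnames(m) <- list(nets, nets)
  m
}

#' Configuration of a synthetic cohort
#'
#' Bundles every parameter of the synthetic-data generators: cohort and
#' acquisition geometry, target network connectivity per group, noise and
#' drift levels, the injected gray-matter group effect, motion-spike
#' probability and the master seed. Defaults emulate the reference study:
#' 20 subjects per group, 240 volumes at TR = 2 s, and 19 visual ROIs
#' split 2/4/13 into PVN, HVN and VSN.
#'
#' @param n_per_group Subjects per group (patients and controls).
#' @param n_volumes BOLD volumes per run (before discarding).
#' @param tr Repetition time in seconds.
#' @param grid_shape Integer vector of 3 voxel dimensions.
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @param roi_count Number of atlas ROIs.
#' @param network_sizes Named integer vector: ROIs per network
#'   (PVN, HVN, VSN); must sum to `roi_count`.
#' @param target_z List with elements `patient` and `control`, each a
#'   symmetric 3x3 matrix of network-level z-scale connectivity targets.
#' @param drift_amplitude Amplitude (signal units) of the slow scanner
#'   drift added to ROI voxels; the drift is a sum of two sinusoids with
#'   periods 128 s and 200 s (below the 0.01 Hz pass-band edge), with
#'   ROI-specific phases.
#' @param noise_sd SD of the white voxel noise added to the unit-variance
#'   ROI signals.
#' @param gm_effect_d Cohen's d of the gray-matter reduction injected in
#'   patients inside `gm_effect_mask` (0 = null cohort).
#' @param gm_effect_mask Integer matrix of voxel coordinates (rows = voxels,
#'   3 columns), or `NULL` to use the voxels of the first atlas ROI.
#' @param gm_noise_sd SD of the between-subject gray-matter noise.
#' @param motion_spike_prob Probability that a subject's motion trace
#'   contains a spike exceeding the 2 mm / 2 degree exclusion threshold.
#' @param seed Master seed; per-subject seeds are derived from it by a
#'   counter-based scheme so that changing the cohort size does not
#'   reshuffle existing subjects.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_per_group = 4, grid_shape = c(16, 16, 16))
#' cfg$network_sizes
#' @export
sim_config <- function(n_per_group = 20,
                       n_volumes = 240,
                       tr = 2.0,
                       grid_shape = c(24L, 24L, 24L),
                       voxel_size_mm = 4,
                       roi_count = 19,
                       network_sizes = c(PVN = 2L, HVN = 4L, VSN = 13L),
                       target_z = list(patient = default_target_z("patient"),
                                       control = default_target_z("control")),
                       drift_amplitude = 1,
                       noise_sd = 0.5,
                       gm_effect_d = 2,
                       gm_effect_mask = NULL,
                       gm_noise_sd = 0.1,
                       motion_spike_prob = 0.05,
                       seed = 1L) {
  stopifnot(n_per_group >= 1, n_volumes > 4, tr > 0,
            length(grid_shape) == 3, all(grid_shape >= 4),
            voxel_size_mm > 0, roi_count >= 1,
            noise_sd >= 0, gm_noise_sd >= 0, drift_amplitude >= 0,
            motion_spike_prob >= 0, motion_spike_prob <= 1)
  if (sum(network_sizes) != roi_count)
    stop("`network_sizes` must sum to `roi_count` (",
         sum(network_sizes), " != ", roi_count, ")")
  if (length(network_sizes) != 3 || is.null(names(network_sizes)))
    names(network_sizes) <- c("PVN", "HVN", "VSN")[seq_along(network_sizes)]
  for (g in c("patient", "control")) {
    z <- target_z[[g]]
    if (is.null(z) || !is.matrix(z) || !all(dim(z) == c(3, 3)))
      stop("`target_z$", g, "` must be a 3x3 matrix")
    if (max(abs(z - t(z))) > 1e-8)
      stop("`target_z$", g, "` must be symmetric")
    if (is.null(dimnames(z)))
      dimnames(target_z[[g]]) <- list(names(network_sizes),
                                      names(network_sizes))
  }
  structure(list(
    n_per_group = as.integer(n_per_group),
    n_volumes = as.integer(n_volumes),
    tr = tr,
    grid_shape = as.integer(grid_shape),
    voxel_size_mm = voxel_size_mm,
    roi_count = as.integer(roi_count),
    network_sizes = setNames(as.integer(network_sizes), names(network_sizes)),
    target_z = target_z,
    drift_amplitude = drift_amplitude,
    noise_sd = noise_sd,
    gm_effect_d = gm_effect_d,
    gm_effect_mask = gm_effect_mask,
    gm_noise_sd = gm_noise_sd,
    motion_spike_prob = motion_spike_prob,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d subjects/group, %d volumes @ TR %.1f s\n",
              x$n_per_group, x$n_volumes, x$tr))
  cat(sprintf("  grid %s, %.0f mm voxels, %d ROIs (%s)\n",
              paste(x$grid_shape, collapse = "x"), x$voxel_size_mm,
              x$roi_count,
              paste(names(x$network_sizes), x$network_sizes,
                    sep = "=", collapse = ", ")))
  cat(sprintf("  noise sd %.2f, drift %.2f, GM effect d = %.1f, seed %d\n",
              x$noise_sd, x$drift_amplitude, x$gm_effect_d, x$seed))
  invisible(x)
}
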