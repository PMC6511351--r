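#' Generate a block atlas of vision-related ROIs
#'
#' Places `roi_count` disjoint cubic ROIs (3x3x3 voxels) on a regular
#' interior lattice of the simulation grid, none touching the grid
#' boundary, and assigns them to the three vision-related networks in
#' order: PVN, then HVN, then VSN. The atlas is a stand-in for a
#' resting-state parcellation restricted to visual regions; its geometry
#' is deterministic given the grid, so identical configurations yield
#' byte-identical label volumes.
#'
#' @param config A [sim_config()].
#' @return An object of class `atlas_networks`: list with `labels` (3D
#'   integer array, 0 = background), `assignment` (named character vector,
#'   ROI id -> network), `affine` (4x4 voxel-to-world matrix) and
#'   `voxel_size_mm`.
#' @examples
#' atlas <- generate_atlas(sim_config(grid_shape = c(16, 16, 16),
#'                                    roi_count = 3,
#'                                    network_sizes = c(1, 1, 1)))
#' table(atlas$assignment)
#' @export
generate_atlas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  dims <- config$grid_shape
  block <- 3L
  # lattice of block starts: margin 1 voxel from every face, 1 voxel gaps
  starts <- lapply(dims, function(d) {
    s <- seq(2L, d - block, by = block + 1L)
    s[s + block - 1L <= d - 1L]
  })
  sites <- as.matrix(expand.grid(starts[[1]], starts[[2]], starts[[3]]))
  if (nrow(sites) < config$roi_count)
    stop("grid ", paste(dims, collapse = "x"), " too small to place ",
         config$roi_count, " disjoint 3x3x3 ROIs (", nrow(sites),
         " sites available)")
  labels <- array(0L, dims)
  for (r in seq_len(config$roi_count)) {
    s <- sites[r, ]
    labels[s[1]:(s[1] + block - 1L),
           s[2]:(s[2] + block - 1L),
           s[3]:(s[3] + block - 1L)] <- r
  }
  assignment <- rep(names(config$network_sizes), config$network_sizes)
  names(assignment) <- as.character(seq_len(config$roi_count))
  vs <- config$voxel_size_mm
  affine <- diag(c(vs, vs, vs, 1))
  affine[1:3, 4] <- -vs * dims / 2
  structure(list(labels = labels, assignment = assignment,
                 affine = affine, voxel_size_mm = vs),
            class = "atlas_networks")
}

#' @export
print.atlas_networks <- function(x, ...) {
  cat(sprintf("Atlas: %d ROIs on a %s grid (%s)\n",
              max(x$labels), paste(dim(x$labels), collapse = "x"),
              paste(names(table(x$assignment)), table(x$assignment),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

# Expand a 3x3 network-level z target into an ROI x ROI correlation matrix:
# within-network pairs share the intra value, cross-network pairs the inter
# value. Non-positive-semi-definite targets are repaired by clipping
# negative eigenvalues at zero and renormalizing to unit diagonal.
expand_target_corr <- function(target_z, network_sizes) {
  r3 <- tanh(target_z)
  net <- rep(seq_along(network_sizes), network_sizes)
  R <- length(net)
  M <- r3[cbind(rep(net, R), rep(net, each = R))]
  M <- matrix(M, R, R)
  diag(M) <- 1
  ev <- eigen(M, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    bad <- which(ev$values < 0)
    warning("target correlation matrix is not positive semi-definite ",
            "(eigenvalues ", paste(signif(ev$values[bad], 3), collapse = ", "),
            "); clipping at zero and renormalizing")
    v <- pmax(ev$values, 0)
    M <- ev$vectors %*% (v * t(ev$vectors))
    d <- sqrt(diag(M))
    M <- M / tcrossprod(d)
  }
  M
}

# Draw T x R ROI signals with population correlation `corr` (unit variance).
draw_roi_signals <- function(corr, n_t) {
  L <- chol(corr + diag(1e-10, nrow(corr)))
  matrix(rnorm(n_t * nrow(corr)), n_t) %*% L
}

# Slow scanner drift: two sinusoids with periods 128 s and 200 s, both
# below the 0.01 Hz pass-band edge. Phases vary per ROI (column of
# `phases`, a 2 x R matrix) so the drift is a spatially varying nuisance,
# not a shared signal: what the band-pass leaves of it (finite-window
# spectral leakage) is then uncorrelated across ROIs.
drift_signal <- function(n_t, tr, amplitude, phases) {
  tt <- (seq_len(n_t) - 1) * tr
  amplitude * (sin(outer(2 * pi * tt / 128, phases[1, ], "+")) +
               sin(outer(2 * pi * tt / 200, phases[2, ], "+")))
}

#' Simulate one subject's BOLD run
#'
#' Generates a 4D BOLD volume on the atlas grid. Each ROI receives a
#' unit-variance Gaussian signal; the population correlation matrix of the
#' ROI signals equals the ROI-level expansion of `tanh(group_target_z)`
#' (within-network pairs share the intra-network value, cross-network
#' pairs the inter-network value). Every ROI voxel is its ROI signal plus
#' white noise and a slow sinusoidal drift; background voxels are pure
#' white noise.
#'
#' @param atlas An [generate_atlas()] result.
#' @param group_target_z Symmetric 3x3 z-scale connectivity target.
#' @param config A [sim_config()].
#' @param subject_seed Integer seed for this subject's draws.
#' @return A `bold4d` object: list with `data` (4D array x,y,z,t),
#'   `affine` and `tr`.
#' @export
generate_bold <- function(atlas, group_target_z, config, subject_seed) {
  stopifnot(inherits(atlas, "atlas_networks"), inherits(config, "sim_config"))
  if (!all(is.finite(group_target_z)))
    stop("`group_target_z` entries must be finite")
  corr <- expand_target_corr(group_target_z, config$network_sizes)
  dims <- dim(atlas$labels)
  n_t <- config$n_volumes
  v <- prod(dims)
  lab <- as.integer(atlas$labels)
  roivox <- which(lab > 0L)
  n_roi <- nrow(corr)
  withr::with_seed(subject_seed, {
    signals <- draw_roi_signals(corr, n_t)            # T x R
    phases <- matrix(runif(2 * n_roi, 0, 2 * pi), 2)
    noise <- if (config$noise_sd > 0)
      matrix(rnorm(v * n_t, 0, config$noise_sd), v, n_t)
    else matrix(0, v, n_t)
  })
  drift <- drift_signal(n_t, config$tr, config$drift_amplitude, phases)
  noise[roivox, ] <- noise[roivox, ] +
    t(signals + drift)[lab[roivox], , drop = FALSE]
  bold4d(array(noise, c(dims, n_t)), atlas$affine, config$tr)
}

#' Construct a BOLD run object
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param affine 4x4 voxel-to-world matrix.
#' @param tr Repetition time, seconds.
#' @return A `bold4d` object.
#' @export
bold4d <- function(data, affine = diag(4), tr = 2) {
  stopifnot(length(dim(data)) == 4, dim(data)[4] >= 1, tr > 0,
            all(dim(affine) == c(4, 4)),
            abs(det(affine)) > .Machine$double.eps)
  structure(list(data = data, affine = affine, tr = tr), class = "bold4d")
}

#' @export
print.bold4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("BOLD run: %s voxels x %d volumes @ TR %.2f s\n",
              paste(d[1:3], collapse = "x"), d[4], x$tr))
  invisible(x)
}

#' Simulate ROI-mean time series directly (voxel-free shortcut)
#'
#' Emulates the ROI-mean series that [extract_roi_timeseries()] would
#' recover from [generate_bold()] output without materializing the voxel
#' grid: ROI signal plus the mean of `n_voxels_per_roi` independent white
#' noise draws (SD `noise_sd / sqrt(n_voxels_per_roi)`) plus the shared
#' drift. Useful for large simulation studies of the connectivity
#' statistics.
#'
#' @inheritParams generate_bold
#' @param n_voxels_per_roi Voxels per ROI being averaged (27 for the
#'   default 3x3x3 atlas blocks).
#' @return A `roi_timeseries` object (see [extract_roi_timeseries()]).
#' @export
generate_roi_timeseries <- function(config, group_target_z, subject_seed,
                                    n_voxels_per_roi = 27) {
  stopifnot(inherits(config, "sim_config"), n_voxels_per_roi >= 1)
  corr <- expand_target_corr(group_target_z, config$network_sizes)
  n_t <- config$n_volumes
  r <- config$roi_count
  withr::with_seed(subject_seed, {
    signals <- draw_roi_signals(corr, n_t)
    phases <- matrix(runif(2 * r, 0, 2 * pi), 2)
    noise <- matrix(rnorm(r * n_t, 0,
                          config$noise_sd / sqrt(n_voxels_per_roi)), r, n_t)
  })
  drift <- drift_signal(n_t, config$tr, config$drift_amplitude, phases)
  m <- t(signals + drift) + noise
  roi_timeseries(m, seq_len(r), config$tr)
}

#' Simulate gray-matter density maps for both groups
#'
#' Control maps are a smooth radial base template plus white
#' between-subject noise; patient maps are drawn identically except that
#' the mean inside `gm_effect_mask` is reduced by
#' `gm_effect_d * gm_noise_sd`, emulating a localized gray-matter deficit.
#'
#' @param atlas An [generate_atlas()] result.
#' @param config A [sim_config()]; `gm_effect_mask = NULL` uses the voxels
#'   of atlas ROI 1.
#' @param n_per_group Optional override of `config$n_per_group`.
#' @return List with elements `patient` and `control`, each a list of
#'   `gm_map` objects (list with `data`, `affine`).
#' @export
generate_gm_maps <- function(atlas, config, n_per_group = NULL) {
  stopifnot(inherits(atlas, "atlas_networks"), inherits(config, "sim_config"))
  n <- if (is.null(n_per_group)) config$n_per_group else as.integer(n_per_group)
  dims <- dim(atlas$labels)
  mask <- gm_effect_voxels(atlas, config)
  if (nrow(mask) == 0 && config$gm_effect_d != 0)
    stop("`gm_effect_mask` is empty but `gm_effect_d` is nonzero")
  template <- gm_template(dims)
  delta <- array(0, dims)
  delta[mask] <- config$gm_effect_d * config$gm_noise_sd
  v <- prod(dims)
  draw <- function(stream, i, effect) {
    noise <- withr::with_seed(subject_seed3(config$seed, stream, i),
                              array(rnorm(v, 0, config$gm_noise_sd), dims))
    structure(list(data = template + noise - effect, affine = atlas$affine),
              class = "gm_map")
  }
  list(patient = lapply(seq_len(n), function(i) draw(2L, 2L * i, delta)),
       control = lapply(seq_len(n), function(i) draw(2L, 2L * i + 1L, 0)))
}

gm_template <- function(dims) {
  ax <- lapply(dims, function(d) (seq_len(d) - (d + 1) / 2) / (d / 2))
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  0.4 + 0.35 * exp(-1.5 * r2)
}

gm_effect_voxels <- function(atlas, config) {
  if (is.null(config$gm_effect_mask)) {
    which(atlas$labels == 1L, arr.ind = TRUE)
  } else {
    m <- config$gm_effect_mask
    stopifnot(is.matrix(m), ncol(m) == 3)
    dims <- dim(atlas$labels)
    if (any(m < 1) || any(m > rep(dims, each = nrow(m))))
      stop("`gm_effect_mask` contains voxels outside the grid")
    m
  }
}

#' Simulate a motion-parameter trace
#'
#' Six-column random walk (3 translations in mm, 3 rotations in degrees)
#' with small steps, clamped well inside the 2 mm / 2 degree exclusion
#' threshold. With probability `motion_spike_prob` a single spike larger
#' than 2 units is injected into one column, and the trace carries the
#' ground-truth QC label in its `"exclude"` attribute.
#'
#' @inheritParams generate_bold
#' @return A data frame with columns `tx, ty, tz, rx, ry, rz`, one row per
#'   volume; attribute `exclude` is `TRUE` when a spike was injected.
#' @export
generate_motion_trace <- function(config, subject_seed) {
  stopifnot(inherits(config, "sim_config"), config$n_volumes >= 1)
  n_t <- config$n_volumes
  withr::with_seed(subject_seed, {
    walk <- apply(matrix(rnorm(n_t * 6, 0, 0.02), n_t), 2, cumsum)
    walk <- matrix(pmin(pmax(walk, -1.5), 1.5), n_t)
    spike <- runif(1) < config$motion_spike_prob
    if (spike) {
      col <- sample.int(6, 1)
      row <- sample.int(n_t, 1)
      walk[row, col] <- sign(rnorm(1)) * runif(1, 2.2, 3)
    }
  })
  trace <- as.data.frame(walk)
  names(trace) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  attr(trace, "exclude") <- spike
  trace
}

#' Simulate a clinical covariate table
#'
#' Draws demographics and laboratory indices from the published cohort
#' moments in [clinical_reference]: age for both groups, sex from the
#' reported male/female ratios, and ammonia, albumin, bilirubin and
#' prothrombin time (patients only; `NA` for controls, matching the
#' reference table). Laboratory values are drawn from zero-truncated
#' normals whose location is calibrated so the post-truncation mean equals
#' the reported mean.
#'
#' @param config A [sim_config()].
#' @return Data frame with one row per subject: `subject_id`, `group`,
#'   `age`, `sex`, `ammonia`, `albumin`, `bilirubin`, `prothrombin_time`.
#' @export
generate_clinical_table <- function(config) {
  stopifnot(inherits(config, "sim_config"), config$n_per_group >= 2)
  n <- config$n_per_group
  ref <- clinical_reference
  # zero-truncated normal with the location parameter calibrated so the
  # post-truncation mean equals the reported mean (truncation would
  # otherwise inflate it, e.g. ammonia by ~4 umol/L)
  rtrunc0 <- function(n, m) {
    target <- m[["mean"]]; s <- m[["sd"]]
    mu <- uniroot(function(mu) {
      a <- -mu / s
      mu + s * dnorm(a) / (1 - pnorm(a)) - target
    }, c(target - 4 * s, target + s))$root
    p0 <- pnorm(0, mu, s)
    qnorm(runif(n, p0, 1), mu, s)
  }
  withr::with_seed(subject_seed3(config$seed, 4L, 0L), {
    pat <- data.frame(
      subject_id = sprintf("sub-P%02d", seq_len(n)),
      group = "patient",
      age = rnorm(n, ref$age$patient["mean"], ref$age$patient["sd"]),
      sex = ifelse(runif(n) < ref$sex_male$patient["male"] /
                     sum(ref$sex_male$patient), "M", "F"),
      ammonia = rtrunc0(n, ref$ammonia),
      albumin = rtrunc0(n, ref$albumin),
      bilirubin = rtrunc0(n, ref$bilirubin),
      prothrombin_time = rtrunc0(n, ref$prothrombin_time))
    ctl <- data.frame(
      subject_id = sprintf("sub-C%02d", seq_len(n)),
      group = "control",
      age = rnorm(n, ref$age$control["mean"], ref$age$control["sd"]),
      sex = ifelse(runif(n) < ref$sex_male$control["male"] /
                     sum(ref$sex_male$control), "M", "F"),
      ammonia = NA_real_, albumin = NA_real_, bilirubin = NA_real_,
      prothrombin_time = NA_real_)
  })
  rbind(pat, ctl)
}

# Three-way seed split: (master, stream, counter) -> 32-bit seed.
# Streams: 1 BOLD, 2 GM, 3 motion, 4 clinical.
subject_seed3 <- function(master_seed, stream, counter) {
  as.integer((as.numeric(master_seed) + 7919 * as.numeric(stream) +
                10007 * as.numeric(counter)) %% 2147483647)
}

#' Simulate a full cohort
#'
#' Generates the atlas, per-subject BOLD runs, gray-matter maps and motion
#' traces for both groups, and the clinical table. Per-subject seeds are
#' derived from the master seed by a counter-based scheme (patient i uses
#' counter 2i, control i counter 2i+1), so enlarging the cohort never
#' reshuffles existing subjects.
#'
#' With `out_dir` set, volumes are written to disk as NIfTI-1 (.nii.gz)
#' and tables as TSV as they are generated (memory stays flat), and a JSON
#' manifest describing the cohort — including the ground-truth block — is
#' written and returned. Without `out_dir` everything is kept in memory;
#' prefer small grids in that case.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory, or `NULL` for an in-memory cohort.
#' @param bold Set `FALSE` to skip BOLD generation (e.g. morphometry-only
#'   cohorts).
#' @param gm Set `FALSE` to skip gray-matter maps.
#' @return An object of class `cohort`: list with `config`, `atlas`,
#'   `clinical`, `subjects` (each with `id`, `group`, `bold`, `gm`,
#'   `motion`, `exclude_truth`; data or file paths), and `manifest_path`
#'   when written.
#' @export
simulate_cohort <- function(config, out_dir = NULL, bold = TRUE, gm = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  atlas <- generate_atlas(config)
  clinical <- generate_clinical_table(config)
  write <- !is.null(out_dir)
  if (write) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gm_all <- if (gm) generate_gm_maps(atlas, config) else NULL
  subjects <- list()
  gi <- c(patient = 0L, control = 0L)
  for (row in seq_len(nrow(clinical))) {
    group <- clinical$group[row]
    gi[group] <- gi[group] + 1L
    i <- gi[[group]]
    counter <- if (group == "patient") 2L * i else 2L * i + 1L
    id <- clinical$subject_id[row]
    motion <- generate_motion_trace(config,
                                    subject_seed3(config$seed, 3L, counter))
    sub <- list(id = id, group = group,
                exclude_truth = isTRUE(attr(motion, "exclude")))
    if (bold) {
      run <- generate_bold(atlas, config$target_z[[group]], config,
                           subject_seed3(config$seed, 1L, counter))
      sub$bold <- if (write) {
        p <- file.path(out_dir, paste0(id, "_bold.nii.gz"))
        write_bold(run, p); p
      } else run
    }
    if (gm) {
      gmap <- gm_all[[group]][[i]]
      sub$gm <- if (write) {
        p <- file.path(out_dir, paste0(id, "_gm.nii.gz"))
        write_gm(gmap, p); p
      } else gmap
    }
    sub$motion <- if (write) {
      p <- file.path(out_dir, paste0(id, "_motion.tsv"))
      write_motion(motion, p); p
    } else motion
    subjects[[id]] <- sub
  }
  cohort <- structure(list(config = config, atlas = atlas,
                           clinical = clinical, subjects = subjects),
                      class = "cohort")
  if (write) {
    write_atlas(atlas, file.path(out_dir, "atlas.nii.gz"),
                file.path(out_dir, "networks.tsv"))
    write.table(clinical, file.path(out_dir, "clinical.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cohort$manifest_path <- write_manifest(cohort, out_dir)
  }
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients + %d controls, %d ROIs\n",
              sum(x$clinical$group == "patient"),
              sum(x$clinical$group == "control"), x$config$roi_count))
  invisible(x)
}
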