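#' TFCE parameters
#'
#' Threshold-free cluster enhancement integrates, over thresholds `h`
#' spaced `dh` apart, the term `extent^E * h^H * dh` for the connected
#' component containing each voxel. `E = 0.5`, `H = 2` are the method's
#' canonical exponents; by default `dh` is the map maximum divided by
#' `n_steps = 100`.
#'
#' @param E Extent exponent.
#' @param H Height exponent.
#' @param dh Threshold step; `NULL` for `max(stat)/n_steps`.
#' @param n_steps Number of integration steps when `dh` is `NULL`.
#' @param connectivity Voxel neighborhood, 6 (faces) or 26 (faces, edges,
#'   corners).
#' @return A `tfce_params` list.
#' @export
tfce_params <- function(E = 0.5, H = 2, dh = NULL, n_steps = 100,
                        connectivity = 26) {
  stopifnot(E > 0, H > 0, is.null(dh) || dh > 0, n_steps >= 1,
            connectivity %in% c(6, 26))
  structure(list(E = E, H = H, dh = dh, n_steps = as.integer(n_steps),
                 connectivity = as.integer(connectivity)),
            class = "tfce_params")
}

# Coerce a set of gray-matter maps (list of gm_map / list of arrays /
# V x n matrix) to a V x n matrix plus shape metadata.
as_map_matrix <- function(maps, dims = NULL) {
  if (is.matrix(maps)) {
    stopifnot(!is.null(dims))
    return(list(m = maps, dims = dims, affine = NULL))
  }
  stopifnot(is.list(maps), length(maps) >= 1)
  affine <- NULL
  arrs <- lapply(maps, function(x) {
    if (inherits(x, "gm_map")) { affine <<- x$affine; x$data } else x
  })
  d <- dim(arrs[[1]])
  if (!all(vapply(arrs, function(a) identical(dim(a), d), TRUE)))
    stop("gray-matter maps do not share a common shape")
  m <- vapply(arrs, as.numeric, numeric(prod(d)))
  list(m = matrix(m, nrow = prod(d)), dims = d, affine = affine)
}

#' Voxel-wise two-sample t statistic map
#'
#' Pooled-variance two-sample t (`group_a` minus `group_b`) at every
#' voxel. Voxels with zero pooled variance (e.g. empty background in
#' synthetic data) are set to 0 rather than NaN.
#'
#' @param group_a,group_b Lists of `gm_map` objects or 3D arrays (or
#'   V x n matrices with `dims` supplied).
#' @param dims Grid shape, required for matrix input.
#' @return A `stat_map` object: list with `data` (3D t array), `affine`,
#'   `direction = "a_minus_b"` and group sizes.
#' @export
voxelwise_ttest <- function(group_a, group_b, dims = NULL) {
  a <- as_map_matrix(group_a, dims)
  b <- as_map_matrix(group_b, dims)
  if (!identical(a$dims, b$dims)) stop("group map shapes differ")
  na <- ncol(a$m); nb <- ncol(b$m)
  if (na < 2 || nb < 2) stop("need at least 2 maps per group")
  ma <- rowMeans(a$m); mb <- rowMeans(b$m)
  ssa <- rowSums((a$m - ma)^2); ssb <- rowSums((b$m - mb)^2)
  sp2 <- (ssa + ssb) / (na + nb - 2)
  tt <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  tt[sp2 <= 1e-24] <- 0
  structure(list(data = array(tt, a$dims),
                 affine = if (is.null(a$affine)) diag(4) else a$affine,
                 direction = "a_minus_b", n_a = na, n_b = nb),
            class = "stat_map")
}

#' Threshold-free cluster enhancement
#'
#' Enhances a voxel-wise statistic map: for voxel `p`,
#' `TFCE(p) = sum_h e(h,p)^E * h^H * dh` over thresholds
#' `h = dh, 2dh, ... <= t_p`, where `e(h,p)` is the size of the connected
#' component containing `p` at threshold `h`. Positive and negative
#' statistics are enhanced separately (on the map and its negation); the
#' returned map carries the sign of the input.
#'
#' @param stat A `stat_map` or 3D numeric array.
#' @param params A [tfce_params()].
#' @return Same type as `stat`, with enhanced values (class `tfce_map`
#'   when the input was a `stat_map`).
#' @export
tfce_enhance <- function(stat, params = tfce_params()) {
  stopifnot(inherits(params, "tfce_params"))
  arr <- if (inherits(stat, "stat_map")) stat$data else stat
  stopifnot(is.array(arr), length(dim(arr)) == 3)
  enh <- tfce_cpp(as.numeric(arr), dim(arr), params$E, params$H,
                  if (is.null(params$dh)) -1 else params$dh,
                  params$n_steps, params$connectivity)
  enh <- array(enh, dim(arr))
  if (inherits(stat, "stat_map")) {
    out <- stat
    out$data <- enh
    class(out) <- c("tfce_map", "stat_map")
    out
  } else enh
}

#' Permutation-based FWE-corrected p-values
#'
#' Family-wise error correction by the max-statistic permutation method:
#' group labels are permuted `n_perm` times, each permuted cohort is
#' reduced to its maximum TFCE value (over voxels and both contrast
#' signs), and every voxel's corrected p is
#' `(1 + #\{perm max >= observed TFCE\}) / (1 + n_perm)` — hence never
#' below `1/(n_perm + 1)`. With `exact = TRUE` all distinct group
#' assignments are enumerated instead and `p = #\{assignment max >=
#' observed\} / #assignments` (the identity assignment included).
#'
#' @inheritParams voxelwise_ttest
#' @param params A [tfce_params()].
#' @param n_perm Number of random permutations.
#' @param seed Seed for the permutation draws.
#' @param exact Enumerate all `choose(n, n_a)` assignments (small cohorts
#'   only).
#' @return A `corrected_p` object: list with `data` (3D array of
#'   FWE-corrected p), `t` (the observed [voxelwise_ttest()] map), `tfce`
#'   (observed signed TFCE), `null_max`, `n_perm`, `seed`.
#' @export
permutation_fwe <- function(group_a, group_b, params = tfce_params(),
                            n_perm = 5000, seed = 1, dims = NULL,
                            exact = FALSE) {
  stopifnot(inherits(params, "tfce_params"))
  if (!exact && n_perm < 1) stop("`n_perm` must be at least 1")
  a <- as_map_matrix(group_a, dims)
  b <- as_map_matrix(group_b, dims)
  if (!identical(a$dims, b$dims)) stop("group map shapes differ")
  na <- ncol(a$m); nb <- ncol(b$m); n <- na + nb
  data <- cbind(a$m, b$m)
  obs_t <- voxelwise_ttest(group_a, group_b, dims = dims)
  obs_tfce <- tfce_enhance(obs_t, params)
  if (exact) {
    combos <- utils::combn(n, na)
    perms <- matrix(0L, ncol(combos), n)
    for (i in seq_len(ncol(combos))) perms[i, combos[, i]] <- 1L
  } else {
    base_labels <- c(rep(1L, na), rep(0L, nb))
    perms <- withr::with_seed(seed, {
      t(vapply(seq_len(n_perm), function(i) base_labels[sample.int(n)],
               integer(n)))
    })
  }
  null_max <- perm_max_tfce_cpp(data, perms, a$dims, params$E, params$H,
                                params$n_steps, params$connectivity)
  obs_abs <- abs(as.numeric(obs_tfce$data))
  ns <- sort(null_max)
  tol <- 1e-9 * (1 + abs(obs_abs))
  n_ge <- length(ns) - findInterval(obs_abs - tol, ns)
  p <- if (exact) n_ge / length(ns) else (1 + n_ge) / (1 + length(ns))
  structure(list(data = array(p, a$dims), t = obs_t, tfce = obs_tfce,
                 null_max = null_max, n_perm = length(ns),
                 seed = if (exact) NA_integer_ else seed,
                 affine = obs_t$affine),
            class = "corrected_p")
}

#' Cluster report from a corrected p map
#'
#' Connected components of the suprathreshold set `{p < alpha}`, one
#' record per cluster, sorted by size descending (ties broken by peak p
#' ascending). The peak is the voxel with the smallest corrected p,
#' reported in world (mm) coordinates via the affine. An empty table (no
#' significant voxels) is a valid result, not an error.
#'
#' @param pmap A `corrected_p` object (or a 3D p array plus `affine`).
#' @param alpha Significance threshold on the corrected p (default the
#'   reference study's 0.0002).
#' @param connectivity 6 or 26.
#' @param label_atlas Optional `atlas_networks`; each cluster is labeled
#'   by its modal overlapping ROI and that ROI's network, or
#'   `"unlabeled"` when it overlaps none.
#' @param affine Voxel-to-world matrix for plain-array input.
#' @return Data frame with columns `cluster_size_voxels`, `x_mm`, `y_mm`,
#'   `z_mm`, `peak_p`, `label`.
#' @export
report_clusters <- function(pmap, alpha = 0.0002, connectivity = 26,
                            label_atlas = NULL, affine = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  if (inherits(pmap, "corrected_p")) {
    arr <- pmap$data
    affine <- pmap$affine
  } else {
    arr <- pmap
    if (is.null(affine)) affine <- diag(4)
  }
  dims <- dim(arr)
  mask <- as.numeric(arr) < alpha
  empty <- data.frame(cluster_size_voxels = integer(0), x_mm = numeric(0),
                      y_mm = numeric(0), z_mm = numeric(0),
                      peak_p = numeric(0), label = character(0))
  if (!any(mask)) return(empty)
  lab <- label_components_cpp(mask, dims, connectivity)
  p <- as.numeric(arr)
  recs <- lapply(seq_len(max(lab)), function(k) {
    vox <- which(lab == k)
    peak <- vox[which.min(p[vox])]
    coord <- arrayInd(peak, dims)
    world <- affine %*% c(coord - 1, 1)
    txt <- "unlabeled"
    if (!is.null(label_atlas)) {
      rois <- label_atlas$labels[cbind(arrayInd(vox, dims))]
      rois <- rois[rois > 0]
      if (length(rois)) {
        modal <- as.integer(names(which.max(table(rois))))
        txt <- sprintf("ROI %d (%s)", modal,
                       label_atlas$assignment[[as.character(modal)]])
      }
    }
    data.frame(cluster_size_voxels = length(vox), x_mm = world[1],
               y_mm = world[2], z_mm = world[3], peak_p = p[peak],
               label = txt)
  })
  out <- do.call(rbind, recs)
  out[order(-out$cluster_size_voxels, out$peak_p), , drop = FALSE]
}
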