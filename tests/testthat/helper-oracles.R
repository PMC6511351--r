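# Independent oracles used to cross-check the package's implementations.
# Deliberately naive: plain R, breadth-first flood fill, literal
# definitions.

# Size of the connected component of `mask` containing `start` (3D array
# of logicals; start = length-3 voxel coordinate).
flood_size <- function(mask, start, connectivity = 26) {
  dims <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  seen <- array(FALSE, dims)
  queue <- matrix(start, nrow = 1)
  seen[matrix(start, 1)] <- TRUE
  size <- 0L
  while (nrow(queue) > 0) {
    v <- queue[1, ]
    queue <- queue[-1, , drop = FALSE]
    size <- size + 1L
    for (k in seq_len(nrow(offs))) {
      u <- v + offs[k, ]
      if (any(u < 1) || any(u > dims)) next
      um <- matrix(u, 1)
      if (mask[um] && !seen[um]) {
        seen[um] <- TRUE
        queue <- rbind(queue, u)
      }
    }
  }
  size
}

# Literal threshold-sum TFCE: for every suprathreshold voxel, loop over
# thresholds h = dh, 2dh, ... <= t_v and flood-fill the component at
# each one.
oracle_tfce <- function(arr, E = 0.5, H = 2, dh = 1, connectivity = 26) {
  dims <- dim(arr)
  out <- array(0, dims)
  vox <- which(arr > 0, arr.ind = TRUE)
  for (i in seq_len(nrow(vox))) {
    v <- vox[i, ]
    tv <- arr[matrix(v, 1)]
    s <- 0
    h <- dh
    while (h <= tv + 1e-9) {
      e <- flood_size(arr >= h - 1e-12, v, connectivity)
      s <- s + e^E * h^H * dh
      h <- h + dh
    }
    out[matrix(v, 1)] <- s
  }
  out
}

# Literal Benjamini-Hochberg step-up: largest k with p_(k) <= k*alpha/m;
# reject the k smallest p-values.
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (j in seq_len(m)) if (ps[j] <= j * alpha / m) k <- j
  reject <- rep(FALSE, m)
  if (k > 0) reject[o[seq_len(k)]] <- TRUE
  reject
}

# Small cohort configuration used across tests: 3 single-ROI networks on
# a 12^3 grid.
tiny_config <- function(n_per_group = 4, n_volumes = 60, ...) {
  sim_config(grid_shape = c(12, 12, 12), roi_count = 3,
             network_sizes = c(PVN = 1L, HVN = 1L, VSN = 1L),
             n_per_group = n_per_group, n_volumes = n_volumes, ...)
}

# Hand-built roi_fc object from an explicit z matrix (r = tanh(z)).
fc_from_z <- function(z, roi_ids = seq_len(nrow(z))) {
  r <- tanh(z)
  diag(r) <- 1
  zz <- z
  diag(zz) <- NA_real_
  structure(list(r = r, z = zz, roi_ids = as.integer(roi_ids)),
            class = "roi_fc")
}

# Minimal atlas carrying only an assignment (for network_matrix tests).
atlas_stub <- function(assignment) {
  structure(list(labels = NULL, assignment = assignment, affine = diag(4),
                 voxel_size_mm = 1), class = "atlas_networks")
}
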