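test_that("ROI extraction takes unweighted voxel means per time point", {
  labels <- array(0L, c(4, 4, 4))
  labels[1, 1, 1] <- 1L; labels[2, 1, 1] <- 1L   # two-voxel ROI
  labels[4, 4, 4] <- 2L                          # single-voxel ROI
  atlas <- structure(list(labels = labels,
                          assignment = c("1" = "PVN", "2" = "HVN"),
                          affine = diag(4), voxel_size_mm = 1),
                     class = "atlas_networks")
  arr <- array(0, c(4, 4, 4, 2))
  arr[1, 1, 1, ] <- c(1, 5); arr[2, 1, 1, ] <- c(3, 7)
  arr[4, 4, 4, ] <- c(9, 2)
  ts <- extract_roi_timeseries(bold4d(arr), atlas)
  expect_equal(ts$matrix[1, ], c(2, 6))   # mean of 1,3 and 5,7
  expect_equal(ts$matrix[2, ], c(9, 2))   # single voxel: its own series
  # an assigned ROI with no voxels is an error naming the ROI
  atlas$assignment <- c(atlas$assignment, "3" = "VSN")
  expect_error(extract_roi_timeseries(bold4d(arr), atlas), "3")
  # grid mismatch
  expect_error(extract_roi_timeseries(
    bold4d(array(0, c(3, 3, 3, 2))), atlas), "grid")
})

test_that("pearson_r matches hand-computed values and validates input", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  # direct covariance/variance computation gives 4/5
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(1:4, 1:5), "lengths")
})

test_that("fisher_z is atanh with clamping at |r| = 1", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(fisher_z(-0.3), -fisher_z(0.3))
  expect_warning(z1 <- fisher_z(1), "clamped")
  expect_equal(z1, atanh(1 - 1e-7))
  expect_true(all(diff(fisher_z(seq(-0.9, 0.9, 0.1))) > 0))
})

test_that("network matrix averages pairwise z within and between networks", {
  z <- matrix(0, 3, 3)
  z[1, 2] <- z[2, 1] <- 0.5
  z[1, 3] <- z[3, 1] <- 0.2
  z[2, 3] <- z[3, 2] <- 0.4
  fc <- fc_from_z(z)
  atlas <- atlas_stub(c("1" = "A", "2" = "A", "3" = "B"))
  nm <- network_matrix(fc, atlas)
  expect_equal(nm["A", "A"], 0.5)               # the single within pair
  expect_equal(nm["A", "B"], (0.2 + 0.4) / 2)   # mean over cross pairs
  expect_true(is.na(nm["B", "B"]))              # single-ROI network
  expect_equal(nm, t(nm))
  # constant z matrix: every defined entry equals the constant
  zc <- matrix(0.3, 3, 3)
  nc <- network_matrix(fc_from_z(zc), atlas_stub(c("1" = "A", "2" = "A", "3" = "A")))
  expect_equal(unname(nc[1, 1]), 0.3)
  # unassigned ROI is an error
  expect_error(network_matrix(fc, atlas_stub(c("1" = "A", "2" = "A"))),
               "assignment")
})

test_that("network matrix is invariant to ROI order and bounded by its pairs", {
  set.seed(14)
  cfg <- sim_config(grid_shape = c(16, 16, 16), roi_count = 6,
                    network_sizes = c(PVN = 2, HVN = 2, VSN = 2),
                    n_volumes = 80)
  atlas <- generate_atlas(cfg)
  ts <- generate_roi_timeseries(cfg, default_target_z("control"), 3)
  fc <- roi_fc(ts)
  nm <- network_matrix(fc, atlas)
  # permuting ROIs inside a network leaves the matrix unchanged
  perm <- c(2L, 1L, 4L, 3L, 6L, 5L)
  fc_p <- structure(list(r = fc$r[perm, perm], z = fc$z[perm, perm],
                         roi_ids = fc$roi_ids[perm]), class = "roi_fc")
  expect_equal(network_matrix(fc_p, atlas), nm)
  # each entry lies between min and max of its constituent pairwise z
  net <- atlas$assignment[as.character(fc$roi_ids)]
  for (a in c("PVN", "HVN", "VSN")) for (b in c("PVN", "HVN", "VSN")) {
    rows <- which(net == a); cols <- which(net == b)
    zz <- fc$z[rows, cols]
    zz <- zz[!is.na(zz)]
    expect_gte(nm[a, b], min(zz) - 1e-12)
    expect_lte(nm[a, b], max(zz) + 1e-12)
  }
})

test_that("group comparison tests all six pairs with per-family FDR", {
  set.seed(2)
  mk <- function(shift) {
    m <- matrix(rnorm(9, sd = 0.05), 3, 3)
    m <- (m + t(m)) / 2
    m[1, 2] <- m[2, 1] <- m[1, 2] + shift
    dimnames(m) <- list(c("PVN", "HVN", "VSN"), c("PVN", "HVN", "VSN"))
    m
  }
  pat <- lapply(1:10, function(i) mk(-0.8))
  ctl <- lapply(1:10, function(i) mk(0))
  cmp <- compare_groups(pat, ctl)
  expect_equal(nrow(cmp$table), 6)
  expect_equal(sort(unique(cmp$table$type)), c("inter", "intra"))
  hp <- cmp$table[cmp$table$pair == "HVN-PVN", ]
  expect_true(hp$significant)
  expect_lt(hp$patient_mean, hp$control_mean)
  # difference matrix is patients minus controls, entrywise
  expect_equal(cmp$difference, cmp$mean_patient - cmp$mean_control)
  # swapping groups negates every t statistic
  rev_cmp <- compare_groups(ctl, pat)
  expect_equal(rev_cmp$table$t, -cmp$table$t, tolerance = 1e-12)
  # inconsistent ordering across subjects is refused
  bad <- pat
  dimnames(bad[[3]]) <- list(c("HVN", "PVN", "VSN"), c("HVN", "PVN", "VSN"))
  expect_error(compare_groups(bad, ctl), "ordering")
})

test_that("clinical correlation recovers exact linear relations", {
  set.seed(6)
  fc <- rnorm(15)
  cc <- correlate_clinical(fc, 2 * fc + 1)
  expect_equal(cc$r, 1)
  expect_equal(cc$slope, 2, tolerance = 1e-12)
  expect_equal(cc$intercept, 1, tolerance = 1e-12)
  expect_true(cc$significant)
  neg <- correlate_clinical(fc, -(2 * fc + 1))
  expect_equal(neg$r, -1)
  expect_equal(neg$slope, -2, tolerance = 1e-12)
  expect_error(correlate_clinical(fc, rep(1, 15)), "constant")
  # NA covariates are dropped pairwise
  cov <- 2 * fc + 1
  cov[c(2, 5)] <- NA
  expect_equal(correlate_clinical(fc, cov)$n, 13)
})
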