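one_voxel_maps <- function(values) lapply(values, function(v) array(v, c(1, 1, 1)))

test_that("voxel-wise t map matches the pooled-variance formula", {
  # hand oracle: a = {1,2,3}, b = {4,5,6}: sp2 = 1, t = -3/sqrt(2/3)
  tt <- voxelwise_ttest(one_voxel_maps(1:3), one_voxel_maps(4:6))
  expect_equal(tt$data[1, 1, 1], -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tt$data[1, 1, 1], -3.674, tolerance = 1e-3)
  # antisymmetry and the null case
  rev_t <- voxelwise_ttest(one_voxel_maps(4:6), one_voxel_maps(1:3))
  expect_equal(rev_t$data, -tt$data)
  same <- voxelwise_ttest(one_voxel_maps(c(2, 2, 2)), one_voxel_maps(c(2, 2, 2)))
  expect_equal(same$data[1, 1, 1], 0)   # zero pooled variance -> 0, not NaN
  expect_error(voxelwise_ttest(one_voxel_maps(1:3),
                               list(array(0, c(2, 1, 1)), array(0, c(2, 1, 1)))),
               "shape")
})

test_that("voxel-wise t agrees with stats::t.test across random voxels", {
  set.seed(12)
  a <- lapply(1:5, function(i) array(rnorm(27), c(3, 3, 3)))
  b <- lapply(1:6, function(i) array(rnorm(27), c(3, 3, 3)))
  tt <- voxelwise_ttest(a, b)
  for (v in c(1, 14, 27)) {
    av <- vapply(a, function(m) m[v], 0)
    bv <- vapply(b, function(m) m[v], 0)
    expect_equal(tt$data[v], unname(t.test(av, bv, var.equal = TRUE)$statistic),
                 tolerance = 1e-10)
  }
})

test_that("TFCE reproduces the hand-computed single-peak example", {
  arr <- array(0, c(3, 1, 1))
  arr[2, 1, 1] <- 2
  # h=1: 1^0.5*1^2*1; h=2: 1^0.5*2^2*1 -> 5 at the peak, 0 elsewhere
  enh <- tfce_enhance(arr, tfce_params(dh = 1))
  expect_equal(enh[2, 1, 1], 5)
  expect_equal(enh[c(1, 3), 1, 1], c(0, 0))
  expect_equal(tfce_enhance(array(0, c(4, 4, 4)), tfce_params()),
               array(0, c(4, 4, 4)))
})

test_that("TFCE matches the brute-force oracle exactly on integer maps", {
  set.seed(31)
  for (conn in c(6, 26)) {
    for (i in 1:8) {
      arr <- array(sample(0:3, 5^3, replace = TRUE, prob = c(.55, .2, .15, .1)),
                   c(5, 5, 5))
      expect_equal(tfce_enhance(arr, tfce_params(dh = 1, connectivity = conn)),
                   oracle_tfce(arr, dh = 1, connectivity = conn),
                   tolerance = 1e-9)
    }
  }
})

test_that("TFCE handles signs separately and respects monotonicity and scaling", {
  set.seed(5)
  arr <- array(rnorm(6^3), c(6, 6, 6))
  enh <- tfce_enhance(arr, tfce_params())
  expect_true(all(sign(enh) == sign(arr) | enh == 0))
  neg <- tfce_enhance(-arr, tfce_params())
  expect_equal(neg, -enh, tolerance = 1e-12)
  # monotonicity: raising one voxel's statistic never lowers any TFCE value
  arr2 <- abs(arr)
  bumped <- arr2
  bumped[3, 3, 3] <- bumped[3, 3, 3] + 1
  p <- tfce_params(dh = 0.05)
  expect_true(all(tfce_enhance(bumped, p) >= tfce_enhance(arr2, p) - 1e-12))
  # scaling: c > 1 strictly increases TFCE at suprathreshold voxels
  e1 <- tfce_enhance(arr2, p)
  e2 <- tfce_enhance(2 * arr2, p)
  supra <- arr2 > 0.05
  expect_true(all(e2[supra] > e1[supra]))
})

test_that("TFCE converges as the threshold step is refined", {
  set.seed(8)
  arr <- smooth_gaussian(array(rnorm(10^3), c(10, 10, 10)), 8, 4)
  arr <- abs(arr) / max(abs(arr))    # non-negative, maximum exactly 1
  coarse <- tfce_enhance(arr, tfce_params(dh = 0.01))
  fine <- tfce_enhance(arr, tfce_params(dh = 0.001))
  expect_equal(max(coarse), max(fine), tolerance = 0.02)
  expect_lt(sqrt(sum((coarse - fine)^2) / sum(fine^2)), 0.02)
  # and halving dh halves the number of integration terms
  expect_equal(tfce_enhance(array(c(0, 2, 0), c(3, 1, 1)),
                            tfce_params(dh = 2))[2, 1, 1],
               sqrt(1) * 2^2 * 2)
})

test_that("permutation p-values respect the floor and the exhaustive limit", {
  set.seed(21)
  a <- lapply(1:4, function(i) array(rnorm(8, 1), c(2, 2, 2)))
  b <- lapply(1:4, function(i) array(rnorm(8), c(2, 2, 2)))
  mc <- permutation_fwe(a, b, n_perm = 400, seed = 9)
  expect_true(all(mc$data >= 1 / 401))
  expect_true(all(mc$data <= 1))
  # exhaustive enumeration of all choose(8,4)=70 assignments is the limit
  ex <- permutation_fwe(a, b, exact = TRUE)
  expect_equal(ex$n_perm, 70)
  expect_equal(as.numeric(mc$data), as.numeric(ex$data), tolerance = 0.08)
  # identical seeds reproduce identical maps
  mc2 <- permutation_fwe(a, b, n_perm = 400, seed = 9)
  expect_identical(mc$data, mc2$data)
})

test_that("an injected gray-matter deficit is detected where it was placed", {
  cfg <- sim_config(grid_shape = c(12, 12, 12), roi_count = 3,
                    network_sizes = c(1, 1, 1), n_per_group = 20,
                    gm_effect_d = 2, gm_noise_sd = 0.1, seed = 42)
  atlas <- generate_atlas(cfg)
  gms <- generate_gm_maps(atlas, cfg)
  pm <- permutation_fwe(gms$control, gms$patient, n_perm = 300, seed = 1)
  sig <- which(as.numeric(pm$data) < 0.05)
  truth <- which(atlas$labels == 1)
  jaccard <- length(intersect(sig, truth)) / length(union(sig, truth))
  expect_gte(jaccard, 0.5)
  cl <- report_clusters(pm, alpha = 0.05, label_atlas = atlas)
  expect_gte(nrow(cl), 1)
  expect_match(cl$label[1], "ROI 1")
})

test_that("cluster reporting respects connectivity, ordering and the affine", {
  p <- array(1, c(6, 6, 6))
  p[2, 2, 2] <- 1e-4                      # isolated voxel
  p[c(4, 5), 4, 4] <- c(2e-4, 5e-5)       # face-adjacent pair
  aff <- diag(c(4, 4, 4, 1)); aff[1:3, 4] <- c(-10, -10, -10)
  cl <- report_clusters(p, alpha = 0.001, connectivity = 6, affine = aff)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$cluster_size_voxels, c(2, 1))  # size-descending
  expect_equal(cl$peak_p[1], 5e-5)
  expect_equal(cl$x_mm[2], (2 - 1) * 4 - 10)     # world coordinates
  # diagonal-only contact splits under 6-connectivity, merges under 26
  q <- array(1, c(5, 5, 5))
  q[2, 2, 2] <- 1e-4
  q[3, 3, 3] <- 1e-4
  expect_equal(nrow(report_clusters(q, 0.001, connectivity = 6)), 2)
  expect_equal(nrow(report_clusters(q, 0.001, connectivity = 26)), 1)
  # nothing significant: empty table, not an error
  expect_equal(nrow(report_clusters(array(1, c(3, 3, 3)), 0.01)), 0)
})
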