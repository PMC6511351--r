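test_that("atlas places the configured ROIs disjointly, inside the grid", {
  cfg <- sim_config()
  atlas <- generate_atlas(cfg)
  lab <- atlas$labels
  expect_setequal(unique(as.integer(lab)), 0:19)
  expect_true(all(table(lab[lab > 0]) == 27))  # disjoint 3x3x3 blocks
  d <- dim(lab)
  expect_true(all(lab[c(1, d[1]), , ] == 0))
  expect_true(all(lab[, c(1, d[2]), ] == 0))
  expect_true(all(lab[, , c(1, d[3])] == 0))
  expect_equal(as.integer(table(atlas$assignment)[c("PVN", "HVN", "VSN")]),
               c(2L, 4L, 13L))
  expect_identical(atlas$labels, generate_atlas(cfg)$labels)
})

test_that("atlas handles the degenerate single-ROI case and refuses tiny grids", {
  cfg1 <- sim_config(roi_count = 1, network_sizes = c(PVN = 1, HVN = 0, VSN = 0),
                     grid_shape = c(8, 8, 8))
  a1 <- generate_atlas(cfg1)
  expect_equal(sort(unique(as.integer(a1$labels))), c(0, 1))
  expect_equal(a1$assignment, c("1" = "PVN"))
  expect_error(generate_atlas(sim_config(grid_shape = c(6, 6, 6))),
               "too small")
})

test_that("BOLD ROI signals recover the target correlation structure", {
  # sampling oracle: long noise-free run, empirical r within 0.03
  cfg <- sim_config(n_volumes = 10000, grid_shape = c(12, 12, 12),
                    roi_count = 5, network_sizes = c(1, 2, 2),
                    noise_sd = 0, drift_amplitude = 0)
  atlas <- generate_atlas(cfg)
  z <- default_target_z("control")
  run <- generate_bold(atlas, z, cfg, 7)
  emp <- cor(t(extract_roi_timeseries(run, atlas)$matrix))
  target <- tanh(z)[cbind(rep(rep(1:3, c(1, 2, 2)), 5),
                          rep(rep(1:3, c(1, 2, 2)), each = 5))]
  target <- matrix(target, 5, 5)
  diag(target) <- 1
  expect_lt(max(abs(emp - target)), 0.03)
})

test_that("zero cross-network targets give cross-network r centered on 0", {
  z0 <- matrix(0, 3, 3)
  diag(z0) <- 0.5
  cfg <- sim_config(n_volumes = 8000, grid_shape = c(12, 12, 12),
                    roi_count = 4, network_sizes = c(2, 1, 1),
                    noise_sd = 0, drift_amplitude = 0)
  atlas <- generate_atlas(cfg)
  ts <- extract_roi_timeseries(generate_bold(atlas, z0, cfg, 11), atlas)
  emp <- cor(t(ts$matrix))
  expect_lt(max(abs(emp[1:2, 3:4])), 0.04)   # cross-network ~ 0
  expect_lt(max(abs(emp[3, 4])), 0.04)
})

test_that("BOLD generation is deterministic and background is pure noise", {
  cfg <- tiny_config(noise_sd = 0.3)
  atlas <- generate_atlas(cfg)
  z <- default_target_z("patient")
  r1 <- generate_bold(atlas, z, cfg, 3)
  r2 <- generate_bold(atlas, z, cfg, 3)
  expect_identical(r1$data, r2$data)
  expect_false(identical(r1$data, generate_bold(atlas, z, cfg, 4)$data))
  # noise-free background voxels are exactly zero
  cfg0 <- tiny_config(noise_sd = 0)
  r0 <- generate_bold(generate_atlas(cfg0), z, cfg0, 3)
  bg <- which(generate_atlas(cfg0)$labels == 0)
  m <- matrix(r0$data, prod(dim(r0$data)[1:3]))
  expect_true(all(m[bg, ] == 0))
})

test_that("non-positive-semi-definite targets are repaired with a warning", {
  z <- matrix(atanh(0.9), 3, 3)
  z[2, 3] <- z[3, 2] <- atanh(-0.9)
  diag(z) <- 0
  cfg <- tiny_config()
  expect_warning(
    generate_roi_timeseries(cfg, z, 1),
    "not positive semi-definite")
})

test_that("the ROI-series shortcut matches the voxel path statistically", {
  cfg <- sim_config(grid_shape = c(12, 12, 12), roi_count = 3,
                    network_sizes = c(1, 1, 1), n_volumes = 4000,
                    noise_sd = 0.5, drift_amplitude = 0)
  atlas <- generate_atlas(cfg)
  z <- default_target_z("control")
  r_vox <- cor(t(extract_roi_timeseries(
    generate_bold(atlas, z, cfg, 21), atlas)$matrix))
  r_short <- cor(t(generate_roi_timeseries(cfg, z, 21)$matrix))
  expect_lt(max(abs(r_vox - r_short)), 0.06)
})

test_that("gray-matter effect injection shifts the patient mean by d x sd", {
  cfg <- sim_config(grid_shape = c(12, 12, 12), roi_count = 3,
                    network_sizes = c(1, 1, 1), n_per_group = 200,
                    gm_effect_d = 2, gm_noise_sd = 0.1)
  atlas <- generate_atlas(cfg)
  gms <- generate_gm_maps(atlas, cfg)
  mp <- Reduce(`+`, lapply(gms$patient, `[[`, "data")) / 200
  mc <- Reduce(`+`, lapply(gms$control, `[[`, "data")) / 200
  mask <- atlas$labels == 1
  expect_equal(mean((mp - mc)[mask]), -2 * 0.1, tolerance = 0.05)
  expect_lt(abs(mean((mp - mc)[!mask])), 0.005)
})

test_that("null gray-matter cohorts are exchangeable and generation deterministic", {
  cfg <- tiny_config(gm_effect_d = 0)
  atlas <- generate_atlas(cfg)
  g1 <- generate_gm_maps(atlas, cfg)
  g2 <- generate_gm_maps(atlas, cfg)
  expect_identical(g1$patient[[1]]$data, g2$patient[[1]]$data)
  tt <- voxelwise_ttest(g1$patient, g1$control)
  # no systematic group difference: ~1% of voxels beyond the 1% critical t
  expect_lt(mean(abs(tt$data) > qt(0.995, df = 6)), 0.03)
  expect_error(
    generate_gm_maps(atlas, tiny_config(
      gm_effect_d = 2, gm_effect_mask = matrix(numeric(0), 0, 3))),
    "empty")
})

test_that("motion traces respect the spike probability and are deterministic", {
  cfg0 <- tiny_config(motion_spike_prob = 0, n_volumes = 240)
  tr0 <- generate_motion_trace(cfg0, 5)
  expect_equal(dim(tr0), c(240L, 6L))
  expect_lt(max(abs(as.matrix(tr0))), 2)
  expect_false(attr(tr0, "exclude"))
  cfg1 <- tiny_config(motion_spike_prob = 1)
  tr1 <- generate_motion_trace(cfg1, 5)
  expect_true(attr(tr1, "exclude"))
  expect_gt(max(abs(as.matrix(tr1))), 2)
  expect_identical(generate_motion_trace(cfg1, 5), tr1)
})

test_that("clinical tables reproduce the reference moments", {
  cfg <- sim_config(n_per_group = 2000)
  cl <- generate_clinical_table(cfg)
  pat <- cl[cl$group == "patient", ]
  ctl <- cl[cl$group == "control", ]
  expect_equal(mean(pat$ammonia), 51.60, tolerance = 2 / 51.60)
  expect_true(all(pat$ammonia > 0))
  expect_equal(mean(pat$age), 51.65, tolerance = 0.02)
  expect_equal(mean(ctl$age), 51.00, tolerance = 0.02)
  expect_true(all(is.na(ctl$ammonia)))
  expect_true(all(is.na(ctl$albumin)))
  expect_equal(mean(pat$sex == "M"), 11 / 20, tolerance = 0.1)
  expect_identical(generate_clinical_table(cfg), cl)
})
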