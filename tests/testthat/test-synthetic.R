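test_that("phantom shape parameters enforce their invariants", {
  expect_error(lv_shape_params(base_radius_mm = 20, wall_thickness_mm = 20),
               "wall_thickness")
  expect_error(lv_shape_params(truncation_fraction = 1.2), "truncation")
  expect_error(lv_shape_params(bulge_amplitude_mm = -1), "bulge")

  # endocardial volume strictly increases with base radius
  vols <- vapply(c(28, 31, 34), function(r)
    enclosed_volume(endocardial_surface(
      generate_lv_mesh(lv_shape_params(base_radius_mm = r), 10))),
    numeric(1))
  expect_true(all(diff(vols) > 0))
})

test_that("generated wall mesh is closed, labelled, and deterministic", {
  m <- fx_wall_mesh()
  expect_true(is_closed_mesh(m))
  expect_setequal(unique(m$vertex_labels), c("endo", "epi", "base"))
  expect_gt(enclosed_volume(m), 0)
  m2 <- generate_lv_mesh(lv_shape_params(), resolution = 12)
  expect_identical(m2$vertices, m$vertices)
  expect_error(generate_lv_mesh(lv_shape_params(), resolution = 4), ">= 8")
})

test_that("endocardial volume matches the 1-D quadrature oracle", {
  sh <- lv_shape_params(base_radius_mm = 33, long_axis_mm = 80,
                        wall_thickness_mm = 8, truncation_fraction = 0.7,
                        septal_flattening_frac = 0)
  m <- generate_lv_mesh(sh, 24)
  v <- enclosed_volume(endocardial_surface(m))
  # oracle: numerical integration of cross-sectional area over the long axis
  ce <- 40 - 8
  re <- 33 - 8
  zb <- 40 * (2 * 0.7 - 1)
  vq <- stats::integrate(function(z) pi * re^2 * (1 - z^2 / ce^2),
                         -ce, zb)$value
  expect_lt(abs(v - vq) / vq, 0.05)
})

test_that("motion model hits the EF target and closes the cycle", {
  frames <- fx_frames()
  tr <- attr(frames, "volume_trace")
  expect_equal(which.max(tr), 1)           # ED at frame 1 (phase 0)
  ef <- 1 - min(tr) / max(tr)
  expect_lt(abs(ef - 0.6), 0.02)

  # periodicity: phase 1 reproduces phase 0 exactly
  mo <- lv_motion_params(n_frames = 6, ef_target = 0.6)
  expect_equal(phase_contraction(mo, 0), phase_contraction(mo, 1))
  expect_equal(phase_contraction(mo, 0), 0)

  # zero amplitudes: every frame equals the input mesh
  still <- deform_mesh_sequence(fx_wall_mesh(),
                                lv_motion_params(n_frames = 3,
                                                 radial_amplitude = 0,
                                                 longitudinal_shortening = 0,
                                                 twist_deg = 0))
  for (f in still) expect_identical(f$vertices, fx_wall_mesh()$vertices)

  # radial contraction monotonically shrinks the cavity
  radial <- deform_mesh_sequence(fx_wall_mesh(),
                                 lv_motion_params(n_frames = 4,
                                                  ef_target = 0.3,
                                                  longitudinal_shortening = 0,
                                                  twist_deg = 0))
  rtr <- attr(radial, "volume_trace")
  expect_lt(min(rtr), max(rtr))

  # unreachable EF raises with a diagnostic
  expect_error(deform_mesh_sequence(fx_wall_mesh(),
                                    lv_motion_params(n_frames = 3,
                                                     ef_target = 0.9,
                                                     radial_amplitude = 0.1,
                                                     longitudinal_shortening
                                                     = 0.05)),
               "unreachable")
})

test_that("voxelization produces consistent label maps and intensities", {
  vox0 <- voxelize_subject(fx_frames()[1], 4, 0, seed = 3)
  img <- vox0$images[[1]]
  expect_length(unique(as.vector(img$voxels)), 3)

  lab <- vox0$labels[[1]]
  vv <- prod(lab$spacing_mm)
  blood <- sum(lab$voxels == 1) * vv
  myo <- sum(lab$voxels == 2) * vv
  m <- fx_frames()[[1]]
  v_endo <- enclosed_volume(endocardial_surface(m))
  v_wall <- enclosed_volume(m)
  # one-voxel-shell tolerance on a coarse grid
  expect_lt(abs(blood - v_endo) / v_endo, 0.10)
  expect_lt(abs(myo - v_wall) / v_wall, 0.10)

  # same seed, same volumes (noise included)
  a <- voxelize_subject(fx_frames()[1], 4, 5, seed = 17)
  b <- voxelize_subject(fx_frames()[1], 4, 5, seed = 17)
  expect_identical(a$images[[1]]$voxels, b$images[[1]]$voxels)
  expect_error(voxelize_subject(fx_frames()[1], -1, 0, 1), "positive")
})

test_that("cine stack geometry follows the slice-spacing contract", {
  st <- fx_cine()
  n_frames <- length(fx_frames())
  n_slices <- length(st$slices) / n_frames
  vol <- fx_vox()$images[[1]]
  d <- dim(vol$voxels)
  extent <- (d[3] - 1) * vol$spacing_mm[3]
  expect_equal(n_slices, ceiling(extent / 8))
  expect_error(make_cine_stack(fx_vox()$images, 8, n_slices = 2),
               "do not cover")
  expect_error(make_cine_stack(fx_vox()$images, 8,
                               plane_normal = c(1, 0, 0)), "long axis")

  # slice spacing equal to voxel size reproduces axial planes
  st1 <- make_cine_stack(fx_vox()$images[1], vol$spacing_mm[3])
  s <- st1$slices[[3]]
  k <- s$slice_index
  expect_equal(s$pixels,
               vol$voxels[, , k + 1],
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("cohort generation is deterministic with calibrated EDVs", {
  spec <- fx_small_spec()
  co <- generate_cohort(spec, voxelize = FALSE)
  expect_length(co$subjects, 4)
  expect_identical(vapply(co$subjects, function(s) s$group, character(1)),
                   c("control", "control", "AS", "AS"))
  co2 <- generate_cohort(spec, voxelize = FALSE)
  expect_identical(co$subjects[[3]]$meshes[[2]]$vertices,
                   co2$subjects[[3]]$meshes[[2]]$vertices)

  # default calibration: EDVs inside the clinical 64-151 mL range
  edv <- vapply(co$subjects, function(s) s$edv_ml, numeric(1))
  expect_true(all(edv >= 64 & edv <= 151))

  # zero group offsets give identically distributed group motion
  spec0 <- synthetic_cohort_spec(n_subjects_per_group = 2,
                                 group_motion_offsets = list(g1 = list(),
                                                             g2 = list()),
                                 seed = 3)
  co0 <- generate_cohort(spec0, voxelize = FALSE)
  hyp <- lapply(co0$subjects, function(s) s$motion$regional_hypokinesia)
  expect_true(all(lengths(hyp) == 0))
})

test_that("a cohort bundle writes a complete on-disk layout", {
  dir <- withr::local_tempdir()
  spec <- synthetic_cohort_spec(n_subjects_per_group = 1,
                                grid_spacing_mm = 6, noise_sd = 3,
                                mesh_resolution = 10,
                                base_motion = lv_motion_params(n_frames = 3),
                                seed = 4)
  co <- generate_cohort(spec)
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "cohort.yaml")))
  sd1 <- file.path(dir, co$subjects[[1]]$id)
  expect_true(file.exists(file.path(sd1, "wh.nii.gz")))
  expect_true(file.exists(file.path(sd1, "wh_seg.nii.gz")))
  expect_true(file.exists(file.path(sd1, "cine", "manifest.json")))
  expect_true(file.exists(file.path(sd1, "gt_frame01.vtk")))
  truth <- yaml::read_yaml(file.path(sd1, "truth.yaml"))
  expect_equal(truth$edv_ml, co$subjects[[1]]$edv_ml, tolerance = 1e-6)
})
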