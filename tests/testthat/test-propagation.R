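test_that("frame assembly reproduces the source volume it was cut from", {
  vox <- fx_vox()
  st <- fx_cine()
  vol <- vox$images[[1]]

  # reassembly at the slice spacing reproduces the slice planes exactly
  av8 <- assemble_frame(st$slices, 0L)
  xyz <- voxel_to_world(av8, cbind(5, 5, 0:(dim(av8$voxels)[3] - 1)))
  slices0 <- Filter(function(s) s$frame_index == 0L, st$slices)
  expect_equal(length(slices0), dim(av8$voxels)[3])
  expect_equal(av8$voxels[6, 6, 1], slices0[[1]]$pixels[6, 6])

  # reassembly at fine spacing: error bounded by a brute-force 1-D linear
  # interpolation oracle along the normal
  av <- assemble_frame(st$slices, 0L, out_spacing_mm = vol$spacing_mm[3])
  ssd_self <- ssd_score(av, av)
  expect_equal(ssd_self, 0)
  n <- dim(av$voxels)
  probe_ij <- cbind(c(8, 10, 12), c(10, 8, 12))
  zs <- seq(0, n[3] - 1)
  pos <- vapply(slices0, function(s) sum(s$position_mm * c(0, 0, 1)),
                numeric(1))
  for (r in seq_len(nrow(probe_ij))) {
    i <- probe_ij[r, 1]
    j <- probe_ij[r, 2]
    w <- voxel_to_world(av, cbind(i, j, zs))
    got <- av$voxels[i + 1, j + 1, ]
    px <- vapply(slices0, function(s) s$pixels[i + 1, j + 1], numeric(1))
    oracle <- stats::approx(pos, px, xout = w[, 3], rule = 2)$y
    expect_lt(max(abs(got - oracle)), 1e-8)
  }

  # shuffled slice order gives an identical volume
  set.seed(8)
  av2 <- assemble_frame(sample(st$slices), 0L,
                        out_spacing_mm = vol$spacing_mm[3])
  expect_identical(av2$voxels, av$voxels)

  expect_error(assemble_frame(st$slices[1], 0L), ">= 2 slices")
})

test_that("SSD scoring matches the brute-force double loop", {
  set.seed(10)
  a <- image_volume(array(runif(8^3), c(8, 8, 8)))
  b <- image_volume(array(runif(8^3), c(8, 8, 8)))
  # same grid: resampling is the identity, so plain sum of squares
  brute <- 0
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    brute <- brute + (a$voxels[i, j, k] - b$voxels[i, j, k])^2
  expect_equal(ssd_score(a, b), brute, tolerance = 1e-10)
  expect_equal(ssd_score(a, a), 0)

  # constant volumes differing by 1 -> overlap voxel count
  c1 <- image_volume(array(1, c(6, 6, 6)))
  c2 <- image_volume(array(2, c(6, 6, 6)))
  expect_equal(ssd_score(c1, c2), 216)

  far <- image_volume(array(1, c(4, 4, 4)), origin_mm = c(100, 100, 100))
  expect_error(ssd_score(far, c1), "overlap")
})

test_that("frame classification follows the strict half-maximum rule", {
  cl <- classify_frames(c(0, 10, 4))
  expect_equal(attr(cl, "threshold"), 5)
  expect_identical(cl$label,
                   c("highly_similar", "poorly_similar", "highly_similar"))

  # all equal scores sit exactly at the threshold -> all poorly similar
  cl2 <- classify_frames(c(3, 3, 3))
  expect_true(all(cl2$label == "poorly_similar"))

  # a score exactly at the threshold is poorly similar (strict inequality)
  cl3 <- classify_frames(c(5, 10, 2))
  expect_identical(cl3$label[1], "poorly_similar")
  expect_error(classify_frames(numeric(0)), "at least one")
})

test_that("demons registration is monotone and recovers a translation", {
  set.seed(4)
  # smooth random texture so the displacement is observable everywhere
  # (an isotropically smooth blob leaves the tangential component of the
  # field unconstrained -- the aperture problem)
  n <- 24
  raw <- array(rnorm(n^3), c(n, n, n))
  sm <- lvssa:::cpp_gauss_smooth3(as.double(raw), c(n, n, n), rep(2, 3))
  sm <- array(100 * sm / sd(sm), c(n, n, n))
  fixed <- image_volume(sm[1:(n - 2), , ], spacing_mm = rep(1.5, 3))
  moving <- image_volume(sm[3:n, , ], spacing_mm = rep(1.5, 3))
  params <- registration_params(pyramid_levels = 2,
                                iterations_per_level = 100,
                                update_smoothing_sigma_mm = 3,
                                field_smoothing_sigma_mm = 1.5,
                                convergence_tol = 1e-7)

  # identical inputs: near-zero field
  f0 <- register_nonrigid(fixed, fixed, params)
  expect_lt(max(abs(f0$field)), 0.1 * 1.5)

  # moving(x) = fixed(x + 2 voxels): truth is -3 mm along x
  fld <- register_nonrigid(moving, fixed, params)
  expect_lte(attr(fld, "ssd_after"), attr(fld, "ssd_before"))
  ux <- mean(fld$field[5:18, 5:20, 5:20, 1])
  expect_lt(abs(ux - (-3)) / 3, 0.2)

  # determinism
  fld2 <- register_nonrigid(moving, fixed, params)
  expect_identical(fld$field, fld2$field)
})

test_that("warping follows interpolation contracts and inverts", {
  vox <- fx_vox()
  vol <- vox$images[[1]]
  lab <- vox$labels[[1]]
  zero <- lvssa:::displacement_field(array(0, c(dim(vol$voxels), 3)), vol)
  expect_equal(warp_volume(vol, zero)$voxels, vol$voxels, tolerance = 1e-12)
  expect_identical(warp_labels(lab, zero)$voxels, lab$voxels)

  # nearest-neighbour label warp never invents labels
  params <- registration_params(pyramid_levels = 2,
                                iterations_per_level = 15,
                                update_smoothing_sigma_mm = 4,
                                field_smoothing_sigma_mm = 4)
  fld <- register_nonrigid(vox$images[[1]], vox$images[[4]], params)
  wl <- warp_labels(lab, fld)
  expect_true(all(unique(as.vector(wl$voxels)) %in%
                    unique(as.vector(lab$voxels))))

  # numerical inverse: sub-voxel round trip for a smooth field
  inv <- invert_field(fld)
  m <- fx_frames()[[1]]
  pts <- m$vertices[seq(1, nrow(m$vertices), by = 23), , drop = FALSE]
  d1 <- sample_field(fld, pts)
  rt <- pts + d1 + sample_field(inv, pts + d1)
  err <- sqrt(rowSums((rt - pts)^2))
  expect_lt(mean(err), 0.5 * mean(vol$spacing_mm))
})

test_that("mesh extraction matches analytic volumes and contracts", {
  # rasterized sphere r = 10 mm at 1 mm spacing
  g <- seq(-13, 13, by = 1)
  arr <- array(0L, c(27, 27, 27))
  for (k in seq_along(g))
    arr[, , k] <- outer(g, g, function(x, y)
      as.integer(x^2 + y^2 + g[k]^2 < 100))
  lab <- label_map(arr, c(background = 0L, sphere = 1L),
                   origin_mm = c(-13, -13, -13))
  mesh <- extract_mesh(lab, "sphere", smoothing_iterations = 10)
  expect_true(is_closed_mesh(mesh))
  expect_lt(abs(enclosed_volume(mesh) - 4188.79) / 4188.79, 0.03)

  # no smoothing: vertices on the half-integer voxel lattice
  raw <- extract_mesh(lab, "sphere", smoothing_iterations = 0)
  frac <- raw$vertices - floor(raw$vertices)
  expect_true(all(abs(frac) < 1e-9 | abs(frac - 0.5) < 1e-9))

  empty <- label_map(array(0L, c(5, 5, 5)),
                     c(background = 0L, sphere = 1L))
  expect_error(extract_mesh(empty, "sphere"), "empty")
})

test_that("motion propagation follows the direct/chained rule", {
  vox <- fx_vox()
  params <- registration_params(pyramid_levels = 2,
                                iterations_per_level = 15,
                                update_smoothing_sigma_mm = 4,
                                field_smoothing_sigma_mm = 4)
  prop <- propagate_motion(vox$images[[1]], vox$images, params)
  expect_length(prop$frames, length(vox$images))
  expect_length(prop$fields, length(vox$images))

  # the strongly contracted ES frame must engage the chain rule
  expect_true(any(prop$scores$label == "poorly_similar"))
  # the WH frame itself scores lowest and is classified highly similar
  expect_equal(which.min(prop$scores$ssd), 1)

  # scores are reproducible bit-exactly
  prop2 <- propagate_motion(vox$images[[1]], vox$images, params)
  expect_identical(prop$scores$ssd, prop2$scores$ssd)

  # label propagation recovers the ground-truth blood pool
  labs <- propagate_labels_atlas(vox$labels[[1]], prop$fields)
  dice <- function(a, b, v) 2 * sum(a == v & b == v) /
    (sum(a == v) + sum(b == v))
  d_es <- dice(labs[[4]]$voxels, vox$labels[[4]]$voxels, 1L)
  expect_gt(d_es, 0.8)

  # segmented volume trace correlates with ground truth
  vv <- prod(vox$labels[[1]]$spacing_mm)
  seg_trace <- vapply(labs, function(l) sum(l$voxels == 1L) * vv, numeric(1))
  gt_trace <- attr(fx_frames(), "volume_trace")
  expect_gt(cor(seg_trace, gt_trace), 0.9)
})

test_that("propagating identical frames returns the whole-heart volume", {
  vox <- fx_vox()
  wh <- vox$images[[1]]
  params <- registration_params(pyramid_levels = 2,
                                iterations_per_level = 10,
                                update_smoothing_sigma_mm = 4,
                                field_smoothing_sigma_mm = 4)
  prop <- propagate_motion(wh, list(wh, wh), params)
  zero_img <- image_volume(array(0, dim(wh$voxels)), wh$origin_mm,
                           wh$spacing_mm, wh$direction)
  base <- ssd_score(wh, zero_img)
  for (f in prop$frames) expect_lt(ssd_score(wh, f), 1e-3 * base)
})
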