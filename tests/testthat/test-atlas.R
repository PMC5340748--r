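test_that("Gaussian kernel matches closed forms and is PSD", {
  expect_equal(gaussian_kernel(matrix(0, 1, 3), matrix(0, 1, 3), 5),
               matrix(1, 1, 1))
  # |x - y| = lambda -> exp(-1)
  expect_equal(gaussian_kernel(matrix(0, 1, 3), matrix(c(7, 0, 0), 1, 3), 7),
               matrix(exp(-1), 1, 1))
  set.seed(12)
  x <- matrix(rnorm(18, 0, 10), 6, 3)
  k <- gaussian_kernel(x, x, 8)
  expect_equal(k, t(k))
  expect_gte(min(eigen(k, symmetric = TRUE)$values), -1e-10)
  expect_error(gaussian_kernel(x, x, 0), "positive")
})

test_that("flow is exact identity at zero momenta and obeys closed forms", {
  m <- fx_wall_mesh()
  cp <- control_point_grid(m, 27)
  k <- kernel_params(13, 23, 10)
  out <- flow(m, cp, matrix(0, nrow(cp), 3), k)
  expect_identical(out$vertices, m$vertices)
  expect_identical(out$vertex_labels, m$vertex_labels)

  # single step, control point on a vertex: displacement = K(0) * p = p
  v <- matrix(c(0, 0, 0, 100, 100, 100), 2, 3, byrow = TRUE)
  tiny <- surface_mesh(rbind(v, c(0, 0, 100)), rbind(c(1, 2, 3)))
  k1 <- kernel_params(13, 10, 1)
  p <- c(1.5, -2, 0.5)
  out1 <- flow(tiny, matrix(0, 1, 3), matrix(p, 1, 3), k1)
  expect_equal(out1$vertices[1, ], tiny$vertices[1, ] + p, tolerance = 1e-12)

  # step-halving convergence: doubling steps changes vertices by < 1% of
  # the maximum displacement
  set.seed(13)
  beta <- matrix(rnorm(nrow(cp) * 3, 0, 2), nrow(cp), 3)
  f10 <- flow(m, cp, beta, kernel_params(13, 23, 10))
  f20 <- flow(m, cp, beta, kernel_params(13, 23, 20))
  maxdisp <- max(sqrt(rowSums((f20$vertices - m$vertices)^2)))
  expect_lt(max(sqrt(rowSums((f20$vertices - f10$vertices)^2))),
            0.01 * maxdisp)
})

test_that("currents distance is a symmetric pseudo-metric with an
           enumeration oracle", {
  a <- fx_blob_mesh()
  b <- surface_mesh(a$vertices + 2, a$triangles)
  expect_equal(currents_distance(a, a, 10), 0, tolerance = 1e-10)
  expect_identical(currents_distance(a, b, 10), currents_distance(b, a, 10))
  expect_gt(currents_distance(a, b, 10), 0)

  # two single-triangle meshes: hand-computed 2x2 double sum
  t1 <- surface_mesh(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)),
                     rbind(c(1, 2, 3)))
  t2 <- surface_mesh(rbind(c(1, 0, 1), c(3, 0, 1), c(1, 2, 1)),
                     rbind(c(1, 2, 3)))
  lam <- 3
  g1 <- triangle_geometry(t1)
  g2 <- triangle_geometry(t2)
  kf <- function(p, q) exp(-sum((p - q)^2) / lam^2)
  oracle <- kf(g1$centers[1, ], g1$centers[1, ]) * sum(g1$normals^2) +
    kf(g2$centers[1, ], g2$centers[1, ]) * sum(g2$normals^2) -
    2 * kf(g1$centers[1, ], g2$centers[1, ]) *
      sum(g1$normals[1, ] * g2$normals[1, ])
  expect_equal(currents_distance(t1, t2, lam), oracle, tolerance = 1e-12)

  # degenerate triangles are skipped with a warning
  dg <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                     rbind(c(1, 2, 3)))
  expect_warning(currents_distance(dg, t1, lam), "zero-area")
})

test_that("momenta deformation energy is rotation invariant", {
  set.seed(14)
  cp <- matrix(rnorm(24, 0, 15), 8, 3)
  beta <- matrix(rnorm(24), 8, 3)
  e0 <- momenta_energy(cp, beta, 12)
  r <- rotation_z(37)
  e1 <- momenta_energy(cp %*% t(r), beta %*% t(r), 12)
  expect_lt(abs(e1 - e0) / e0, 1e-8)
  expect_equal(momenta_energy(cp, 0 * beta, 12), 0)
})

test_that("registration recovers a translation and decreases energy
           monotonically", {
  dec <- decimate_mesh(fx_bulged_mesh(), 7)
  tgt <- surface_mesh(dec$vertices +
                        matrix(c(3, 0, 0), nrow(dec$vertices), 3,
                               byrow = TRUE), dec$triangles)
  cp <- control_point_grid(dec, 27)
  k <- kernel_params(13, 40, 8)
  b <- estimate_registration(dec, tgt, cp, k,
                             list(max_iter = 50, gamma = 0.1))
  moved <- flow(dec, cp, b, k)
  expect_lt(surface_distance(moved, tgt)$mean, 0.5)
  trace <- attr(b, "energy")
  expect_true(all(diff(trace) < 0))

  # target == template: momenta stay near zero
  b0 <- estimate_registration(dec, dec, cp, k, list(max_iter = 10))
  expect_lt(max(abs(b0)), 1e-6)

  # determinism
  b2 <- estimate_registration(dec, tgt, cp, k,
                              list(max_iter = 50, gamma = 0.1))
  expect_identical(unclass(b)[seq_along(b)], unclass(b2)[seq_along(b2)])
})

test_that("atlas estimation satisfies its limit cases", {
  # identical input shapes: template equals them, momenta ~ 0
  dec <- decimate_mesh(fx_wall_mesh(), 8)
  at <- estimate_atlas(list(dec, dec, dec), kernel_params(13, 23, 6), 27,
                       list(max_outer = 2, reg_iters = 5, max_iter = 5))
  expect_lt(surface_distance(at$template, dec)$mean, 1e-3)
  expect_lt(max(abs(at$momenta[[1]])), 1e-4)
  tr <- attr(at, "energy_trace")
  # non-increasing up to the cancellation noise of the currents sums
  expect_true(all(diff(tr) <= 1e-6 + 1e-8 * abs(tr[1])))

  # two spheres r = 9, 11: template volume brackets the inputs
  s9 <- icosphere(9, 2)
  s11 <- icosphere(11, 2)
  at2 <- estimate_atlas(list(s9, s11), kernel_params(8, 15, 6), 27,
                        list(max_outer = 4, reg_iters = 12, max_iter = 12,
                             gamma = 0.1))
  vt <- signed_volume_for_tests(at2$template)
  expect_gt(vt, enclosed_volume(s9))
  expect_lt(vt, enclosed_volume(s11))
})

test_that("known momenta deformations are re-estimated within 1 mm", {
  set.seed(15)
  dec <- decimate_mesh(fx_bulged_mesh(), 8)
  cp <- control_point_grid(dec, 27)
  k <- kernel_params(13, 30, 8)
  beta_true <- matrix(rnorm(nrow(cp) * 3, 0, 1.5), nrow(cp), 3)
  target <- flow(dec, cp, beta_true, k)
  b <- estimate_registration(dec, target, cp, k,
                             list(max_iter = 60, gamma = 0.05))
  rec <- flow(dec, cp, b, k)
  expect_lt(surface_distance(rec, target)$mean, 1)
})

test_that("kernel-width tuning returns the argmin of its own table", {
  frames <- lapply(fx_frames()[c(1, 3, 5)], decimate_mesh, cell_mm = 9)
  tuned <- tune_parameters(frames, lambda_w_grid = c(10, 16),
                           lambda_v_grid = c(25),
                           n_control_points = 27,
                           opt_params = list(max_outer = 2, reg_iters = 6,
                                             max_iter = 6, gamma = 0.1))
  expect_equal(nrow(tuned$table), 2)
  best <- tuned$table[which.min(tuned$table$mean_surface_distance_mm), ]
  expect_equal(tuned$kernel$lambda_w_mm, best$lambda_w_mm)
  expect_equal(tuned$kernel$lambda_v_mm, best$lambda_v_mm)

  single <- tune_parameters(frames, 13, 23, 27,
                            list(max_outer = 1, reg_iters = 4, max_iter = 4,
                                 gamma = 0.1))
  expect_equal(nrow(single$table), 1)
  expect_equal(single$kernel$lambda_w_mm, 13)
})
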