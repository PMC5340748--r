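test_that("momenta stacking fixes the flattening convention", {
  b1 <- matrix(1:12, 4, 3)
  b2 <- matrix(13:24, 4, 3)
  x <- stack_momenta(list(b1, b2))
  expect_equal(dim(x), c(2, 12))
  # point-major, xyz within point
  expect_equal(x[1, 1:6], c(1, 5, 9, 2, 6, 10))
  expect_equal(lvssa:::unstack_momenta(x[2, ]), b2)
  expect_error(stack_momenta(list(b1, matrix(0, 3, 3))), "disagree")
})

test_that("PCA matches a dense eigen oracle and reconstructs exactly", {
  set.seed(17)
  x <- matrix(rnorm(6 * 12), 6, 12)
  p <- fit_pca(x)
  oracle <- eigen(stats::cov(x), symmetric = TRUE)$values[1:5]
  expect_equal(p$eigenvalues, oracle, tolerance = 1e-10)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_equal(crossprod(p$modes), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(p$eigenvalues), sum(diag(stats::cov(x))),
               tolerance = 1e-8)
  expect_equal(sum(p$variance_fraction), 1)

  # completeness: projection onto all modes reconstructs each row
  for (i in seq_len(nrow(x))) {
    cf <- project(x[i, ], p)
    rec <- p$mean + as.vector(p$modes %*% cf)
    expect_equal(rec, x[i, ], tolerance = 1e-8)
  }

  # two samples: exactly one mode carrying all the variance
  p2 <- fit_pca(x[1:2, ])
  expect_length(p2$eigenvalues, 1)
  expect_equal(p2$variance_fraction, 1)

  # zero-variance input
  expect_warning(p0 <- fit_pca(rbind(x[1, ], x[1, ])), "zero-variance")
  expect_equal(p0$eigenvalues, 0)
})

test_that("projection is the centered dot product and shift equivariant", {
  set.seed(18)
  x <- matrix(rnorm(5 * 9), 5, 9)
  p <- fit_pca(x)
  expect_equal(unname(project(p$mean, p)), rep(0, length(p$eigenvalues)))
  cf <- project(x[3, ], p)
  brute <- vapply(seq_len(ncol(p$modes)), function(j)
    sum(p$modes[, j] * (x[3, ] - p$mean)), numeric(1))
  expect_equal(unname(cf), brute, tolerance = 1e-12)

  # adding a constant row vector to all momenta changes no coefficient
  shift <- matrix(rnorm(9), nrow(x), ncol(x), byrow = TRUE)
  ps <- fit_pca(x + shift)
  for (i in seq_len(nrow(x))) {
    a <- abs(project(x[i, ], p))
    b <- abs(project((x + shift)[i, ], ps))
    expect_equal(a, b, tolerance = 1e-6)
  }
})

test_that("mode meshes bend the template and map magnitudes correctly", {
  dec <- decimate_mesh(fx_wall_mesh(), 8)
  cp <- control_point_grid(dec, 27)
  k <- kernel_params(13, 25, 6)
  set.seed(19)
  momenta <- lapply(1:4, function(i)
    matrix(rnorm(nrow(cp) * 3, 0, 1), nrow(cp), 3))
  pca <- fit_pca(stack_momenta(momenta))
  plus <- mode_mesh(dec, cp, pca, 1, 2, k)
  minus <- mode_mesh(dec, cp, pca, 1, -2, k)
  expect_gt(surface_distance(plus, minus)$mean, 0)
  zero <- mode_mesh(dec, cp, pca, 1, 0, k)
  mean_mesh <- flow(dec, cp, lvssa:::unstack_momenta(pca$mean), k)
  expect_equal(zero$vertices, mean_mesh$vertices)
  expect_error(mode_mesh(dec, cp, pca, 1, 4, k), "sigma")

  mag <- deformation_magnitude_map(dec, plus, minus)
  brute <- sqrt(rowSums((plus$vertices - minus$vertices)^2))
  expect_equal(mag, brute)
  expect_equal(which.max(mag), which.max(brute))
  expect_equal(deformation_magnitude_map(dec, plus, plus),
               rep(0, nrow(dec$vertices)))
  bad <- surface_mesh(plus$vertices[-1, , drop = FALSE],
                      rbind(c(1, 2, 3)))
  expect_error(deformation_magnitude_map(dec, plus, bad), "topology")
})

test_that("shape analysis of identical subjects yields null shape vectors", {
  dec <- decimate_mesh(fx_wall_mesh(), 8)
  cp <- control_point_grid(dec, 8)
  k <- kernel_params(13, 25, 5)
  model <- anatomical_model(dec, cp, list(matrix(0, nrow(cp), 3)), k)
  models <- list(model, model, model)
  expect_warning(
    res <- run_shape_analysis(models, k, n_modes = 1, n_control_points = 27,
                              opt_params = list(max_outer = 1,
                                                reg_iters = 3, max_iter = 3),
                              phase = "ED"),
    "zero-variance")
  expect_lt(max(abs(res$shape_vectors$mode_1)), 1e-6)
  expect_lte(sum(res$pca$variance_fraction), 1 + 1e-12)
})
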