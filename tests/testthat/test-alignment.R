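test_that("endocardial/epicardial extraction produces nested closed
           surfaces", {
  m <- fx_wall_mesh()
  endo <- endocardial_surface(m)
  epi <- epicardial_surface(m)
  expect_true(is_closed_mesh(endo))
  expect_true(is_closed_mesh(epi))
  expect_lt(enclosed_volume(endo), enclosed_volume(epi))
  # extraction keeps every endo-labelled vertex (plus cap centroids)
  expect_gte(nrow(endo$vertices), sum(m$vertex_labels == "endo"))
  expect_error(endocardial_surface(surface_mesh(m$vertices, m$triangles)),
               "labels")
})

test_that("volume scaling hits the reference volume exactly", {
  mesh_to_model <- function(mesh) {
    cp <- control_point_grid(mesh, 8)
    anatomical_model(mesh, cp, list(matrix(0.5, nrow(cp), 3)),
                     kernel_params(13, 23, 5))
  }
  model <- mesh_to_model(fx_wall_mesh())
  v0 <- enclosed_volume(endocardial_surface(model$template))

  same <- scale_model(model, v0)
  expect_equal(attr(same, "transform")$scale, 1, tolerance = 1e-12)

  half <- scale_model(model, v0 / 8)
  expect_equal(attr(half, "transform")$scale, 0.5, tolerance = 1e-12)
  expect_lt(abs(enclosed_volume(endocardial_surface(half$template)) -
                  v0 / 8) / (v0 / 8), 1e-6)
  # momenta and kernel widths scale along
  expect_equal(half$momenta[[1]][1, 1], 0.25, tolerance = 1e-12)
  expect_equal(half$kernel$lambda_v_mm, 23 * 0.5, tolerance = 1e-12)
})

test_that("rigid ICP recovers a 10-degree rotation within 0.5 degrees", {
  m <- fx_blob_mesh()
  r <- rotation_z(10)
  m2 <- surface_mesh(m$vertices %*% t(r) +
                       matrix(c(3, -2, 1), nrow(m$vertices), 3, byrow = TRUE),
                     m$triangles)
  tf <- icp_rigid(m, m2)
  ang <- acos(pmin(1, (sum(diag(tf$rotation %*% t(r))) - 1) / 2)) * 180 / pi
  expect_lt(ang, 0.5)
  expect_true(all(diff(attr(tf, "rms")) < 1e-9))

  # fixed == moving: identity within tolerance
  tfi <- icp_rigid(m, m)
  expect_lt(max(abs(tfi$rotation - diag(3))), 1e-6)
  expect_lt(max(abs(tfi$translation_mm)), 1e-6)
})

test_that("generalized Procrustes aligns rigidly displaced copies", {
  m <- fx_blob_mesh()
  m2 <- surface_mesh(m$vertices %*% t(rotation_z(8)) +
                       matrix(c(5, 1, -2), nrow(m$vertices), 3,
                              byrow = TRUE), m$triangles)
  m3 <- surface_mesh(m$vertices %*% t(rotation_z(-6)) +
                       matrix(c(-3, 2, 4), nrow(m$vertices), 3,
                              byrow = TRUE), m$triangles)
  gpa <- generalized_procrustes(list(m, m2, m3))
  expect_lt(surface_distance(gpa$aligned[[1]], gpa$aligned[[2]])$mean, 0.1)
  expect_lt(surface_distance(gpa$aligned[[1]], gpa$aligned[[3]])$mean, 0.1)
  # identical pre-aligned meshes: all transforms identity
  gpa0 <- generalized_procrustes(list(m, m, m))
  for (tf in gpa0$transforms) {
    expect_lt(max(abs(tf$rotation - diag(3))), 1e-6)
    expect_lt(max(abs(tf$translation_mm)), 1e-6)
  }
})

test_that("model transforms commute with the flow", {
  dec <- decimate_mesh(fx_bulged_mesh(), 8)
  cp <- control_point_grid(dec, 27)
  set.seed(16)
  beta <- matrix(rnorm(nrow(cp) * 3, 0, 1.5), nrow(cp), 3)
  k <- kernel_params(13, 25, 6)
  model <- anatomical_model(dec, cp, list(beta), k)
  tf <- similarity_transform(rotation_z(25), c(4, -7, 2), 1.3)

  tmodel <- apply_transform_to_model(model, tf)
  # path 1: transform then flow (with the transformed model's kernel)
  p1 <- flow(tmodel$template, tmodel$control_points, tmodel$momenta[[1]],
             tmodel$kernel)
  # path 2: flow then transform
  p2 <- flow(model$template, model$control_points, model$momenta[[1]],
             model$kernel)
  p2v <- sweep(p2$vertices %*% t(tf$rotation) * tf$scale, 2,
               tf$translation_mm, `+`)
  expect_lt(max(abs(p1$vertices - p2v)), 1e-6)

  # identity transform returns an identical model
  ident <- apply_transform_to_model(model, similarity_transform())
  expect_equal(ident$template$vertices, model$template$vertices)
  expect_equal(ident$momenta, model$momenta)

  # rotation preserves the deformation energy
  rot <- apply_transform_to_model(model, similarity_transform(rotation_z(40)))
  e0 <- momenta_energy(model$control_points, beta, k$lambda_v_mm)
  e1 <- momenta_energy(rot$control_points, rot$momenta[[1]],
                       rot$kernel$lambda_v_mm)
  expect_lt(abs(e1 - e0) / e0, 1e-8)
})
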