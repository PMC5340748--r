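test_that("NIfTI volumes round-trip voxels and geometry", {
  dir <- withr::local_tempdir()
  vox <- fx_vox()
  img <- vox$images[[1]]
  p <- file.path(dir, "img.nii.gz")
  write_volume(img, p)
  back <- read_volume(p)
  expect_equal(back$voxels, img$voxels, tolerance = 1e-6)
  expect_lt(max(abs(back$origin_mm - img$origin_mm)), 1e-5)
  expect_lt(max(abs(back$spacing_mm - img$spacing_mm)), 1e-5)
  expect_lt(max(abs(back$direction - img$direction)), 1e-5)

  # label maps round-trip their histogram exactly
  lab <- vox$labels[[1]]
  pl <- file.path(dir, "lab.nii.gz")
  write_volume(lab, pl)
  lback <- read_label_map(pl, lab$label_dictionary)
  expect_identical(table(as.vector(lback$voxels)),
                   table(as.vector(lab$voxels)))

  # anisotropic spacing and rotated direction survive
  rot <- rotation_z(30)
  an <- image_volume(array(runif(60), c(3, 4, 5)), c(5, -3, 2),
                     c(1.1, 2.2, 3.3), rot)
  pa <- file.path(dir, "aniso.nii.gz")
  write_volume(an, pa)
  aback <- read_volume(pa)
  expect_lt(max(abs(aback$spacing_mm - an$spacing_mm)), 1e-5)
  expect_lt(max(abs(aback$direction - rot)), 1e-5)

  # 4D files are rejected
  p4 <- file.path(dir, "4d.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(3, 3, 3, 2))), p4)
  expect_error(read_volume(p4), "4D")
  expect_error(read_volume(file.path(dir, "missing.nii.gz")), "not found")
})

test_that("voxel/world mapping is consistent under IO round trip", {
  dir <- withr::local_tempdir()
  vol <- image_volume(array(0, c(6, 5, 4)), c(-10, 4, 7), c(1.4, 1.4, 2),
                      rotation_z(20))
  set.seed(9)
  ijk <- cbind(runif(20, 0, 5), runif(20, 0, 4), runif(20, 0, 3))
  p <- file.path(dir, "v.nii.gz")
  write_volume(vol, p)
  back <- read_volume(p)
  expect_lt(max(abs(voxel_to_world(vol, ijk) - voxel_to_world(back, ijk))),
            1e-4)
  expect_lt(max(abs(world_to_voxel(vol, voxel_to_world(vol, ijk)) - ijk)),
            1e-10)
})

test_that("mesh formats round-trip with labels and reject bad cells", {
  dir <- withr::local_tempdir()
  m <- fx_wall_mesh()
  pv <- file.path(dir, "m.vtk")
  write_mesh(m, pv)
  m2 <- read_mesh(pv)
  expect_identical(m2$triangles, m$triangles)
  expect_identical(m2$vertex_labels, m$vertex_labels)
  expect_identical(m2$vertices, m$vertices)  # 17 digits => exact

  pp <- file.path(dir, "m.ply")
  write_mesh(m2, pp)
  m3 <- read_mesh(pp)
  expect_identical(m3$triangles, m$triangles)
  expect_identical(m3$vertex_labels, m$vertex_labels)

  # STL read deduplicates shared vertices
  cube <- cube_mesh()
  ps <- file.path(dir, "c.stl")
  tg <- triangle_geometry(cube)
  con <- file(ps, "w")
  writeLines("solid cube", con)
  for (i in seq_len(nrow(cube$triangles))) {
    writeLines(sprintf("facet normal %g %g %g", tg$normals[i, 1],
                       tg$normals[i, 2], tg$normals[i, 3]), con)
    writeLines("outer loop", con)
    for (j in 1:3) {
      v <- cube$vertices[cube$triangles[i, j], ]
      writeLines(sprintf("vertex %.9g %.9g %.9g", v[1], v[2], v[3]), con)
    }
    writeLines(c("endloop", "endfacet"), con)
  }
  writeLines("endsolid cube", con)
  close(con)
  stl <- read_mesh(ps)
  expect_equal(nrow(stl$vertices), 8)
  expect_equal(nrow(stl$triangles), 12)
  expect_true(is_closed_mesh(stl))

  # corrupt inputs
  bad <- file.path(dir, "bad.vtk")
  writeLines(c("# vtk DataFile Version 3.0", "t", "ASCII",
               "DATASET POLYDATA", "POINTS 3 double", "0 0 0", "1 0 0",
               "0 1 0", "POLYGONS 1 5", "4 0 1 2 2"), bad)
  expect_error(read_mesh(bad), "non-triangular")
})

test_that("cine manifests load losslessly, sorted and validated", {
  dir <- withr::local_tempdir()
  st <- fx_cine()
  mp <- write_cine_stack(st, file.path(dir, "cine"))
  slices <- read_cine_manifest(mp)
  expect_length(slices, length(st$slices))

  # order invariance: shuffle manifest records
  rec <- jsonlite::read_json(mp, simplifyVector = FALSE)
  set.seed(5)
  jsonlite::write_json(sample(rec), mp, auto_unbox = TRUE, digits = NA)
  slices2 <- read_cine_manifest(mp)
  key <- function(ss) vapply(ss, function(s)
    paste(s$frame_index, s$slice_index), character(1))
  expect_identical(key(slices2), key(slices))
  expect_identical(slices2[[3]]$pixels, slices[[3]]$pixels)

  # trigger times: equal across slices of a frame, increasing across frames
  tt <- vapply(slices, function(s) s$trigger_time_ms, numeric(1))
  fi <- vapply(slices, function(s) s$frame_index, integer(1))
  expect_true(all(tapply(tt, fi, function(v) length(unique(v)) == 1)))
  expect_true(all(diff(tapply(tt, fi, unique)) > 0))

  # missing field rejected
  rec[[1]]$trigger_time_ms <- NULL
  jsonlite::write_json(rec, mp, auto_unbox = TRUE, digits = NA)
  expect_error(read_cine_manifest(mp), "trigger_time")
})

test_that("CSV tables round-trip doubles exactly and reject ragged rows", {
  dir <- withr::local_tempdir()
  set.seed(7)
  df <- data.frame(id = c("a", "b"), x = c(pi, exp(1)) * 1e-7,
                   n = c(1L, 2L))
  p <- file.path(dir, "t.csv")
  write_table(df, p)
  back <- read_table(p)
  expect_identical(back$x, df$x)
  expect_identical(back$id, df$id)
  expect_error(write_table(list(list(a = 1, b = 2), list(a = 1)), p),
               "ragged")
  expect_error(read_table(file.path(dir, "none.csv")), "not found")
})
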