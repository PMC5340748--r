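# Shared fixtures, built once per test run and memoized. All geometry is
# generated in code; sizes are kept small (coarse voxels, few frames) so the
# whole suite stays desk-scale.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_wall_mesh <- function() fixture("wall_mesh", function()
  generate_lv_mesh(lv_shape_params(), resolution = 12))

fx_bulged_mesh <- function() fixture("bulged_mesh", function()
  generate_lv_mesh(lv_shape_params(bulge_amplitude_mm = 8), resolution = 12))

# irregular asymmetric mesh (marching tetrahedra of a rasterized bulged LV)
fx_blob_mesh <- function() fixture("blob_mesh", function() {
  vox <- voxelize_subject(list(fx_bulged_mesh()), 4, 0, seed = 1)
  decimate_mesh(extract_mesh(vox$labels[[1]], "myocardium", 4), 5)
})

fx_frames <- function() fixture("frames", function()
  deform_mesh_sequence(fx_wall_mesh(),
                       lv_motion_params(n_frames = 6, ef_target = 0.6)))

fx_vox <- function() fixture("vox", function()
  voxelize_subject(fx_frames(), 4, 3, seed = 3))

fx_cine <- function() fixture("cine", function()
  make_cine_stack(fx_vox()$images, 8))

# unit cube surface mesh (12 triangles, outward oriented)
cube_mesh <- function() {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  tris <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0 face (normal -z)
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  surface_mesh(v, tris)
}

# icosphere by subdividing an icosahedron, radius r
icosphere <- function(r = 10, subdivisions = 3) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    edge_id <- new.env()
    mid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- edge_id[[key]]
      if (!is.null(id)) return(id)
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      edge_id[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- NULL
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- mid(a, b); bc <- mid(b, c); ca <- mid(c, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    f <- nf
    v <- v / sqrt(rowSums(v^2))
  }
  v <- v / sqrt(rowSums(v^2)) * r
  surface_mesh(v, f)
}

# small deterministic random mesh (open): perturbed grid patch
random_patch <- function(n = 4, seed = 1) {
  set.seed(seed)
  g <- expand.grid(x = seq_len(n), y = seq_len(n))
  v <- cbind(g$x, g$y, rnorm(nrow(g), 0, 0.3))
  f <- NULL
  idx <- function(i, j) (j - 1) * n + i
  for (j in seq_len(n - 1))
    for (i in seq_len(n - 1))
      f <- rbind(f, c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
                 c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  surface_mesh(v, f)
}

signed_volume_for_tests <- function(m) lvssa:::signed_mesh_volume(m)

rotation_z <- function(deg) {
  th <- deg * pi / 180
  rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
}

# tiny test cohort at very coarse resolution (pipeline smoke scale)
fx_small_spec <- function(seed = 11)
  synthetic_cohort_spec(n_subjects_per_group = 2, seed = seed,
                        grid_spacing_mm = 4, noise_sd = 4,
                        mesh_resolution = 12,
                        base_motion = lv_motion_params(n_frames = 10))
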