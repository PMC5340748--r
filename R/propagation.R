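# Motion propagation: assemble per-phase 3D volumes from the cine stack,
# score them against the whole-heart (WH) volume with SSD, classify frames
# against the half-maximum threshold, and generate synthetic WH frames by
# demons non-rigid registration -- directly from WH for highly similar
# frames, chained from the previous synthetic frame otherwise.

#' Assemble a 3D volume from the cine slices of one cardiac phase
#'
#' Stacks all slices sharing `frame_index` along their common normal and
#' fills the through-plane gaps by linear interpolation along the normal; the
#' in-plane grid is preserved.
#'
#' @param slices list of [cine_slice()] (any order).
#' @param frame_index phase to assemble.
#' @param out_spacing_mm through-plane spacing of the output (defaults to the
#'   slice gap).
#' @return an [image_volume()].
#' @export
assemble_frame <- function(slices, frame_index, out_spacing_mm = NULL) {
  sl <- Filter(function(s) s$frame_index == frame_index, slices)
  if (length(sl) < 2) stopf("need >= 2 slices for frame %d", frame_index)
  nrm <- slice_normal(sl[[1]])
  for (s in sl) {
    if (acos(min(1, abs(sum(slice_normal(s) * nrm)))) > 2 * pi / 180)
      stopf("slices of frame %d are not parallel within 2 degrees",
            frame_index)
    if (max(abs(s$row_dir - sl[[1]]$row_dir)) > 1e-6 ||
        max(abs(s$col_dir - sl[[1]]$col_dir)) > 1e-6)
      stopf("slices of frame %d have inconsistent in-plane axes", frame_index)
  }
  proj <- vapply(sl, function(s) sum(s$position_mm * nrm), numeric(1))
  ord <- order(proj)
  sl <- sl[ord]
  proj <- proj[ord]
  gaps <- diff(proj)
  if (any(gaps <= 0)) stopf("duplicate slice positions in frame %d",
                            frame_index)
  if (is.null(out_spacing_mm)) out_spacing_mm <- mean(gaps)
  if (out_spacing_mm <= 0) stopf("out_spacing_mm must be positive")
  s1 <- sl[[1]]
  np <- dim(s1$pixels)
  nz <- max(2L, floor((proj[length(proj)] - proj[1]) / out_spacing_mm) + 1L)
  zpos <- proj[1] + (seq_len(nz) - 1) * out_spacing_mm
  vox <- array(0, c(np[1], np[2], nz))
  for (k in seq_len(nz)) {
    z <- zpos[k]
    i2 <- findInterval(z, proj, all.inside = TRUE)
    z0 <- proj[i2]
    z1 <- proj[i2 + 1]
    w <- if (z1 > z0) min(1, max(0, (z - z0) / (z1 - z0))) else 0
    vox[, , k] <- (1 - w) * sl[[i2]]$pixels + w * sl[[i2 + 1]]$pixels
  }
  image_volume(vox, s1$position_mm + (zpos[1] - proj[1]) * nrm,
               c(s1$pixel_spacing_mm, out_spacing_mm),
               cbind(s1$row_dir, s1$col_dir, nrm))
}

#' Sum-of-squared-differences similarity between two volumes
#'
#' The reference is resampled onto the frame grid with linear interpolation;
#' the score is the sum over overlap voxels of the squared intensity
#' difference (voxels outside the overlap are excluded).
#'
#' @param reference,frame [image_volume()] objects.
#' @return nonnegative SSD.
#' @export
ssd_score <- function(reference, frame) {
  xyz <- volume_grid_world(frame)
  r <- sample_volume(reference, xyz, "linear", fill = NA_real_)
  ok <- !is.na(r)
  if (!any(ok)) stopf("volumes do not overlap")
  sum((r[ok] - as.double(frame$voxels)[ok])^2)
}

#' Classify cine frames against the half-maximum SSD threshold
#'
#' The threshold is `0.5 * max(ssd)`; a frame is `highly_similar` when its
#' SSD is strictly below the threshold, `poorly_similar` otherwise (equality
#' included).
#'
#' @param scores numeric SSD vector, or data frame with columns
#'   `frame_index`, `ssd`.
#' @return data frame with `frame_index`, `ssd`, `label`, and the threshold
#'   as attribute `"threshold"`.
#' @export
classify_frames <- function(scores) {
  if (is.data.frame(scores)) {
    fi <- scores$frame_index
    ssd <- scores$ssd
  } else {
    ssd <- as.numeric(scores)
    fi <- seq_along(ssd) - 1L
  }
  if (length(ssd) < 1) stopf("need at least one score")
  if (any(ssd < 0)) stopf("SSD scores must be nonnegative")
  thr <- 0.5 * max(ssd)
  out <- data.frame(frame_index = fi, ssd = ssd,
                    label = ifelse(ssd < thr, "highly_similar",
                                   "poorly_similar"))
  attr(out, "threshold") <- thr
  out
}

#' Parameters of the demons registration engine
#'
#' @param pyramid_levels multi-resolution levels (coarse to fine).
#' @param iterations_per_level demons iterations per level.
#' @param update_smoothing_sigma_mm Gaussian sigma applied to each update
#'   (fluid-like regularization).
#' @param field_smoothing_sigma_mm Gaussian sigma applied to the accumulated
#'   field (diffusion-like regularization).
#' @param step_length update scaling.
#' @param convergence_tol relative SSD decrease below which a level stops.
#' @return object of class `registration_params`.
#' @export
registration_params <- function(pyramid_levels = 3, iterations_per_level = 30,
                                update_smoothing_sigma_mm = 2,
                                field_smoothing_sigma_mm = 2,
                                step_length = 1, convergence_tol = 1e-4) {
  vals <- c(pyramid_levels, iterations_per_level, update_smoothing_sigma_mm,
            field_smoothing_sigma_mm, step_length, convergence_tol)
  if (any(vals <= 0)) stopf("all registration parameters must be positive")
  structure(list(pyramid_levels = as.integer(pyramid_levels),
                 iterations_per_level = as.integer(iterations_per_level),
                 update_smoothing_sigma_mm = update_smoothing_sigma_mm,
                 field_smoothing_sigma_mm = field_smoothing_sigma_mm,
                 step_length = step_length,
                 convergence_tol = convergence_tol),
            class = "registration_params")
}

displacement_field <- function(field, grid) {
  structure(list(field = field, origin_mm = grid$origin_mm,
                 spacing_mm = grid$spacing_mm, direction = grid$direction),
            class = "displacement_field")
}

field_grid_volume <- function(field) {
  image_volume(array(0, dim(field$field)[1:3]), field$origin_mm,
               field$spacing_mm, field$direction)
}

downsample2 <- function(arr) {
  d <- dim(arr)
  nd <- pmax(1L, d %/% 2L)
  idx <- lapply(1:3, function(q) pmin(d[q], 2 * seq_len(nd[q]) - 1))
  a0 <- arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  idx2 <- lapply(1:3, function(q) pmin(d[q], 2 * seq_len(nd[q])))
  a1 <- arr[idx2[[1]], idx2[[2]], idx2[[3]], drop = FALSE]
  array((a0 + a1) / 2, nd)
}

upsample_field2 <- function(u, newdim) {
  # u: (nx,ny,nz,3) displacements in fine-level voxel units of the next level
  out <- array(0, c(newdim, 3))
  d <- dim(u)[1:3]
  pts <- as.matrix(expand.grid(i = (0:(newdim[1] - 1)) / 2,
                               j = (0:(newdim[2] - 1)) / 2,
                               k = (0:(newdim[3] - 1)) / 2))
  pts[, 1] <- pmin(pts[, 1], d[1] - 1)
  pts[, 2] <- pmin(pts[, 2], d[2] - 1)
  pts[, 3] <- pmin(pts[, 3], d[3] - 1)
  for (q in 1:3)
    out[, , , q] <- array(2 * cpp_trilinear(as.double(u[, , , q]), d, pts, 0),
                          newdim)
  out
}

demons_level <- function(fixed, moving, u, params, spacing_vox) {
  d <- dim(fixed)
  base <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                                k = 0:(d[3] - 1)))
  sig_u <- params$update_smoothing_sigma_mm / spacing_vox
  sig_f <- params$field_smoothing_sigma_mm / spacing_vox
  warp_m <- function(u) {
    pts <- base + cbind(as.double(u[, , , 1]), as.double(u[, , , 2]),
                        as.double(u[, , , 3]))
    array(cpp_trilinear(as.double(moving), d, pts, mean(moving)), d)
  }
  ssd_of <- function(u) sum((warp_m(u) - fixed)^2)
  cur_ssd <- ssd_of(u)
  scale <- params$step_length
  # intensity-scale normalization of the demons force (keeps the update
  # magnitude invariant under rescaling of the image intensities)
  knorm <- stats::var(as.vector(fixed))
  if (knorm < 1e-12) knorm <- 1
  best_u <- u
  best_ssd <- cur_ssd
  stall <- 0
  for (it in seq_len(params$iterations_per_level)) {
    mw <- warp_m(u)
    g <- cpp_gradient3(as.double(mw), d)
    diff <- mw - fixed
    den <- g$x^2 + g$y^2 + g$z^2 + diff^2 / knorm
    den[den < 1e-12] <- 1e-12
    f <- -diff / den
    upd <- array(0, c(d, 3))
    upd[, , , 1] <- array(cpp_gauss_smooth3(as.double(f * g$x), d, sig_u), d)
    upd[, , , 2] <- array(cpp_gauss_smooth3(as.double(f * g$y), d, sig_u), d)
    upd[, , , 3] <- array(cpp_gauss_smooth3(as.double(f * g$z), d, sig_u), d)
    # per-voxel cap at one voxel per iteration
    mag <- sqrt(upd[, , , 1]^2 + upd[, , , 2]^2 + upd[, , , 3]^2)
    fac <- array(1 / pmax(1, mag), d)
    for (q in 1:3) upd[, , , q] <- upd[, , , q] * fac
    u <- u + scale * upd
    for (q in 1:3)
      u[, , , q] <- array(cpp_gauss_smooth3(as.double(u[, , , q]), d,
                                            sig_f), d)
    cur_ssd <- ssd_of(u)
    if (cur_ssd < best_ssd * (1 - params$convergence_tol)) {
      best_ssd <- cur_ssd
      best_u <- u
      stall <- 0
    } else {
      if (cur_ssd < best_ssd) {
        best_ssd <- cur_ssd
        best_u <- u
      }
      stall <- stall + 1
      if (stall >= 8) break
    }
  }
  best_u
}

#' Demons non-rigid registration
#'
#' Diffusion-regularized demons with the SSD metric, multi-resolution coarse
#' to fine, monotone in SSD (an update is only accepted when it lowers the
#' SSD, so `SSD(warp(moving), fixed) <= SSD(moving, fixed)` always holds).
#' Deterministic given its inputs.
#'
#' @param moving,fixed [image_volume()] objects with overlapping fields of
#'   view; the moving volume is first resampled onto the fixed grid.
#' @param params a [registration_params()].
#' @param init_field optional `displacement_field` on the fixed grid used to
#'   initialize the finest level (e.g. the previous frame's field when
#'   registering a temporal sequence); the pyramid is skipped in that case.
#' @return a `displacement_field` on the fixed grid (mm displacements along
#'   world axes) with attributes `ssd_before`, `ssd_after` and
#'   `jacobian_range`.
#' @export
register_nonrigid <- function(moving, fixed, params = registration_params(),
                              init_field = NULL) {
  d <- dim(fixed$voxels)
  mov <- array(sample_volume(moving, volume_grid_world(fixed), "linear",
                             fill = NA_real_), d)
  if (!any(!is.na(mov))) stopf("volumes do not overlap")
  mov[is.na(mov)] <- mean(mov, na.rm = TRUE)
  fx <- as.double(fixed$voxels)
  dim(fx) <- d
  if (!is.null(init_field)) {
    # world-mm displacements -> fixed-grid voxel units
    minv <- solve(fixed$direction %*% diag(fixed$spacing_mm))
    u <- array(0, c(d, 3))
    for (r in 1:3) {
      acc <- array(0, d)
      for (q in 1:3) acc <- acc + minv[r, q] * init_field$field[, , , q]
      u[, , , r] <- acc
    }
    u <- demons_level(fx, mov, u, params, fixed$spacing_mm)
  } else {
    # pyramid
    fixes <- list(fx)
    movs <- list(mov)
    spacings <- list(fixed$spacing_mm)
    for (l in seq_len(params$pyramid_levels - 1)) {
      if (any(dim(fixes[[l]]) < 8)) break
      fixes[[l + 1]] <- downsample2(fixes[[l]])
      movs[[l + 1]] <- downsample2(movs[[l]])
      spacings[[l + 1]] <- spacings[[l]] * 2
    }
    nl <- length(fixes)
    u <- array(0, c(dim(fixes[[nl]]), 3))
    for (l in nl:1) {
      if (l < nl) u <- upsample_field2(u, dim(fixes[[l]]))
      u <- demons_level(fixes[[l]], movs[[l]], u, params, spacings[[l]])
    }
  }
  # convert voxel displacements (fixed grid axes) to world mm
  umm <- array(0, c(d, 3))
  for (q in 1:3) {
    acc <- array(0, d)
    for (r in 1:3)
      acc <- acc + fixed$direction[q, r] * fixed$spacing_mm[r] * u[, , , r]
    umm[, , , q] <- acc
  }
  out <- displacement_field(umm, fixed)
  ssd0 <- sum((mov - fx)^2)
  ssd1 <- demons_final_ssd(fx, mov, u)
  if (ssd1 > ssd0 + 1e-9 * ssd0) {
    if (!is.null(init_field))  # a bad initialization: redo from scratch
      return(register_nonrigid(moving, fixed, params))
    stopf("registration diverged: SSD %.6g -> %.6g", ssd0, ssd1)
  }
  attr(out, "ssd_before") <- ssd0
  attr(out, "ssd_after") <- ssd1
  attr(out, "jacobian_range") <- jacobian_dev_range(u)
  out
}

demons_final_ssd <- function(fx, mov, u) {
  d <- dim(fx)
  base <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                                k = 0:(d[3] - 1)))
  pts <- base + cbind(as.double(u[, , , 1]), as.double(u[, , , 2]),
                      as.double(u[, , , 3]))
  sum((array(cpp_trilinear(as.double(mov), d, pts, mean(mov)), d) - fx)^2)
}

jacobian_dev_range <- function(u) {
  d <- dim(u)[1:3]
  jm <- array(0, d)
  gx <- lapply(1:3, function(q) cpp_gradient3(as.double(u[, , , q]), d))
  det <- (1 + gx[[1]]$x) * ((1 + gx[[2]]$y) * (1 + gx[[3]]$z) -
                              gx[[2]]$z * gx[[3]]$y) -
    gx[[1]]$y * (gx[[2]]$x * (1 + gx[[3]]$z) - gx[[2]]$z * gx[[3]]$x) +
    gx[[1]]$z * (gx[[2]]$x * gx[[3]]$y - (1 + gx[[2]]$y) * gx[[3]]$x)
  range(det - 1)
}

#' Warp a volume or label map through a displacement field
#'
#' Output voxels live on the field grid; each grid point x samples the input
#' at `x + u(x)` -- linearly for intensities, nearest-neighbour for labels
#' (which therefore never creates labels absent from the input). Points
#' mapped outside the input return background (0).
#'
#' @param vol an [image_volume()].
#' @param field a `displacement_field` from [register_nonrigid()].
#' @return warped [image_volume()] / [label_map()].
#' @export
warp_volume <- function(vol, field) {
  grid <- field_grid_volume(field)
  xyz <- volume_grid_world(grid) + cbind(as.double(field$field[, , , 1]),
                                         as.double(field$field[, , , 2]),
                                         as.double(field$field[, , , 3]))
  image_volume(array(sample_volume(vol, xyz, "linear", fill = 0),
                     dim(grid$voxels)),
               grid$origin_mm, grid$spacing_mm, grid$direction)
}

#' @rdname warp_volume
#' @param labels a [label_map()].
#' @export
warp_labels <- function(labels, field) {
  grid <- field_grid_volume(field)
  xyz <- volume_grid_world(grid) + cbind(as.double(field$field[, , , 1]),
                                         as.double(field$field[, , , 2]),
                                         as.double(field$field[, , , 3]))
  out <- array(as.integer(sample_volume(labels, xyz, "nearest", fill = 0)),
               dim(grid$voxels))
  label_map(out, labels$label_dictionary, grid$origin_mm, grid$spacing_mm,
            grid$direction)
}

#' Numerically invert a displacement field
#'
#' Fixed-point iteration `v <- -u(x + v)`; the composition of `u` and the
#' inverse has sub-voxel round-trip error for smooth, moderate fields.
#'
#' @param field a `displacement_field`.
#' @param iterations fixed-point iterations.
#' @return a `displacement_field` on the same grid.
#' @export
invert_field <- function(field, iterations = 20) {
  grid <- field_grid_volume(field)
  d <- dim(grid$voxels)
  xyz <- volume_grid_world(grid)
  v <- array(0, c(d, 3))
  uq <- lapply(1:3, function(q) as.double(field$field[, , , q]))
  for (it in seq_len(iterations)) {
    pts <- xyz + cbind(as.double(v[, , , 1]), as.double(v[, , , 2]),
                       as.double(v[, , , 3]))
    vox <- world_to_voxel(grid, pts)
    for (q in 1:3)
      v[, , , q] <- -array(cpp_trilinear(uq[[q]], d, vox, 0), d)
  }
  displacement_field(v, grid)
}

#' Sample a displacement field at world points
#'
#' @param field a `displacement_field`.
#' @param xyz N x 3 world coordinates.
#' @return N x 3 displacements (mm).
#' @export
sample_field <- function(field, xyz) {
  grid <- field_grid_volume(field)
  vox <- world_to_voxel(grid, xyz)
  d <- dim(grid$voxels)
  cbind(cpp_trilinear(as.double(field$field[, , , 1]), d, vox, 0),
        cpp_trilinear(as.double(field$field[, , , 2]), d, vox, 0),
        cpp_trilinear(as.double(field$field[, , , 3]), d, vox, 0))
}

compose_fields <- function(outer, inner) {
  # (outer after inner)(x) = inner(x) + outer(x + inner(x))
  grid <- field_grid_volume(inner)
  xyz <- volume_grid_world(grid)
  d <- dim(grid$voxels)
  disp_in <- cbind(as.double(inner$field[, , , 1]),
                   as.double(inner$field[, , , 2]),
                   as.double(inner$field[, , , 3]))
  disp_out <- sample_field(outer, xyz + disp_in)
  total <- disp_in + disp_out
  displacement_field(array(total, c(d, 3)), grid)
}

#' Propagate whole-heart detail through the cardiac cycle
#'
#' Scores every assembled cine frame against the whole-heart volume, applies
#' the half-maximum threshold rule, and generates one synthetic WH frame per
#' cine frame: frames classified highly similar are registered directly from
#' the WH volume; poorly similar frames are registered from the previously
#' generated synthetic frame. Processing runs in cyclic temporal order
#' starting at the frame of minimum SSD (the phase closest to the
#' mid-diastolic WH acquisition). Returned fields are composed back to the
#' WH volume, so each one maps its frame grid into WH space and can carry
#' the WH segmentation to that frame.
#'
#' @param wh the whole-heart [image_volume()].
#' @param cine_frames list of assembled per-phase [image_volume()].
#' @param params a [registration_params()].
#' @return list with `frames` (synthetic WH volumes), `fields` (composite
#'   `displacement_field`s frame -> WH), `scores` (classification table).
#' @export
propagate_motion <- function(wh, cine_frames, params = registration_params()) {
  n <- length(cine_frames)
  if (n < 2) stopf("need at least 2 cine frames")
  ssd <- vapply(cine_frames, function(f) ssd_score(wh, f), numeric(1))
  scores <- classify_frames(ssd)
  start <- which.min(ssd)
  order_idx <- ((start - 1 + 0:(n - 1)) %% n) + 1
  frames <- vector("list", n)
  fields <- vector("list", n)
  prev_syn <- wh
  prev_field <- NULL
  for (t in order_idx) {
    if (scores$label[t] == "highly_similar" || is.null(prev_field)) {
      fld <- register_nonrigid(wh, cine_frames[[t]], params,
                               init_field = prev_field)
      frames[[t]] <- warp_volume(wh, fld)
      fields[[t]] <- fld
    } else {
      fld <- register_nonrigid(prev_syn, cine_frames[[t]], params)
      frames[[t]] <- warp_volume(prev_syn, fld)
      fields[[t]] <- compose_fields(prev_field, fld)
    }
    prev_syn <- frames[[t]]
    prev_field <- fields[[t]]
  }
  list(frames = frames, fields = fields, scores = scores)
}

#' Propagate the WH segmentation to every frame (single-atlas propagation)
#'
#' @param wh_labels [label_map()] on the WH grid.
#' @param fields composite fields from [propagate_motion()].
#' @return list of per-frame [label_map()].
#' @export
propagate_labels_atlas <- function(wh_labels, fields) {
  lapply(fields, function(f) warp_labels(wh_labels, f))
}

#' Extract a triangulated surface from a label map
#'
#' Marching-tetrahedra isosurface of the binary mask at 0.5, followed by
#' Laplacian smoothing with volume-drift correction (enclosed volume is
#' restored by a uniform rescale, keeping the drift below measurement
#' precision). The output is closed and outward oriented.
#'
#' @param labels a [label_map()].
#' @param label_name name in the label dictionary.
#' @param smoothing_iterations Laplacian sweeps (0 leaves marching-tetrahedra
#'   vertices on the half-integer voxel lattice).
#' @return a closed [surface_mesh()] in world coordinates.
#' @export
extract_mesh <- function(labels, label_name, smoothing_iterations = 10) {
  code <- labels$label_dictionary[[label_name]]
  if (is.null(code)) stopf("label '%s' not in dictionary", label_name)
  mask <- labels$voxels == code
  nvox <- sum(mask)
  if (nvox == 0) stopf("label '%s' is empty", label_name)
  if (nvox < 100)
    stopf("label '%s' has only %d voxels (>= 100 required)", label_name, nvox)
  d <- dim(mask) + 2L
  arr <- array(0, d)
  arr[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- mask
  mt <- cpp_march_tets(as.double(arr), d, 0.5)
  verts <- voxel_to_world(labels, mt$vertices - 1)
  mesh <- surface_mesh(verts, mt$triangles + 1L)
  if (!is_closed_mesh(mesh)) stopf("internal error: isosurface not closed")
  if (signed_mesh_volume(mesh) < 0)
    mesh$triangles <- mesh$triangles[, c(1, 3, 2)]
  smooth_mesh(mesh, smoothing_iterations)
}

#' Label wall-mesh vertices as endo/epi by adjacency to the blood pool
#'
#' For a myocardium surface extracted from a segmentation, classifies each
#' vertex by sampling the label map a small distance along the outward vertex
#' normal: blood on the outside of the wall surface means the vertex lies on
#' the endocardial sheet.
#'
#' @param mesh extracted myocardium [surface_mesh()].
#' @param labels the [label_map()] it came from.
#' @param blood_name,myo_name dictionary names.
#' @return the mesh with `vertex_labels` set to `"endo"`/`"epi"`.
#' @export
label_mesh_vertices <- function(mesh, labels, blood_name = "blood",
                                myo_name = "myocardium") {
  g <- triangle_geometry(mesh)
  # accumulate area-weighted triangle normals onto vertices
  vn <- matrix(0, n_vertices(mesh), 3)
  for (c in 1:3) {
    idx <- mesh$triangles[, c]
    for (q in 1:3)
      vn[, q] <- vn[, q] + as.vector(tapply(g$normals[, q], factor(
        idx, levels = seq_len(n_vertices(mesh))), sum, default = 0))
  }
  vn[is.na(vn)] <- 0
  nn <- sqrt(rowSums(vn^2))
  nn[nn == 0] <- 1
  vn <- vn / nn
  h <- mean(labels$spacing_mm)
  bl <- labels$label_dictionary[[blood_name]]
  lab <- rep("epi", n_vertices(mesh))
  for (mult in c(1, 2)) {
    s <- sample_volume(labels, mesh$vertices + mult * h * vn, "nearest",
                       fill = 0)
    lab[s == bl] <- "endo"
  }
  mesh$vertex_labels <- lab
  mesh
}

#' Warp a mesh from WH space into a frame's space
#'
#' Inverts the frame's composite field and moves the vertices with it, giving
#' per-frame meshes in exact vertexwise correspondence with the reference
#' mesh (the route the pipeline uses to build per-subject mesh sequences of
#' shared topology).
#'
#' @param mesh reference mesh in WH space.
#' @param field composite `displacement_field` (frame -> WH).
#' @return warped [surface_mesh()].
#' @export
propagate_mesh <- function(mesh, field) {
  inv <- invert_field(field)
  disp <- sample_field(inv, mesh$vertices)
  surface_mesh(mesh$vertices + disp, mesh$triangles, mesh$vertex_labels)
}
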