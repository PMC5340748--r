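#' Single cine slice
#'
#' One 2D short-axis image at one slice location and one cardiac phase, with
#' full plane geometry: world position of pixel (0,0), in-plane direction unit
#' vectors, pixel spacing and trigger time.
#'
#' @param pixels 2D numeric array.
#' @param position_mm world position of pixel (0,0).
#' @param row_dir,col_dir orthogonal in-plane unit vectors.
#' @param pixel_spacing_mm length-2 positive spacing (mm).
#' @param trigger_time_ms nonnegative trigger time (ms).
#' @param slice_index,frame_index integer indices.
#' @return object of class `cine_slice`.
#' @export
cine_slice <- function(pixels, position_mm, row_dir, col_dir,
                       pixel_spacing_mm, trigger_time_ms, slice_index,
                       frame_index) {
  if (length(dim(pixels)) != 2) stopf("pixels must be a 2D array")
  row_dir <- as.numeric(row_dir)
  col_dir <- as.numeric(col_dir)
  if (abs(sum(row_dir * col_dir)) > 1e-6)
    stopf("row_dir and col_dir must be orthogonal within 1e-6")
  if (abs(sqrt(sum(row_dir^2)) - 1) > 1e-6 ||
      abs(sqrt(sum(col_dir^2)) - 1) > 1e-6)
    stopf("row_dir and col_dir must be unit vectors")
  if (trigger_time_ms < 0) stopf("trigger_time_ms must be nonnegative")
  structure(list(pixels = pixels, position_mm = as.numeric(position_mm),
                 row_dir = row_dir, col_dir = col_dir,
                 pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                 trigger_time_ms = as.numeric(trigger_time_ms),
                 slice_index = as.integer(slice_index),
                 frame_index = as.integer(frame_index)),
            class = "cine_slice")
}

slice_normal <- function(slice) {
  r <- slice$row_dir
  c <- slice$col_dir
  c(r[2] * c[3] - r[3] * c[2], r[3] * c[1] - r[1] * c[3],
    r[1] * c[2] - r[2] * c[1])
}

#' Cut a short-axis cine stack out of a sequence of 3D frames
#'
#' Resamples each 3D frame on a stack of parallel planes orthogonal to
#' `plane_normal`, spaced `slice_spacing_mm` apart, covering the full extent
#' of the volume along the normal (number of slices =
#' `ceiling(extent / slice_spacing_mm)`). Trigger times are uniform over an RR
#' interval of `rr_ms` and equal across the slices of one frame.
#'
#' @param frames list of [image_volume()], one per cardiac phase.
#' @param slice_spacing_mm through-plane slice spacing (mm).
#' @param plane_normal stack normal; must align with the volume's third axis
#'   (the long-axis convention of the generator) within 20 degrees.
#' @param pixel_spacing_mm in-plane spacing; defaults to the first frame's
#'   in-plane spacing.
#' @param n_slices optionally force the slice count; raises if the requested
#'   count does not cover the base-to-apex extent.
#' @param rr_ms RR interval used for trigger times (ms).
#' @return list with `slices` (list of [cine_slice()]) and `manifest`
#'   (data frame, one row per slice file as written by [write_cine_stack()]).
#' @export
make_cine_stack <- function(frames, slice_spacing_mm = 8,
                            plane_normal = c(0, 0, 1),
                            pixel_spacing_mm = NULL, n_slices = NULL,
                            rr_ms = 1000) {
  if (slice_spacing_mm <= 0) stopf("slice_spacing_mm must be positive")
  vol <- frames[[1]]
  nrm <- unit_vector(as.numeric(plane_normal))
  axis3 <- vol$direction[, 3]
  if (sum(nrm * axis3) < 0) nrm <- -nrm
  if (acos(min(1, abs(sum(nrm * axis3)))) > 20 * pi / 180)
    stopf("plane_normal deviates more than 20 degrees from the long axis")
  d <- dim(vol$voxels)
  corners <- voxel_to_world(vol, as.matrix(expand.grid(c(0, d[1] - 1),
                                                       c(0, d[2] - 1),
                                                       c(0, d[3] - 1))))
  proj <- corners %*% nrm
  extent <- max(proj) - min(proj)
  needed <- ceiling(extent / slice_spacing_mm)
  if (is.null(n_slices)) n_slices <- needed
  if (n_slices < needed)
    stopf("%d slices at %.3g mm do not cover the %.3g mm base-to-apex extent",
          n_slices, slice_spacing_mm, extent)
  # in-plane frame: use the volume's first two axes projected off the normal
  row_dir <- unit_vector(vol$direction[, 1] - sum(vol$direction[, 1] * nrm) * nrm)
  col_dir <- unit_vector(vol$direction[, 2] - sum(vol$direction[, 2] * nrm) * nrm -
                         sum(vol$direction[, 2] * row_dir) * row_dir)
  ps <- pixel_spacing_mm %||% vol$spacing_mm[1:2]
  if (length(ps) == 1) ps <- c(ps, ps)
  er <- corners %*% row_dir
  ec <- corners %*% col_dir
  nr <- floor((max(er) - min(er)) / ps[1] + 1e-9) + 1
  nc <- floor((max(ec) - min(ec)) / ps[2] + 1e-9) + 1
  # pixel (0,0) anchored at the bounding-box corner so the slice lattice
  # coincides with the voxel lattice whenever the axes agree
  p00 <- as.vector(min(er)) * row_dir + as.vector(min(ec)) * col_dir
  rr_grid <- (seq_len(nr) - 1) * ps[1]
  cc_grid <- (seq_len(nc) - 1) * ps[2]
  grid_rc <- as.matrix(expand.grid(r = rr_grid, c = cc_grid))
  n_frames <- length(frames)
  slices <- list()
  for (t in seq_len(n_frames)) {
    tt <- (t - 1) * rr_ms / n_frames
    for (s in seq_len(n_slices)) {
      target_n <- min(proj) + (s - 1) * slice_spacing_mm
      pos <- p00 + (target_n - sum(p00 * nrm)) * nrm
      xyz <- sweep(grid_rc[, 1, drop = FALSE] %*% t(row_dir) +
                   grid_rc[, 2, drop = FALSE] %*% t(col_dir), 2, pos, `+`)
      px <- matrix(sample_volume(frames[[t]], xyz, "linear", fill = 0),
                   nrow = nr)
      slices[[length(slices) + 1]] <-
        cine_slice(px, pos, row_dir, col_dir, ps, tt, s - 1L, t - 1L)
    }
  }
  list(slices = slices, manifest = cine_manifest_df(slices))
}

cine_manifest_df <- function(slices, paths = NA_character_) {
  do.call(rbind, lapply(seq_along(slices), function(i) {
    s <- slices[[i]]
    data.frame(slice_id = s$slice_index, frame_id = s$frame_index,
               pos_x = s$position_mm[1], pos_y = s$position_mm[2],
               pos_z = s$position_mm[3],
               row_x = s$row_dir[1], row_y = s$row_dir[2],
               row_z = s$row_dir[3],
               col_x = s$col_dir[1], col_y = s$col_dir[2],
               col_z = s$col_dir[3],
               ps_r = s$pixel_spacing_mm[1], ps_c = s$pixel_spacing_mm[2],
               trigger_time_ms = s$trigger_time_ms,
               path = if (length(paths) == length(slices)) paths[i]
                      else NA_character_)
  }))
}

#' Write a cine stack to a directory with a JSON manifest
#'
#' Each slice becomes a small NIfTI file; the manifest records
#' `{slice_id, frame_id, position_mm, row_dir, col_dir, pixel_spacing_mm,
#' trigger_time_ms, path}` with paths relative to the manifest.
#'
#' @param stack result of [make_cine_stack()] (or a bare list of slices).
#' @param dir output directory (created if missing).
#' @return path to `manifest.json`, invisibly.
#' @export
write_cine_stack <- function(stack, dir) {
  slices <- if (!is.null(stack$slices)) stack$slices else stack
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(slices))
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    paths[i] <- sprintf("slice_f%03d_s%03d.nii.gz", s$frame_index,
                        s$slice_index)
    vol <- image_volume(array(s$pixels, dim = c(dim(s$pixels), 1)),
                        s$position_mm, c(s$pixel_spacing_mm, 1),
                        cbind(s$row_dir, s$col_dir, slice_normal(s)))
    write_volume(vol, file.path(dir, paths[i]))
  }
  records <- lapply(seq_along(slices), function(i) {
    s <- slices[[i]]
    list(slice_id = s$slice_index, frame_id = s$frame_index,
         position_mm = s$position_mm, row_dir = s$row_dir,
         col_dir = s$col_dir, pixel_spacing_mm = s$pixel_spacing_mm,
         trigger_time_ms = s$trigger_time_ms, path = paths[i])
  })
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(records, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Read a cine manifest
#'
#' Loads all slices referenced by a JSON cine manifest and returns them
#' grouped and sorted by `(frame_index, position along the stack normal)`;
#' the result is therefore invariant to the ordering of manifest rows.
#'
#' @param path path to `manifest.json`.
#' @return list of [cine_slice()].
#' @export
read_cine_manifest <- function(path) {
  if (!file.exists(path)) stopf("cine manifest not found: %s", path)
  records <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(records) == 0) stopf("empty cine manifest: %s", path)
  dir <- dirname(path)
  slices <- lapply(records, function(r) {
    for (f in c("slice_id", "frame_id", "position_mm", "row_dir", "col_dir",
                "pixel_spacing_mm", "trigger_time_ms", "path"))
      if (is.null(r[[f]])) stopf("manifest record missing field '%s'", f)
    img <- RNifti::readNifti(file.path(dir, r$path))
    px <- as.array(img)
    if (length(dim(px)) == 3) px <- px[, , 1]
    attributes(px) <- list(dim = dim(px))
    cine_slice(px, unlist(r$position_mm), unlist(r$row_dir),
               unlist(r$col_dir), unlist(r$pixel_spacing_mm),
               r$trigger_time_ms, r$slice_id, r$frame_id)
  })
  ps <- t(vapply(slices, function(s) s$pixel_spacing_mm, numeric(2)))
  if (max(ps) - min(ps) > 1e-9)
    stopf("inconsistent pixel spacing across manifest slices")
  nrm <- slice_normal(slices[[1]])
  ord <- order(vapply(slices, function(s) s$frame_index, integer(1)),
               vapply(slices, function(s) sum(s$position_mm * nrm),
                      numeric(1)))
  slices[ord]
}
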