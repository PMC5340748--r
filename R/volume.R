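#' 3D image volume with world geometry
#'
#' Voxel data plus the geometry needed to map voxel indices to patient
#' coordinates: world position of voxel `(i,j,k)` (0-based) is
#' `origin + direction %*% (spacing * c(i,j,k))`. The direction matrix must be
#' orthonormal. All world-coordinate computations in the package go through
#' [voxel_to_world()] / [world_to_voxel()].
#'
#' @param voxels 3D numeric array.
#' @param origin_mm world position of voxel (0,0,0).
#' @param spacing_mm positive voxel spacing per axis (mm).
#' @param direction 3 x 3 orthonormal matrix (columns = world directions of
#'   the voxel axes).
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(voxels, origin_mm = c(0, 0, 0),
                         spacing_mm = c(1, 1, 1), direction = diag(3)) {
  if (length(dim(voxels)) != 3) stopf("voxels must be a 3D array")
  if (any(spacing_mm <= 0)) stopf("spacing must be positive")
  direction <- as.matrix(direction)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stopf("direction matrix is not orthonormal within 1e-6")
  structure(list(voxels = voxels, origin_mm = as.numeric(origin_mm),
                 spacing_mm = as.numeric(spacing_mm), direction = direction),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("%s: %s voxels, spacing (%s) mm\n",
              class(x)[1], paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = ", ")))
  invisible(x)
}

#' Integer-valued volume with a label dictionary
#'
#' @param voxels 3D integer array of label codes.
#' @param label_dictionary named integer vector mapping label name to code;
#'   every voxel value must appear in it.
#' @inheritParams image_volume
#' @return an object of class `label_map` (also an `image_volume`).
#' @export
label_map <- function(voxels, label_dictionary, origin_mm = c(0, 0, 0),
                      spacing_mm = c(1, 1, 1), direction = diag(3)) {
  storage.mode(voxels) <- "integer"
  vol <- image_volume(voxels, origin_mm, spacing_mm, direction)
  if (!all(unique(as.vector(voxels)) %in% label_dictionary))
    stopf("voxel values not covered by label_dictionary")
  vol$label_dictionary <- label_dictionary
  class(vol) <- c("label_map", class(vol))
  vol
}

#' Voxel index to world coordinate mapping
#'
#' @param vol an [image_volume()].
#' @param ijk N x 3 matrix of 0-based (possibly fractional) voxel indices.
#' @return N x 3 matrix of world coordinates (mm).
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  sweep(ijk %*% diag(vol$spacing_mm) %*% t(vol$direction), 2,
        vol$origin_mm, `+`)
}

#' @rdname voxel_to_world
#' @param xyz N x 3 matrix of world coordinates (mm).
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  sweep(xyz, 2, vol$origin_mm) %*% vol$direction %*% diag(1 / vol$spacing_mm)
}

volume_grid_world <- function(vol) {
  d <- dim(vol$voxels)
  ijk <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  voxel_to_world(vol, ijk)
}

voxel_volume <- function(vol) prod(vol$spacing_mm)

#' Sample a volume at world coordinates
#'
#' @param vol an [image_volume()].
#' @param xyz N x 3 world coordinates (mm).
#' @param method `"linear"` (intensities) or `"nearest"` (labels).
#' @param fill value returned outside the grid.
#' @return numeric vector of sampled values.
#' @export
sample_volume <- function(vol, xyz, method = c("linear", "nearest"),
                          fill = 0) {
  method <- match.arg(method)
  pts <- world_to_voxel(vol, xyz)
  if (method == "linear")
    cpp_trilinear(as.double(vol$voxels), dim(vol$voxels), pts, fill)
  else
    cpp_nearest(as.double(vol$voxels), dim(vol$voxels), pts, fill)
}

#' Read / write NIfTI-1 volumes
#'
#' The qform is treated as the authoritative geometry; if an sform is present
#' and inconsistent with the qform beyond 1e-3 mm a warning is emitted and the
#' qform is used. 4D files are rejected (volumes in this package are per-frame
#' 3D). Integer voxel data round-trips bitwise; geometry round-trips within
#' 1e-5 mm (quaternion storage is single precision).
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @return an [image_volume()] (or [label_map()] when `labels` given).
#' @export
read_volume <- function(path, labels = NULL) {
  if (!file.exists(path)) stopf("volume file not found: %s", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stopf("cannot read %s: %s", path,
                                            conditionMessage(e)))
  if (length(dim(img)) != 3)
    stopf("%s is %dD; per-frame 3D volumes are required", path,
          length(dim(img)))
  xf <- RNifti::xform(img, useQuaternionFirst = TRUE)
  sf <- try(RNifti::niftiHeader(img), silent = TRUE)
  if (!inherits(sf, "try-error") && sf$sform_code > 0 && sf$qform_code > 0) {
    sm <- rbind(sf$srow_x, sf$srow_y, sf$srow_z)
    if (max(abs(sm - xf[1:3, ])) > 1e-3)
      warnf("qform/sform mismatch in %s; using qform", path)
  }
  sp <- sqrt(colSums(xf[1:3, 1:3]^2))
  dirm <- xf[1:3, 1:3] %*% diag(1 / sp)
  vox <- as.array(img)
  attributes(vox) <- list(dim = dim(vox))
  if (is.null(labels))
    image_volume(vox, xf[1:3, 4], sp, dirm)
  else
    label_map(vox, labels, xf[1:3, 4], sp, dirm)
}

#' @rdname read_volume
#' @param vol an [image_volume()] to write.
#' @export
write_volume <- function(vol, path) {
  vox <- vol$voxels
  img <- RNifti::asNifti(vox)
  pixdim(img) <- vol$spacing_mm
  m <- rbind(cbind(vol$direction %*% diag(vol$spacing_mm), vol$origin_mm),
             c(0, 0, 0, 1))
  qform(img) <- structure(m, code = 1L)
  sform(img) <- structure(m, code = 1L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @param labels named integer label dictionary for reading a [label_map()].
#' @export
read_label_map <- function(path, labels) read_volume(path, labels = labels)
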