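# Statistical shape analysis: PCA over momenta, shape modes visualized by
# deforming the template +/- 2 sigma along each mode, and per-subject shape
# vectors (projections of the centered momenta onto the modes).

#' Stack momenta sets into a samples-by-coefficients matrix
#'
#' Flattening is point-major with xyz contiguous within a point:
#' row = `(x1, y1, z1, x2, y2, z2, ...)`. Row order equals input order.
#'
#' @param momenta list of K x 3 momenta matrices sharing one control grid.
#' @return n x 3K matrix.
#' @export
stack_momenta <- function(momenta) {
  if (!length(momenta)) stopf("no momenta sets given")
  k <- nrow(momenta[[1]])
  rows <- lapply(momenta, function(m) {
    if (!is.matrix(m) || ncol(m) != 3 || nrow(m) != k)
      stopf("momenta sets disagree in control-point count")
    as.vector(t(m))
  })
  do.call(rbind, rows)
}

unstack_momenta <- function(v) matrix(v, ncol = 3, byrow = TRUE)

#' Principal component analysis of momenta vectors
#'
#' Column-mean centering followed by an eigendecomposition of the sample
#' covariance (divisor n - 1), computed through the SVD of the centered
#' matrix. At most n - 1 eigenvalues are nonzero. Mode signs follow a fixed
#' convention (the largest-magnitude loading of each mode is positive) so
#' results are reproducible; coefficient signs are otherwise arbitrary.
#'
#' @param x n x p matrix (rows = samples), e.g. from [stack_momenta()].
#' @return object of class `pca_model`: `mean`, `modes` (p x r orthonormal),
#'   `eigenvalues` (descending), `variance_fraction` (sums to 1).
#' @export
fit_pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stopf("need at least 2 samples")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc)
  r <- min(nrow(x) - 1, ncol(x))
  eig <- (sv$d^2 / (nrow(x) - 1))[seq_len(r)]
  modes <- sv$v[, seq_len(r), drop = FALSE]
  if (sum(eig) <= 1e-24) {
    warnf("zero-variance input: PCA model has a single zero mode")
    modes <- modes[, 1, drop = FALSE]
    eig <- 0
  }
  for (j in seq_len(ncol(modes))) {
    i <- which.max(abs(modes[, j]))
    if (modes[i, j] < 0) modes[, j] <- -modes[, j]
  }
  vf <- if (sum(eig) > 0) eig / sum(eig) else 1
  structure(list(mean = mu, modes = modes, eigenvalues = eig,
                 variance_fraction = vf),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d modes, leading variance fractions %s\n",
              length(x$eigenvalues),
              paste(sprintf("%.1f%%", 100 * head(x$variance_fraction, 4)),
                    collapse = ", ")))
  invisible(x)
}

#' Project a momenta set onto the PCA modes
#'
#' Coefficients are `t(modes) %*% (flattened - mean)`: each entry states how
#' far along the corresponding mode the template must be deformed to match
#' the shape.
#'
#' @param momenta K x 3 matrix (or an already-flattened 3K vector).
#' @param pca a `pca_model` from [fit_pca()].
#' @return named numeric vector of mode coefficients.
#' @export
project <- function(momenta, pca) {
  v <- if (is.matrix(momenta) && ncol(momenta) == 3) as.vector(t(momenta))
       else as.numeric(momenta)
  if (length(v) != length(pca$mean))
    stopf("momenta dimension %d does not match the PCA model (%d)",
          length(v), length(pca$mean))
  cf <- as.vector(crossprod(pca$modes, v - pca$mean))
  names(cf) <- paste0("mode_", seq_along(cf))
  cf
}

#' Template deformed to a mode extreme
#'
#' Flows the template with momenta `mean + sigma_multiple * sqrt(eigenvalue)
#' * mode`; `sigma_multiple = 2` and `-2` give the +/- 2 sigma shapes used to
#' visualize a mode.
#'
#' @param template template [surface_mesh()].
#' @param cp control points of the model the PCA was fitted on.
#' @param pca a `pca_model`.
#' @param mode_index which mode.
#' @param sigma_multiple in \[-3, 3\].
#' @param kernel [kernel_params()] of the model.
#' @return deformed [surface_mesh()].
#' @export
mode_mesh <- function(template, cp, pca, mode_index, sigma_multiple, kernel) {
  if (abs(sigma_multiple) > 3) stopf("|sigma_multiple| must be <= 3")
  if (mode_index < 1 || mode_index > length(pca$eigenvalues))
    stopf("mode_index out of range")
  v <- pca$mean + sigma_multiple * sqrt(pca$eigenvalues[mode_index]) *
    pca$modes[, mode_index]
  flow(template, cp, unstack_momenta(v), kernel)
}

#' Per-vertex deformation magnitude between mode extremes
#'
#' @param template template mesh (used for the `"template"` reference).
#' @param mode_mesh_plus,mode_mesh_minus the +/- sigma meshes (same
#'   topology).
#' @param reference `"pair"` (displacement between the two extremes) or
#'   `"template"` (mean displacement of the extremes from the template).
#' @return numeric per-vertex magnitude (mm).
#' @export
deformation_magnitude_map <- function(template, mode_mesh_plus,
                                      mode_mesh_minus,
                                      reference = c("pair", "template")) {
  reference <- match.arg(reference)
  if (!identical(dim(mode_mesh_plus$vertices),
                 dim(mode_mesh_minus$vertices)))
    stopf("mode meshes disagree in topology")
  if (reference == "pair")
    return(sqrt(rowSums((mode_mesh_plus$vertices -
                           mode_mesh_minus$vertices)^2)))
  if (!identical(dim(template$vertices), dim(mode_mesh_plus$vertices)))
    stopf("template topology does not match the mode meshes")
  0.5 * (sqrt(rowSums((mode_mesh_plus$vertices - template$vertices)^2)) +
           sqrt(rowSums((mode_mesh_minus$vertices - template$vertices)^2)))
}

select_phase_mesh <- function(model, phase = c("ED", "ES")) {
  phase <- match.arg(phase)
  vols <- vapply(model$momenta, function(b) {
    m <- flow(model$template, model$control_points, b, model$kernel)
    if (!is.null(m$vertex_labels) && any(m$vertex_labels == "endo"))
      endocardial_volume(m)
    else
      abs(signed_mesh_volume(m))
  }, numeric(1))
  t <- if (phase == "ED") which.max(vols) else which.min(vols)
  list(mesh = flow(model$template, model$control_points, model$momenta[[t]],
                   model$kernel),
       frame = t, volume = vols[t])
}

default_mode_count <- function(pca, n_modes = NULL, cum_target = 0.75) {
  if (!is.null(n_modes)) return(min(n_modes, length(pca$eigenvalues)))
  cf <- cumsum(pca$variance_fraction)
  max(1L, min(which(cf >= cum_target), length(pca$eigenvalues)))
}

#' Cross-subject shape analysis at one cardiac phase
#'
#' Uses each subject's end-diastolic (maximal endocardial volume) or
#' end-systolic (minimal) mesh, estimates one anatomical model over those
#' phase meshes, runs PCA on the per-subject momenta, and returns shape
#' vectors plus +/- 2 sigma mode meshes with deformation-magnitude maps.
#'
#' Phase meshes are ideally the subjects' own segmented frame meshes brought
#' into the common space (`phase_meshes`); when not supplied, each subject's
#' template is flowed with the extremal-volume frame momenta instead (which
#' carries any template-fit bias into the phase shapes).
#'
#' @param models per-subject [anatomical_model()]s in the common (scaled and
#'   aligned) space.
#' @param kernel [kernel_params()] for the phase atlas.
#' @param n_modes modes to report; default reaches 75% cumulative variance.
#' @param n_control_points,opt_params passed to [estimate_atlas()].
#' @param phase `"ED"` or `"ES"`.
#' @param subject_ids optional ids (defaults to model provenance or index).
#' @param phase_meshes optional list (one [surface_mesh()] per subject) of
#'   the selected phase meshes in the common space.
#' @return list with `phase`, `model` (the phase atlas), `pca`,
#'   `shape_vectors` (data frame), `mode_meshes` (list of `plus`/`minus`
#'   per mode), `magnitude_maps`.
#' @export
run_shape_analysis <- function(models, kernel, n_modes = NULL,
                               n_control_points = 125, opt_params = list(),
                               phase = c("ED", "ES"), subject_ids = NULL,
                               phase_meshes = NULL) {
  phase <- match.arg(phase)
  if (length(models) < 2) stopf("need at least 2 subjects")
  ids <- subject_ids %||% vapply(seq_along(models), function(i)
    models[[i]]$provenance$subject_id %||% sprintf("subject_%d", i),
    character(1))
  if (is.null(phase_meshes))
    phase_meshes <- lapply(models, function(m)
      select_phase_mesh(m, phase)$mesh)
  if (length(phase_meshes) != length(models))
    stopf("need one phase mesh per subject")
  atlas <- estimate_atlas(phase_meshes, kernel, n_control_points, opt_params)
  x <- stack_momenta(atlas$momenta)
  pca <- fit_pca(x)
  nm <- default_mode_count(pca, n_modes)
  sv <- t(vapply(seq_along(models), function(i)
    project(atlas$momenta[[i]], pca)[seq_len(nm)], numeric(nm)))
  shape_vectors <- data.frame(subject_id = ids, sv)
  names(shape_vectors)[-1] <- paste0("mode_", seq_len(nm))
  mode_meshes <- list()
  magnitude_maps <- list()
  for (m in seq_len(nm)) {
    plus <- mode_mesh(atlas$template, atlas$control_points, pca, m, 2,
                      atlas$kernel)
    minus <- mode_mesh(atlas$template, atlas$control_points, pca, m, -2,
                       atlas$kernel)
    mode_meshes[[m]] <- list(plus = plus, minus = minus)
    magnitude_maps[[m]] <- deformation_magnitude_map(atlas$template, plus,
                                                     minus)
  }
  list(phase = phase, model = atlas, pca = pca,
       shape_vectors = shape_vectors, mode_meshes = mode_meshes,
       magnitude_maps = magnitude_maps)
}
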