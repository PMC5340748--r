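# Subject anatomical models: a template mesh plus, per target shape, a set of
# momenta attached to a control-point grid. Deformations are flows of the
# Gaussian-kernel velocity field carried by the momenta (a desk-scale variant
# of large-deformation diffeomorphic registration: momenta are held constant
# along the flow, control points are advected). The data term is the currents
# metric, which compares oriented surfaces without point correspondence.

#' Kernel parameters of an anatomical model
#'
#' `lambda_w_mm` sets the spatial resolution of the currents data term (how
#' fine a shape detail is seen); `lambda_v_mm` sets the stiffness of the
#' deformation field (displacements closer than `lambda_v` move together).
#'
#' @param lambda_w_mm data-term kernel width (mm).
#' @param lambda_v_mm deformation kernel width (mm).
#' @param n_integration_steps Euler steps used to integrate flows.
#' @return object of class `kernel_params`.
#' @export
kernel_params <- function(lambda_w_mm = 13, lambda_v_mm = 23,
                          n_integration_steps = 10) {
  if (lambda_w_mm <= 0 || lambda_v_mm <= 0) stopf("kernel widths must be > 0")
  if (n_integration_steps < 1) stopf("n_integration_steps must be >= 1")
  structure(list(lambda_w_mm = lambda_w_mm, lambda_v_mm = lambda_v_mm,
                 n_integration_steps = as.integer(n_integration_steps)),
            class = "kernel_params")
}

#' Gaussian kernel matrix
#'
#' Entries `exp(-|x_a - y_b|^2 / lambda^2)`; symmetric positive semidefinite
#' when `x == y`.
#'
#' @param x,y point sets (N x 3, M x 3).
#' @param lambda_mm kernel width (mm).
#' @return N x M matrix.
#' @export
gaussian_kernel <- function(x, y, lambda_mm) {
  if (lambda_mm <= 0) stopf("lambda must be positive")
  x <- as_num_matrix(x, 3, "x")
  y <- as_num_matrix(y, 3, "y")
  d2 <- outer(rowSums(x^2), rowSums(y^2), `+`) - 2 * tcrossprod(x, y)
  exp(-pmax(d2, 0) / lambda_mm^2)
}

#' Regular control-point grid over a mesh bounding box
#'
#' @param mesh a [surface_mesh()].
#' @param n_control_points requested count; realized as the nearest integer
#'   cube (e.g. 125 gives a 5 x 5 x 5 grid).
#' @param margin_mm bounding-box expansion.
#' @return K x 3 matrix of control points.
#' @export
control_point_grid <- function(mesh, n_control_points = 125, margin_mm = 5) {
  k1 <- max(2L, round(n_control_points^(1 / 3)))
  lo <- apply(mesh$vertices, 2, min) - margin_mm
  hi <- apply(mesh$vertices, 2, max) + margin_mm
  g <- lapply(1:3, function(q) seq(lo[q], hi[q], length.out = k1))
  as.matrix(expand.grid(g[[1]], g[[2]], g[[3]]))
}

flow_points <- function(x, cp, momenta, kernel) {
  cpp_flow(as_num_matrix(x, 3, "points"), as_num_matrix(cp, 3, "cp"),
           as_num_matrix(momenta, 3, "momenta"), kernel$lambda_v_mm,
           kernel$n_integration_steps)
}

#' Deform a mesh by flowing its vertices along a momenta field
#'
#' Integrates `dx/dt = sum_k K_v(x, c_k(t)) beta_k` with forward Euler over
#' t in \[0, 1\]; control points are advected by the same field and momenta
#' held constant. Zero momenta return the input bit-exactly. Connectivity and
#' labels are preserved.
#'
#' @param mesh a [surface_mesh()].
#' @param cp K x 3 control points.
#' @param momenta K x 3 momenta vectors.
#' @param kernel a [kernel_params()].
#' @return deformed [surface_mesh()].
#' @export
flow <- function(mesh, cp, momenta, kernel) {
  fl <- flow_points(mesh$vertices, cp, momenta, kernel)
  if (any(!is.finite(fl$x))) stopf("non-finite vertices after flow")
  surface_mesh(fl$x, mesh$triangles, mesh$vertex_labels)
}

mesh_currents_geometry <- function(mesh, warn_degenerate = TRUE) {
  g <- triangle_geometry(mesh)
  ok <- g$areas > 1e-12
  if (!all(ok) && warn_degenerate)
    warnf("skipping %d zero-area triangles in currents computation",
          sum(!ok))
  list(centers = g$centers[ok, , drop = FALSE],
       normals = g$normals[ok, , drop = FALSE])
}

#' Currents distance between two oriented surfaces
#'
#' `||a - b||^2 = S(a,a) + S(b,b) - 2 S(a,b)` with
#' `S(p,q) = sum_ij K_w(c_i, c_j) (n_i . n_j)` over triangle centers and
#' area-weighted normals. Symmetric, zero for identical meshes, and defined
#' without any point correspondence between the meshes.
#'
#' @param a,b triangulated [surface_mesh()] objects.
#' @param lambda_w_mm data-term kernel width (mm).
#' @return nonnegative squared currents distance.
#' @export
currents_distance <- function(a, b, lambda_w_mm) {
  ga <- mesh_currents_geometry(a)
  gb <- mesh_currents_geometry(b)
  saa <- cpp_currents_product(ga$centers, ga$normals, ga$centers, ga$normals,
                              lambda_w_mm)
  sbb <- cpp_currents_product(gb$centers, gb$normals, gb$centers, gb$normals,
                              lambda_w_mm)
  # canonical argument order so d(a,b) and d(b,a) sum in the same order
  # (floating-point addition is not commutative across orderings)
  swap <- nrow(gb$centers) < nrow(ga$centers) ||
    (nrow(gb$centers) == nrow(ga$centers) &&
       isTRUE(sum(gb$centers) < sum(ga$centers)))
  sab <- if (swap)
    cpp_currents_product(gb$centers, gb$normals, ga$centers, ga$normals,
                         lambda_w_mm)
  else
    cpp_currents_product(ga$centers, ga$normals, gb$centers, gb$normals,
                         lambda_w_mm)
  max(0, saa + sbb - 2 * sab)
}

#' Deformation energy of a momenta set
#'
#' `sum_kl K_v(c_k, c_l) (beta_k . beta_l)`; invariant under joint rigid
#' rotation of control points and momenta.
#'
#' @param cp K x 3 control points.
#' @param momenta K x 3 momenta.
#' @param lambda_v_mm deformation kernel width.
#' @return nonnegative energy.
#' @export
momenta_energy <- function(cp, momenta, lambda_v_mm) {
  k <- gaussian_kernel(cp, cp, lambda_v_mm)
  sum((k %*% momenta) * momenta)
}

default_opt_params <- function(opt_params = list()) {
  defaults <- list(max_iter = 60, tol = 1e-6, gamma = 1, step0 = NULL,
                   max_outer = 30, outer_tol = 1e-4, reg_iters = 25,
                   optimize_control_points = FALSE, warm_start_chain = FALSE,
                   verbose = FALSE)
  defaults[names(opt_params)] <- opt_params
  defaults
}

registration_energy <- function(verts, tris, cp, beta, kernel, gb, sbb,
                                gamma, kv) {
  fl <- cpp_flow(verts, cp, beta, kernel$lambda_v_mm,
                 kernel$n_integration_steps)
  m <- surface_mesh(fl$x, tris)
  ga <- mesh_currents_geometry(m, warn_degenerate = FALSE)
  saa <- cpp_currents_product(ga$centers, ga$normals, ga$centers, ga$normals,
                              kernel$lambda_w_mm)
  sab <- cpp_currents_product(ga$centers, ga$normals, gb$centers, gb$normals,
                              kernel$lambda_w_mm)
  e <- saa - 2 * sab + sbb + gamma * sum((kv %*% beta) * beta)
  attr(e, "area") <- sum(sqrt(rowSums(ga$normals^2)))
  e
}

#' Register a template mesh onto a target by momenta estimation
#'
#' Minimizes `J(beta) = ||flow(template, beta) - target||^2_currents +
#' gamma * sum_kl K_v(c_k, c_l) beta_k . beta_l` by gradient descent with
#' backtracking line search (adjoint gradients through the Euler flow).
#' Deterministic given its inputs; the energy strictly decreases across
#' accepted iterations.
#'
#' @param template,target [surface_mesh()] objects.
#' @param cp K x 3 control points.
#' @param kernel a [kernel_params()].
#' @param opt_params list: `max_iter`, `tol` (relative energy decrease),
#'   `gamma` (regularity weight), `step0`, `init_momenta` (warm start).
#' @return K x 3 momenta matrix with attributes `energy` (trace of accepted
#'   energies), `target_id`.
#' @export
estimate_registration <- function(template, target, cp, kernel,
                                  opt_params = list()) {
  opt <- default_opt_params(opt_params)
  verts <- template$vertices
  tris <- template$triangles
  cp <- as_num_matrix(cp, 3, "cp")
  gb <- mesh_currents_geometry(target, warn_degenerate = FALSE)
  sbb <- cpp_currents_product(gb$centers, gb$normals, gb$centers, gb$normals,
                              kernel$lambda_w_mm)
  kv <- gaussian_kernel(cp, cp, kernel$lambda_v_mm)
  beta <- opt_params$init_momenta %||% matrix(0, nrow(cp), 3)
  # the currents norm of a surface shrinks as the surface shrinks, so a
  # partial collapse of the deformed template can masquerade as a good fit;
  # candidates whose total area drops below 70% of the target's area are
  # rejected outright
  target_area <- sum(sqrt(rowSums(gb$normals^2)))
  energy <- function(b) registration_energy(verts, tris, cp, b, kernel, gb,
                                            sbb, opt$gamma, kv)
  grad <- function(b) {
    fl <- cpp_flow(verts, cp, b, kernel$lambda_v_mm,
                   kernel$n_integration_steps)
    eg <- cpp_currents_energy_grad(fl$x, tris - 1L, gb$centers, gb$normals,
                                   sbb, kernel$lambda_w_mm)
    vjp <- cpp_flow_vjp(fl$xs, fl$cs, b, kernel$lambda_v_mm,
                        kernel$n_integration_steps, eg$grad)
    list(g = vjp$dbeta + 2 * opt$gamma * (kv %*% b),
         e = eg$energy + opt$gamma * sum((kv %*% b) * b))
  }
  g0 <- grad(beta)
  e <- g0$e
  cur_area <- attr(energy(beta), "area")
  trace <- e
  gscale <- max(abs(g0$g), 1e-12)
  step <- opt$step0 %||% (0.5 / gscale)
  g <- g0$g
  for (it in seq_len(opt$max_iter)) {
    accepted <- FALSE
    while (step > 1e-14 / gscale) {
      cand <- beta - step * g
      ec <- energy(cand)
      ok_area <- attr(ec, "area") >= 0.7 * target_area ||
        attr(ec, "area") > cur_area
      if (is.finite(ec) && ec < e && ok_area) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break  # no descent possible at machine step: converged
    rel <- (e - ec) / max(abs(e), 1e-12)
    beta <- cand
    e <- ec
    cur_area <- attr(ec, "area")
    trace <- c(trace, as.numeric(e))
    if (rel < opt$tol) break
    gg <- grad(beta)
    g <- gg$g
    step <- step * 1.5
  }
  structure(beta, energy = trace, target_id = attr(target, "id"))
}

#' Subject anatomical model
#'
#' @param template template [surface_mesh()].
#' @param control_points K x 3 control points.
#' @param momenta list of K x 3 momenta matrices, one per target shape.
#' @param kernel a [kernel_params()].
#' @param provenance free-form list (input ids, seeds).
#' @return object of class `anatomical_model`.
#' @export
anatomical_model <- function(template, control_points, momenta, kernel,
                             provenance = list()) {
  control_points <- as_num_matrix(control_points, 3, "control_points")
  for (m in momenta)
    if (!all(dim(m) == dim(control_points)))
      stopf("each momenta set must be K x 3 matching the control points")
  structure(list(template = template, control_points = control_points,
                 momenta = momenta, kernel = kernel,
                 provenance = provenance),
            class = "anatomical_model")
}

#' @export
print.anatomical_model <- function(x, ...) {
  cat(sprintf(paste0("anatomical_model: template %d vertices, %d control ",
                     "points, %d momenta sets (lambda_w %.3g mm, lambda_v ",
                     "%.3g mm)\n"),
              n_vertices(x$template), nrow(x$control_points),
              length(x$momenta), x$kernel$lambda_w_mm, x$kernel$lambda_v_mm))
  invisible(x)
}

atlas_total_energy <- function(template, cp, momenta, kernel, shapes_geom,
                               sbb_list, gamma, kv) {
  tot <- 0
  for (i in seq_along(momenta))
    tot <- tot + registration_energy(template$vertices, template$triangles,
                                     cp, momenta[[i]], kernel,
                                     shapes_geom[[i]], sbb_list[[i]], gamma,
                                     kv)
  tot
}

#' Estimate a template-and-momenta atlas from a set of shapes
#'
#' Alternate optimization: (i) given the template, estimate per-shape momenta
#' with [estimate_registration()] (warm-started); (ii) given the momenta,
#' update template vertices by a backtracking gradient step on the summed
#' currents energies. The template is initialized as the vertexwise mean when
#' all shapes share one topology, otherwise as the first shape; control
#' points sit on a regular grid over the template bounding box. The total
#' energy is non-increasing across outer iterations.
#'
#' @param shapes list of >= 2 [surface_mesh()] objects.
#' @param kernel a [kernel_params()].
#' @param n_control_points requested control-point count (default 125).
#' @param opt_params list; see [estimate_registration()] plus `max_outer`,
#'   `outer_tol`, `optimize_control_points`.
#' @return an [anatomical_model()] with attribute `energy_trace`.
#' @export
estimate_atlas <- function(shapes, kernel, n_control_points = 125,
                           opt_params = list()) {
  if (length(shapes) < 2) stopf("need at least 2 shapes")
  opt <- default_opt_params(opt_params)
  same_topology <- all(vapply(shapes, function(s)
    identical(dim(s$triangles), dim(shapes[[1]]$triangles)) &&
      all(s$triangles == shapes[[1]]$triangles), logical(1)))
  template <- shapes[[1]]
  if (same_topology) {
    vm <- Reduce(`+`, lapply(shapes, function(s) s$vertices)) / length(shapes)
    template <- surface_mesh(vm, shapes[[1]]$triangles,
                             shapes[[1]]$vertex_labels)
  }
  cp <- control_point_grid(template, n_control_points)
  kv <- gaussian_kernel(cp, cp, kernel$lambda_v_mm)
  geoms <- lapply(shapes, mesh_currents_geometry, warn_degenerate = FALSE)
  sbbs <- lapply(geoms, function(g)
    cpp_currents_product(g$centers, g$normals, g$centers, g$normals,
                         kernel$lambda_w_mm))
  momenta <- rep(list(matrix(0, nrow(cp), 3)), length(shapes))
  reg_opt <- opt
  reg_opt$max_iter <- opt$reg_iters
  e_tot <- atlas_total_energy(template, cp, momenta, kernel, geoms, sbbs,
                              opt$gamma, kv)
  trace <- e_tot
  for (outer in seq_len(opt$max_outer)) {
    # (i) momenta updates; with warm_start_chain (temporally ordered inputs,
    # e.g. cardiac frames) the first sweep seeds each shape's momenta from
    # its predecessor's solution
    for (i in seq_along(shapes)) {
      ro <- reg_opt
      init <- momenta[[i]]
      if (isTRUE(opt$warm_start_chain) && outer == 1 && i > 1 &&
          all(init == 0))
        init <- momenta[[i - 1]]
      ro$init_momenta <- init
      momenta[[i]] <- unclass(estimate_registration(template, shapes[[i]],
                                                    cp, kernel, ro))
      attributes(momenta[[i]])[c("energy", "target_id")] <- NULL
    }
    # (ii) template vertex update by backtracking gradient step
    gsum <- matrix(0, n_vertices(template), 3)
    for (i in seq_along(shapes)) {
      fl <- cpp_flow(template$vertices, cp, momenta[[i]], kernel$lambda_v_mm,
                     kernel$n_integration_steps)
      eg <- cpp_currents_energy_grad(fl$x, template$triangles - 1L,
                                     geoms[[i]]$centers, geoms[[i]]$normals,
                                     sbbs[[i]], kernel$lambda_w_mm)
      vjp <- cpp_flow_vjp(fl$xs, fl$cs, momenta[[i]], kernel$lambda_v_mm,
                          kernel$n_integration_steps, eg$grad)
      gsum <- gsum + vjp$dx0
    }
    e_cur <- atlas_total_energy(template, cp, momenta, kernel, geoms, sbbs,
                                opt$gamma, kv)
    step <- 0.5 / max(abs(gsum), 1e-12)
    repeat {
      cand <- surface_mesh(template$vertices - step * gsum,
                           template$triangles, template$vertex_labels)
      ec <- atlas_total_energy(cand, cp, momenta, kernel, geoms, sbbs,
                               opt$gamma, kv)
      if (is.finite(ec) && ec < e_cur) {
        template <- cand
        e_cur <- ec
        break
      }
      step <- step / 2
      if (step < 1e-12) break
    }
    if (opt$verbose)
      message(sprintf("atlas outer %d: energy %.6g", outer, e_cur))
    trace <- c(trace, e_cur)
    if ((e_tot - e_cur) / max(abs(e_tot), 1e-12) < opt$outer_tol) {
      e_tot <- e_cur
      break
    }
    e_tot <- e_cur
  }
  structure(anatomical_model(template, cp, momenta, kernel,
                             provenance = list(n_shapes = length(shapes))),
            energy_trace = trace)
}

#' Tune kernel widths on a grid by template-match surface distance
#'
#' For every `(lambda_w, lambda_v)` combination, estimates an atlas and
#' records the mean (over shapes) of the mean surface distance between the
#' flowed template and each input shape; returns the argmin and the full
#' score table.
#'
#' @param shapes list of [surface_mesh()].
#' @param lambda_w_grid,lambda_v_grid candidate widths (mm).
#' @param n_control_points,opt_params passed to [estimate_atlas()].
#' @return list with `kernel` (best [kernel_params()]) and `table`
#'   (data frame lambda_w, lambda_v, mean_surface_distance_mm).
#' @export
tune_parameters <- function(shapes, lambda_w_grid, lambda_v_grid,
                            n_control_points = 125, opt_params = list()) {
  if (!length(lambda_w_grid) || !length(lambda_v_grid))
    stopf("parameter grids must be non-empty")
  rows <- NULL
  for (lw in lambda_w_grid)
    for (lv in lambda_v_grid) {
      k <- kernel_params(lw, lv)
      model <- estimate_atlas(shapes, k, n_control_points, opt_params)
      ds <- vapply(seq_along(shapes), function(i) {
        m <- flow(model$template, model$control_points, model$momenta[[i]],
                  model$kernel)
        surface_distance(m, shapes[[i]])$mean
      }, numeric(1))
      rows <- rbind(rows, data.frame(lambda_w_mm = lw, lambda_v_mm = lv,
                                     mean_surface_distance_mm = mean(ds)))
    }
  best <- rows[which.min(rows$mean_surface_distance_mm), ]
  list(kernel = kernel_params(best$lambda_w_mm, best$lambda_v_mm),
       table = rows)
}
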