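# Cross-subject normalization: volume scaling of each subject model followed
# by rigid co-alignment of the subject templates (generalized Procrustes on
# the endocardial surfaces, rigid ICP inside), with the resulting transforms
# applied to the whole model (template, control points, momenta).

#' Extract the closed endocardial (blood-pool) surface
#'
#' Takes the triangles whose vertices are all labelled `"endo"`, closes the
#' basal opening with a fan cap, and orients the result outward (positive
#' enclosed volume).
#'
#' @param mesh a labelled [surface_mesh()].
#' @return closed [surface_mesh()].
#' @export
endocardial_surface <- function(mesh) {
  if (is.null(mesh$vertex_labels)) stopf("mesh has no vertex labels")
  if (!any(mesh$vertex_labels == "endo")) stopf("mesh has no endo labels")
  close_surface_subset(mesh, mesh$vertex_labels == "endo")
}

#' @rdname endocardial_surface
#' @export
epicardial_surface <- function(mesh) {
  if (is.null(mesh$vertex_labels)) stopf("mesh has no vertex labels")
  if (!any(mesh$vertex_labels == "epi")) stopf("mesh has no epi labels")
  close_surface_subset(mesh, mesh$vertex_labels == "epi")
}

#' Endocardial volume of a labelled wall mesh
#'
#' Divergence-theorem volume of the capped endocardial submesh. Unlike
#' [enclosed_volume()] this tolerates the non-manifold artifacts that
#' decimated meshes can carry: the capped submesh is consistently oriented
#' by construction, so the magnitude of its signed volume is reliable even
#' when the strict edge-pairing closedness check fails.
#'
#' @param mesh a labelled [surface_mesh()].
#' @return endocardial (blood-pool) volume in mm^3.
#' @export
endocardial_volume <- function(mesh) {
  abs(signed_mesh_volume(endocardial_surface(mesh)))
}

#' Similarity transform (rotation, translation, isotropic scale)
#'
#' @param rotation 3 x 3 orthonormal, det +1.
#' @param translation_mm 3-vector (mm).
#' @param scale positive scalar.
#' @return object of class `similarity_transform`.
#' @export
similarity_transform <- function(rotation = diag(3),
                                 translation_mm = c(0, 0, 0), scale = 1) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stopf("rotation is not orthonormal within 1e-8")
  if (det(rotation) < 0) stopf("rotation has negative determinant")
  if (scale <= 0) stopf("scale must be positive")
  structure(list(rotation = rotation,
                 translation_mm = as.numeric(translation_mm), scale = scale),
            class = "similarity_transform")
}

apply_transform_points <- function(tf, x) {
  sweep(x %*% t(tf$rotation) * tf$scale, 2, tf$translation_mm, `+`)
}

apply_transform_mesh <- function(tf, mesh) {
  surface_mesh(apply_transform_points(tf, mesh$vertices), mesh$triangles,
               mesh$vertex_labels)
}

compose_transforms <- function(t2, t1) {
  # returns t2 o t1
  similarity_transform(t2$rotation %*% t1$rotation,
                       t2$scale * as.vector(t2$rotation %*%
                                              t1$translation_mm) +
                         t2$translation_mm,
                       t2$scale * t1$scale)
}

#' Scale a subject model to a reference endocardial volume
#'
#' Computes `s = (V_ref / V_subject)^(1/3)` from the template's endocardial
#' volume and scales template vertices, control points and momenta about the
#' template centroid. Kernel widths are scaled by the same factor so the
#' scaled momenta reproduce the scaled deformations exactly.
#'
#' @param model an [anatomical_model()] with a labelled template.
#' @param reference_volume_mm3 target endocardial volume (mm^3).
#' @return rescaled [anatomical_model()]; the applied transform is attached
#'   as attribute `"transform"`.
#' @export
scale_model <- function(model, reference_volume_mm3) {
  if (reference_volume_mm3 <= 0) stopf("reference volume must be positive")
  v <- endocardial_volume(model$template)
  s <- (reference_volume_mm3 / v)^(1 / 3)
  ctr <- mesh_centroid(model$template)
  tf <- similarity_transform(diag(3), ctr - s * ctr, s)
  out <- apply_transform_to_model(model, tf)
  attr(out, "transform") <- tf
  out
}

#' Apply a similarity transform to a whole anatomical model
#'
#' Vertices and control points map as `x -> s R x + t`; momenta map as
#' `beta -> s R beta`; kernel widths scale by `s`. With that convention the
#' flow commutes with the transform:
#' `flow(T(template), T(beta)) == T(flow(template, beta))`.
#'
#' @param model an [anatomical_model()].
#' @param tf a [similarity_transform()].
#' @return transformed [anatomical_model()].
#' @export
apply_transform_to_model <- function(model, tf) {
  kern <- model$kernel
  kern$lambda_v_mm <- kern$lambda_v_mm * tf$scale
  kern$lambda_w_mm <- kern$lambda_w_mm * tf$scale
  anatomical_model(apply_transform_mesh(tf, model$template),
                   apply_transform_points(tf, model$control_points),
                   lapply(model$momenta, function(b)
                     b %*% t(tf$rotation) * tf$scale),
                   kern, model$provenance)
}

kabsch_rotation <- function(src, dst) {
  # least-squares rotation mapping centered src onto centered dst
  h <- crossprod(src, dst)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
}

principal_axes_candidates <- function(mv, fv) {
  # candidate initial transforms: identity (centroid shift), principal-axes
  # alignments for all det +1 sign assignments, and rotations about the
  # dominant principal axis (the in-plane eigenvectors are unreliable when
  # the transverse eigenvalues are nearly degenerate)
  em <- eigen(stats::cov(mv), symmetric = TRUE)$vectors
  ef <- eigen(stats::cov(fv), symmetric = TRUE)$vectors
  if (det(em) < 0) em[, 3] <- -em[, 3]
  if (det(ef) < 0) ef[, 3] <- -ef[, 3]
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  cands <- c(list(diag(3)),
             lapply(signs, function(s) ef %*% diag(s) %*% t(em)))
  axis <- ef[, 1]
  for (ang in c(-30, -15, 15, 30) * pi / 180) {
    c1 <- cos(ang)
    s1 <- sin(ang)
    k <- rbind(c(0, -axis[3], axis[2]), c(axis[3], 0, -axis[1]),
               c(-axis[2], axis[1], 0))
    raxis <- diag(3) + s1 * k + (1 - c1) * (k %*% k)
    cands[[length(cands) + 1]] <- raxis
  }
  mc <- colMeans(mv)
  fc <- colMeans(fv)
  lapply(cands, function(r)
    similarity_transform(r, fc - as.vector(r %*% mc), 1))
}

#' Rigid iterative-closest-point alignment
#'
#' Alternates nearest-vertex correspondence with a Kabsch (SVD, reflection
#' guarded) rigid solve, after a pre-alignment of centroids and principal
#' axes. The RMS closest-point distance is non-increasing across iterations;
#' scale is fixed at 1.
#'
#' @param moving,fixed [surface_mesh()] objects.
#' @param max_iter iteration cap.
#' @param tol stop when the RMS improves by less than `tol` (mm).
#' @param max_points correspondence searches use at most this many evenly
#'   spaced moving vertices (the fitted transform is exact either way).
#' @return a [similarity_transform()] with attributes `rms` (trace) and
#'   `converged`.
#' @export
icp_rigid <- function(moving, fixed, max_iter = 50, tol = 1e-6,
                      max_points = 800) {
  mv <- moving$vertices
  # evenly spaced vertex subset for correspondence search (deterministic)
  if (nrow(mv) > max_points)
    mv <- mv[round(seq(1, nrow(mv), length.out = max_points)), , drop = FALSE]
  fv <- fixed$vertices

  icp_iterations <- function(tf, n_iter) {
    cur <- apply_transform_points(tf, mv)
    rms_trace <- numeric(0)
    best_rms <- Inf
    converged <- FALSE
    for (it in seq_len(n_iter)) {
      nn <- cpp_nearest_vertex(cur, fv)
      rms <- sqrt(mean(nn$distance^2))
      rms_trace <- c(rms_trace, rms)
      if (best_rms - rms < tol && it > 1) {
        converged <- TRUE
        break
      }
      best_rms <- min(best_rms, rms)
      corr <- fv[nn$index, , drop = FALSE]
      mc <- colMeans(cur)
      cc <- colMeans(corr)
      r <- kabsch_rotation(sweep(cur, 2, mc), sweep(corr, 2, cc))
      step <- similarity_transform(r, cc - as.vector(r %*% mc), 1)
      cand <- apply_transform_points(step, cur)
      nn2 <- cpp_nearest_vertex(cand, fv)
      if (sqrt(mean(nn2$distance^2)) > rms + 1e-12) break  # keep best
      cur <- cand
      tf <- compose_transforms(step, tf)
    }
    list(tf = tf, rms_trace = rms_trace, converged = converged,
         rms = tail(rms_trace, 1))
  }

  # multi-start: principal-axes candidates (near-degenerate eigenvalues make
  # any single candidate unreliable) plus in-plane rotations about the
  # dominant axis; each start is refined briefly, the best one runs to
  # convergence
  starts <- principal_axes_candidates(mv, fv)
  probes <- lapply(starts, icp_iterations, n_iter = 5)
  best <- probes[[which.min(vapply(probes, `[[`, numeric(1), "rms"))]]
  out <- icp_iterations(best$tf, max_iter)
  tf <- out$tf
  rms_trace <- out$rms_trace
  converged <- out$converged
  if (!converged && max_iter > 0)
    attr(tf, "warning") <- "ICP did not converge within max_iter"
  attr(tf, "rms") <- rms_trace
  attr(tf, "converged") <- converged
  tf
}

mean_mesh_of <- function(meshes, reference) {
  same <- all(vapply(meshes, function(m)
    identical(dim(m$vertices), dim(reference$vertices)), logical(1)))
  if (same) {
    vm <- Reduce(`+`, lapply(meshes, function(m) m$vertices)) /
      length(meshes)
    return(surface_mesh(vm, reference$triangles, reference$vertex_labels))
  }
  # closest-point projected mean on the reference topology
  acc <- matrix(0, n_vertices(reference), 3)
  for (m in meshes) {
    nn <- cpp_nearest_vertex(reference$vertices, m$vertices)
    acc <- acc + m$vertices[nn$index, , drop = FALSE]
  }
  surface_mesh(acc / length(meshes), reference$triangles,
               reference$vertex_labels)
}

#' Generalized Procrustes alignment of a set of meshes
#'
#' Iteratively aligns every mesh to the current mean shape with rigid ICP and
#' recomputes the mean, until the mean stops moving. The mean is the
#' vertexwise mean when all meshes share a topology, otherwise a
#' closest-point projected mean on the first mesh's topology.
#'
#' @param meshes list of >= 2 [surface_mesh()].
#' @param tol stop when the mean-vertex displacement falls below `tol` (mm).
#' @param max_iter outer iteration cap.
#' @return list with `aligned` (meshes), `transforms` (per mesh,
#'   [similarity_transform()] with scale 1), `mean` (mesh), and `objective`
#'   (trace of the summed RMS distances to the mean).
#' @export
generalized_procrustes <- function(meshes, tol = 1e-4, max_iter = 20) {
  if (length(meshes) < 2) stopf("need at least 2 meshes")
  aligned <- meshes
  transforms <- rep(list(similarity_transform()), length(meshes))
  mean_mesh <- mean_mesh_of(aligned, meshes[[1]])
  objective <- numeric(0)
  for (it in seq_len(max_iter)) {
    total <- 0
    for (i in seq_along(aligned)) {
      tf <- icp_rigid(aligned[[i]], mean_mesh)
      aligned[[i]] <- apply_transform_mesh(tf, aligned[[i]])
      transforms[[i]] <- compose_transforms(tf, transforms[[i]])
      rms <- attr(tf, "rms")
      total <- total + tail(rms, 1)
    }
    objective <- c(objective, total)
    new_mean <- mean_mesh_of(aligned, mean_mesh)
    shift <- mean(sqrt(rowSums((new_mean$vertices -
                                  mean_mesh$vertices)^2)))
    mean_mesh <- new_mean
    if (shift < tol) break
  }
  list(aligned = aligned, transforms = transforms, mean = mean_mesh,
       objective = objective)
}
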