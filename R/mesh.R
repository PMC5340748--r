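#' Triangulated surface mesh
#'
#' The unit of all shape computation in the package: vertex coordinates in
#' millimetres, a triangle index matrix, and an optional per-vertex label
#' channel (`"endo"`, `"epi"`, `"base"`) used to identify the endocardial
#' sheet, the epicardial sheet and the basal cap of a ventricular wall mesh.
#'
#' The orientation convention throughout the package is outward normals with
#' counter-clockwise winding viewed from outside, so that the divergence
#' theorem gives a positive enclosed volume.
#'
#' @param vertices numeric N x 3 matrix of vertex positions (mm).
#' @param triangles integer M x 3 matrix of 1-based vertex indices.
#' @param vertex_labels optional character vector of length N.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, vertex_labels = NULL) {
  vertices <- as_num_matrix(vertices, 3, "vertices")
  dimnames(vertices) <- NULL
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(triangles) <- NULL
  if (ncol(triangles) != 3) stopf("triangles must have 3 columns")
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1 || max(triangles) > nrow(vertices)))
    stopf("triangle indices out of range [1, %d]", nrow(vertices))
  if (!is.null(vertex_labels)) {
    vertex_labels <- as.character(vertex_labels)
    if (length(vertex_labels) != nrow(vertices))
      stopf("vertex_labels must have one entry per vertex")
  }
  structure(list(vertices = vertices, triangles = triangles,
                 vertex_labels = vertex_labels),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles%s\n",
              nrow(x$vertices), nrow(x$triangles),
              if (!is.null(x$vertex_labels)) ", labelled" else ""))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)
n_triangles <- function(mesh) nrow(mesh$triangles)

#' Test whether a mesh is closed and consistently oriented
#'
#' A mesh is closed and oriented when every undirected edge is shared by
#' exactly two triangles, once in each direction.
#'
#' @param mesh a [surface_mesh()].
#' @return logical scalar.
#' @export
is_closed_mesh <- function(mesh) {
  tr <- mesh$triangles
  if (nrow(tr) == 0) return(FALSE)
  nv <- as.double(n_vertices(mesh))
  from <- c(tr[, 1], tr[, 2], tr[, 3])
  to <- c(tr[, 2], tr[, 3], tr[, 1])
  directed <- (from - 1) * nv + (to - 1)
  if (anyDuplicated(directed) > 0) return(FALSE)
  reversed <- (to - 1) * nv + (from - 1)
  all(directed %in% reversed)
}

#' Triangle centers and area-weighted normals
#'
#' @param mesh a [surface_mesh()].
#' @return list with `centers` (M x 3), `normals` (M x 3, area-weighted,
#'   i.e. |n| equals the triangle area), and `areas`.
#' @export
triangle_geometry <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  p0 <- v[tr[, 1], , drop = FALSE]
  p1 <- v[tr[, 2], , drop = FALSE]
  p2 <- v[tr[, 3], , drop = FALSE]
  centers <- (p0 + p1 + p2) / 3
  e1 <- p1 - p0
  e2 <- p2 - p0
  normals <- 0.5 * cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                         e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                         e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  list(centers = centers, normals = normals,
       areas = sqrt(rowSums(normals^2)))
}

signed_mesh_volume <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  p0 <- v[tr[, 1], , drop = FALSE]
  p1 <- v[tr[, 2], , drop = FALSE]
  p2 <- v[tr[, 3], , drop = FALSE]
  sum(p0[, 1] * (p1[, 2] * p2[, 3] - p1[, 3] * p2[, 2]) -
      p0[, 2] * (p1[, 1] * p2[, 3] - p1[, 3] * p2[, 1]) +
      p0[, 3] * (p1[, 1] * p2[, 2] - p1[, 2] * p2[, 1])) / 6
}

#' Volume enclosed by a closed oriented surface
#'
#' Divergence-theorem volume, `(1/6) * sum_t det(v0, v1, v2)`. Positive for
#' outward-oriented surfaces; an inward orientation raises an error rather
#' than silently returning a negative volume.
#'
#' @param mesh a closed, outward-oriented [surface_mesh()].
#' @return enclosed volume in mm^3.
#' @export
enclosed_volume <- function(mesh) {
  if (!is_closed_mesh(mesh)) stopf("enclosed_volume requires a closed mesh")
  v <- signed_mesh_volume(mesh)
  if (v < 0)
    stopf("mesh is inward-oriented (signed volume %.3g); flip triangles", v)
  v
}

mesh_centroid <- function(mesh) colMeans(mesh$vertices)

#' Minimum distance from each vertex of a mesh to a reference surface
#'
#' Point-to-triangle distances (not merely point-to-vertex), one-directional
#' from `mesh` to `reference`.
#'
#' @param mesh query [surface_mesh()].
#' @param reference reference [surface_mesh()].
#' @return list with `distances` (per vertex of `mesh`), `mean`, `max`.
#' @export
surface_distance <- function(mesh, reference) {
  if (n_triangles(reference) == 0) stopf("reference mesh is empty")
  d <- cpp_point_triangle_dist(mesh$vertices, reference$vertices,
                               reference$triangles - 1L)
  list(distances = d, mean = mean(d), max = max(d))
}

vertex_adjacency <- function(mesh) {
  tr <- mesh$triangles
  i <- c(tr[, 1], tr[, 2], tr[, 2], tr[, 3], tr[, 3], tr[, 1])
  j <- c(tr[, 2], tr[, 1], tr[, 3], tr[, 2], tr[, 1], tr[, 3])
  a <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(n_vertices(mesh), n_vertices(mesh)))
  a@x[] <- 1  # collapse duplicate entries
  a
}

#' Laplacian smoothing with volume-drift correction
#'
#' Iteratively moves each vertex toward the mean of its neighbours, then
#' rescales the mesh about its centroid so the enclosed volume matches the
#' input (Laplacian smoothing shrinks closed surfaces; the correction keeps
#' the drift at zero up to floating point).
#'
#' @param mesh a closed [surface_mesh()].
#' @param iterations number of smoothing sweeps.
#' @param relaxation step toward the neighbour mean in (0, 1].
#' @return smoothed [surface_mesh()].
#' @export
smooth_mesh <- function(mesh, iterations, relaxation = 0.5) {
  if (iterations <= 0) return(mesh)
  v0 <- signed_mesh_volume(mesh)
  a <- vertex_adjacency(mesh)
  deg <- Matrix::rowSums(a)
  deg[deg == 0] <- 1
  v <- mesh$vertices
  for (i in seq_len(iterations)) {
    nb <- as.matrix(a %*% v) / deg
    v <- (1 - relaxation) * v + relaxation * nb
  }
  out <- surface_mesh(v, mesh$triangles, mesh$vertex_labels)
  v1 <- signed_mesh_volume(out)
  if (v0 > 0 && v1 > 0) {
    s <- (v0 / v1)^(1 / 3)
    ctr <- mesh_centroid(out)
    out$vertices <- sweep(sweep(out$vertices, 2, ctr) * s, 2, ctr, `+`)
  }
  out
}

boundary_loops <- function(triangles) {
  from <- c(triangles[, 1], triangles[, 2], triangles[, 3])
  to <- c(triangles[, 2], triangles[, 3], triangles[, 1])
  nv <- max(triangles)
  key <- paste(pmin(from, to), pmax(from, to))
  cnt <- table(key)
  bnd <- which(cnt[key] == 1)
  if (length(bnd) == 0) return(list())
  nxt <- integer(nv)
  nxt[from[bnd]] <- to[bnd]
  starts <- from[bnd]
  seen <- logical(nv)
  loops <- list()
  for (s in starts) {
    if (seen[s]) next
    loop <- s
    cur <- nxt[s]
    while (cur != s && cur != 0 && !seen[cur]) {
      seen[cur] <- TRUE
      loop <- c(loop, cur)
      cur <- nxt[cur]
    }
    seen[s] <- TRUE
    if (cur == s && length(loop) >= 3) loops[[length(loops) + 1]] <- loop
  }
  loops
}

# Closed, outward-oriented surface from the triangles whose vertices all
# satisfy 'vertex_mask': boundary loops are capped by a fan to the loop
# centroid, and the global orientation flipped if the signed volume is
# negative.
close_surface_subset <- function(mesh, vertex_mask, cap_label = "base") {
  keep_tri <- matrix(vertex_mask[mesh$triangles], ncol = 3)
  tri <- mesh$triangles[rowSums(keep_tri) == 3, , drop = FALSE]
  if (nrow(tri) == 0) stopf("no triangles in the requested vertex subset")
  used <- sort(unique(as.vector(tri)))
  remap <- integer(n_vertices(mesh))
  remap[used] <- seq_along(used)
  verts <- mesh$vertices[used, , drop = FALSE]
  has_labels <- !is.null(mesh$vertex_labels)
  labels <- if (has_labels) mesh$vertex_labels[used] else NULL
  tri <- matrix(remap[tri], ncol = 3)
  loops <- boundary_loops(tri)
  for (loop in loops) {
    ctr <- colMeans(verts[loop, , drop = FALSE])
    verts <- rbind(verts, ctr)
    if (has_labels) labels <- c(labels, cap_label)
    ci <- nrow(verts)
    nb <- c(loop[-1], loop[1])
    # boundary edge a->b appears once; cap triangle (b, a, ctr) keeps the
    # winding globally consistent
    tri <- rbind(tri, cbind(nb, loop, ci))
  }
  out <- surface_mesh(verts, tri, labels)
  if (signed_mesh_volume(out) < 0) out$triangles <- out$triangles[, c(1, 3, 2)]
  out
}

#' Decimate a mesh by vertex clustering
#'
#' Snaps vertices to a regular grid of the given cell size, merges vertices in
#' the same cell (averaging positions), and drops collapsed triangles. Used to
#' bring marching-tetrahedra meshes down to atlas-friendly sizes; the result
#' is not guaranteed manifold and is intended for the correspondence-free
#' currents data term.
#'
#' @param mesh a [surface_mesh()].
#' @param cell_mm clustering cell edge length (mm).
#' @return decimated [surface_mesh()].
#' @export
decimate_mesh <- function(mesh, cell_mm) {
  if (cell_mm <= 0) stopf("cell_mm must be positive")
  v <- mesh$vertices
  key <- apply(floor(sweep(v, 2, apply(v, 2, min)) / cell_mm), 1, paste,
               collapse = ",")
  grp <- match(key, unique(key))
  nv <- max(grp)
  newv <- matrix(0, nv, 3)
  for (q in 1:3) newv[, q] <- tapply(v[, q], grp, mean)
  tr <- matrix(grp[mesh$triangles], ncol = 3)
  keep <- tr[, 1] != tr[, 2] & tr[, 2] != tr[, 3] & tr[, 1] != tr[, 3]
  tr <- tr[keep, , drop = FALSE]
  labels <- NULL
  if (!is.null(mesh$vertex_labels)) {
    labels <- vapply(split(mesh$vertex_labels, grp), function(l)
      names(sort(table(l), decreasing = TRUE))[1], character(1))
    labels <- as.character(labels[order(as.integer(names(labels)))])
  }
  surface_mesh(newv, tr, labels)
}
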