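# On-disk mesh formats: VTK legacy ASCII polydata and PLY (read+write),
# ASCII STL (read). Vertex labels survive VTK and PLY round trips as an
# integer point-data channel with a name dictionary.

label_codes <- c(endo = 1L, epi = 2L, base = 3L)

encode_labels <- function(labels) {
  codes <- label_codes[labels]
  codes[is.na(codes)] <- 0L
  as.integer(codes)
}

decode_labels <- function(codes) {
  nm <- names(label_codes)[match(codes, label_codes)]
  nm[is.na(nm)] <- "none"
  nm
}

#' Write a surface mesh to disk
#'
#' Format chosen by extension: `.vtk` (legacy ASCII polydata) or `.ply`
#' (ASCII). Coordinates are serialized with 17 significant digits so that
#' write-then-read round-trips are exact in double precision.
#'
#' @param mesh a [surface_mesh()].
#' @param path output file path ending in `.vtk` or `.ply`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         vtk = write_mesh_vtk(mesh, path),
         ply = write_mesh_ply(mesh, path),
         stopf("unsupported mesh format '.%s' for writing (use .vtk or .ply)",
               ext))
  invisible(path)
}

#' Read a surface mesh from disk
#'
#' Supports legacy ASCII VTK polydata, ASCII PLY, and ASCII STL. STL has no
#' shared vertex indexing, so vertices are deduplicated with a 1e-6 mm
#' tolerance on read. Non-triangular cells raise an error.
#'
#' @param path file path ending in `.vtk`, `.ply` or `.stl`.
#' @return a [surface_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stopf("mesh file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         vtk = read_mesh_vtk(path),
         ply = read_mesh_ply(path),
         stl = read_mesh_stl(path),
         stopf("unsupported mesh format '.%s' (use .vtk, .ply or .stl)", ext))
}

fmt_num <- function(x) sprintf("%.17g", x)

write_mesh_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- n_vertices(mesh)
  nt <- n_triangles(mesh)
  writeLines(c("# vtk DataFile Version 3.0", "lvssa surface mesh", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", nv)), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(fmt_num(r), collapse = " ")), con)
  writeLines(sprintf("POLYGONS %d %d", nt, 4 * nt), con)
  writeLines(paste(3L, mesh$triangles[, 1] - 1L, mesh$triangles[, 2] - 1L,
                   mesh$triangles[, 3] - 1L), con)
  if (!is.null(mesh$vertex_labels)) {
    writeLines(c(sprintf("POINT_DATA %d", nv), "SCALARS vertex_label int 1",
                 "LOOKUP_TABLE default"), con)
    writeLines(as.character(encode_labels(mesh$vertex_labels)), con)
  }
  path
}

read_mesh_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  toks <- function(s) strsplit(trimws(s), "\\s+")[[1]]
  ip <- grep("^POINTS", lines)[1]
  if (is.na(ip)) stopf("no POINTS section in %s", path)
  nv <- as.integer(toks(lines[ip])[2])
  # points may wrap across lines: take the first 3*nv numbers after POINTS
  acc <- numeric(0)
  li <- ip + 1
  while (length(acc) < 3 * nv) {
    acc <- c(acc, as.numeric(toks(lines[li])))
    li <- li + 1
  }
  verts <- matrix(acc[1:(3 * nv)], ncol = 3, byrow = TRUE)
  it <- grep("^POLYGONS", lines)[1]
  if (is.na(it)) stopf("no POLYGONS section in %s", path)
  hdr <- toks(lines[it])
  nt <- as.integer(hdr[2])
  acc <- integer(0)
  li <- it + 1
  while (length(acc) < as.integer(hdr[3])) {
    acc <- c(acc, as.integer(toks(lines[li])))
    li <- li + 1
  }
  counts <- acc[seq(1, length(acc), by = 4)]
  if (any(counts != 3L)) stopf("non-triangular cells in %s", path)
  tris <- matrix(acc, ncol = 4, byrow = TRUE)[, 2:4, drop = FALSE] + 1L
  labels <- NULL
  il <- grep("^SCALARS vertex_label", lines)[1]
  if (!is.na(il)) {
    codes <- integer(0)
    li <- il + 2
    while (length(codes) < nv && li <= length(lines)) {
      codes <- c(codes, as.integer(toks(lines[li])))
      li <- li + 1
    }
    labels <- decode_labels(codes)
  }
  surface_mesh(verts, tris, labels)
}

write_mesh_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- n_vertices(mesh)
  nt <- n_triangles(mesh)
  has_lab <- !is.null(mesh$vertex_labels)
  hdr <- c("ply", "format ascii 1.0", "comment lvssa surface mesh",
           sprintf("element vertex %d", nv),
           "property double x", "property double y", "property double z")
  if (has_lab) hdr <- c(hdr, "property int label")
  hdr <- c(hdr, sprintf("element face %d", nt),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  vl <- apply(mesh$vertices, 1, function(r) paste(fmt_num(r), collapse = " "))
  if (has_lab) vl <- paste(vl, encode_labels(mesh$vertex_labels))
  writeLines(vl, con)
  writeLines(paste(3L, mesh$triangles[, 1] - 1L, mesh$triangles[, 2] - 1L,
                   mesh$triangles[, 3] - 1L), con)
  path
}

read_mesh_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end <- grep("^end_header", lines)[1]
  if (is.na(end)) stopf("not a PLY file: %s", path)
  hdr <- lines[1:end]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex",
                                                   hdr, value = TRUE)[1]))
  nt <- as.integer(sub("element face ", "", grep("^element face",
                                                 hdr, value = TRUE)[1]))
  vprops <- sub("^property ", "",
                grep("^property (double|float|int|uchar) ",
                     hdr[seq_len(grep("^element face", hdr)[1])],
                     value = TRUE))
  has_lab <- any(grepl(" label$", vprops))
  vl <- lines[(end + 1):(end + nv)]
  vm <- matrix(as.numeric(unlist(strsplit(trimws(vl), "\\s+"))),
               nrow = nv, byrow = TRUE)
  verts <- vm[, 1:3, drop = FALSE]
  labels <- if (has_lab) decode_labels(as.integer(vm[, 4])) else NULL
  fl <- lines[(end + nv + 1):(end + nv + nt)]
  fm <- matrix(as.integer(unlist(strsplit(trimws(fl), "\\s+"))),
               nrow = nt, byrow = TRUE)
  if (any(fm[, 1] != 3L)) stopf("non-triangular cells in %s", path)
  surface_mesh(verts, fm[, 2:4, drop = FALSE] + 1L, labels)
}

read_mesh_stl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^\\s*solid", lines[1])))
    stopf("only ASCII STL is supported: %s", path)
  vlines <- grep("^\\s*vertex", lines, value = TRUE)
  nums <- as.numeric(unlist(lapply(strsplit(trimws(vlines), "\\s+"),
                                   function(t) t[2:4])))
  raw <- matrix(nums, ncol = 3, byrow = TRUE)
  if (nrow(raw) %% 3 != 0) stopf("malformed STL facet list in %s", path)
  # deduplicate with 1e-6 mm tolerance
  key <- apply(round(raw / 1e-6), 1, paste, collapse = ",")
  grp <- match(key, unique(key))
  nv <- max(grp)
  verts <- matrix(0, nv, 3)
  for (q in 1:3) verts[, q] <- tapply(raw[, q], grp, mean)
  tris <- matrix(grp, ncol = 3, byrow = TRUE)
  surface_mesh(verts, tris)
}
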