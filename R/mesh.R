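#' Tetrahedral mesh with per-cell tissue labels
#'
#' Light container for a labelled tetrahedral mesh: vertex coordinates in
#' metres, 4-column connectivity (1-based), a tissue label per tetrahedron,
#' and per-tetrahedron barycentres and volumes (computed on construction).
#'
#' @param vertices Numeric matrix, n x 3, coordinates in metres.
#' @param tets Integer matrix, m x 4, vertex indices (1-based).
#' @param tissue_label Character vector of length m.
#' @return An object of class `tet_mesh` with elements `vertices`, `tets`,
#'   `tissue_label`, `barycentres` (m x 3) and `volumes` (length m, m^3).
#' @export
tet_mesh <- function(vertices, tets, tissue_label) {
  vertices <- as.matrix(vertices)
  tets <- matrix(as.integer(as.matrix(tets)), ncol = 4)
  stopifnot(ncol(vertices) == 3, nrow(tets) == length(tissue_label),
            all(tets >= 1L), all(tets <= nrow(vertices)))
  geom <- mesh_geometry(vertices, tets)
  if (any(geom$volumes <= 0)) {
    abort("mesh contains degenerate (zero-volume) tetrahedra")
  }
  structure(
    list(vertices = vertices, tets = tets,
         tissue_label = as.character(tissue_label),
         barycentres = geom$barycentres, volumes = geom$volumes),
    class = "tet_mesh"
  )
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("<tet_mesh> ", nrow(x$tets), " tets, ", nrow(x$vertices), " vertices, ",
      "volume ", format(sum(x$volumes) * 1e6, digits = 4), " cm^3\n", sep = "")
  tab <- sort(table(x$tissue_label), decreasing = TRUE)
  cat("  tissues:", paste0(names(tab), " (", tab, ")", collapse = ", "), "\n")
  invisible(x)
}

## vectorized barycentre + volume for all tets
mesh_geometry <- function(vertices, tets) {
  a <- vertices[tets[, 1], , drop = FALSE]
  b <- vertices[tets[, 2], , drop = FALSE]
  c_ <- vertices[tets[, 3], , drop = FALSE]
  d <- vertices[tets[, 4], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a; e3 <- d - a
  det <- e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
         e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
         e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
  list(barycentres = (a + b + c_ + d) / 4, volumes = abs(det) / 6)
}

#' Barycentre and volume of a single tetrahedron
#'
#' The volume is |det of the edge matrix| / 6 and the barycentre the mean of
#' the four vertices.
#'
#' @param verts Numeric 4 x 3 matrix of vertex coordinates (m).
#' @return List with `barycentre` (length-3 numeric) and `volume` (m^3).
#' @examples
#' tet_geometry(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
#' @export
tet_geometry <- function(verts) {
  verts <- as.matrix(verts)
  stopifnot(nrow(verts) == 4, ncol(verts) == 3)
  g <- mesh_geometry(verts, matrix(1:4, nrow = 1))
  if (g$volumes <= 0) {
    abort("degenerate tetrahedron: the four points are coplanar (zero volume)")
  }
  list(barycentre = as.numeric(g$barycentres), volume = g$volumes)
}

tissue_ids <- function(labels, tissues) {
  id <- match(labels, tissues$name)
  if (anyNA(id)) {
    abort(paste0("tissue label(s) not in tissue table: ",
                 paste(unique(labels[is.na(id)]), collapse = ", ")))
  }
  id
}

#' Write / read a labelled tetrahedral mesh
#'
#' Supported plain-text formats: Gmsh MSH v2.2 ASCII (tissue as the physical
#' tag of each element) and legacy VTK unstructured grid (tissue as integer
#' cell data named `tissue`). Labels are encoded as the row index of the
#' tissue in `tissues`; a write followed by a read with the same table
#' reproduces vertices, connectivity and labels exactly.
#'
#' @param mesh A [tet_mesh()].
#' @param path Output/input file path.
#' @param format `"msh"` or `"vtk"`; default guessed from the file extension.
#' @param tissues Tissue table used to encode/decode integer labels.
#' @return `write_mesh()` returns `path` invisibly; `read_mesh()` a
#'   [tet_mesh()].
#' @export
write_mesh <- function(mesh, path, format = NULL, tissues = tissue_table()) {
  stopifnot(inherits(mesh, "tet_mesh"))
  format <- format %||% guess_mesh_format(path)
  ids <- tissue_ids(mesh$tissue_label, tissues)
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); nt <- nrow(mesh$tets)
  coords <- apply(mesh$vertices, 1, function(v) paste(sprintf("%.17g", v), collapse = " "))
  if (format == "msh") {
    writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes", nv), con)
    writeLines(paste(seq_len(nv), coords), con)
    writeLines(c("$EndNodes", "$Elements", nt), con)
    writeLines(paste(seq_len(nt), 4, 2, ids, 0,
                     mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3], mesh$tets[, 4]), con)
    writeLines("$EndElements", con)
  } else if (format == "vtk") {
    writeLines(c("# vtk DataFile Version 3.0", "mwistroke head mesh", "ASCII",
                 "DATASET UNSTRUCTURED_GRID", paste("POINTS", nv, "double")), con)
    writeLines(coords, con)
    writeLines(paste("CELLS", nt, nt * 5L), con)
    writeLines(paste(4, mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                     mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L), con)
    writeLines(paste("CELL_TYPES", nt), con)
    writeLines(as.character(rep(10L, nt)), con)
    writeLines(c(paste("CELL_DATA", nt), "SCALARS tissue int 1",
                 "LOOKUP_TABLE default"), con)
    writeLines(as.character(ids), con)
  } else {
    abort(paste0("unknown mesh format: ", format))
  }
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path, format = NULL, tissues = tissue_table()) {
  format <- format %||% guess_mesh_format(path)
  lines <- readLines(path)
  if (format == "msh") {
    parsed <- parse_msh2(lines)
  } else if (format == "vtk") {
    parsed <- parse_vtk_legacy(lines)
  } else {
    abort(paste0("unknown mesh format: ", format))
  }
  bad <- parsed$ids < 1L | parsed$ids > nrow(tissues)
  if (any(bad)) {
    abort(paste0("mesh tissue id(s) absent from tissue table: ",
                 paste(unique(parsed$ids[bad]), collapse = ", ")))
  }
  tet_mesh(parsed$vertices, parsed$tets, tissues$name[parsed$ids])
}

guess_mesh_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("msh", "vtk")) ext else
    abort(paste0("cannot guess mesh format from extension '", ext,
                 "'; pass format = \"msh\" or \"vtk\""))
}

scan_fields <- function(lines) {
  con <- textConnection(lines)
  on.exit(close(con))
  scan(con, what = numeric(), quiet = TRUE)
}

parse_msh2 <- function(lines) {
  sec <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) abort(paste0("MSH file: missing $", name, " section"))
    lines[(i0 + 1):(i1 - 1)]
  }
  nodes <- sec("Nodes")
  nv <- as.integer(nodes[1])
  nm <- matrix(scan_fields(nodes[-1]), ncol = 4, byrow = TRUE)
  vertices <- matrix(NA_real_, nv, 3)
  vertices[nm[, 1], ] <- nm[, 2:4]
  elems <- sec("Elements")
  ne <- as.integer(elems[1])
  rows <- strsplit(trimws(elems[1 + seq_len(ne)]), "\\s+")
  tets <- matrix(0L, ne, 4); ids <- integer(ne)
  for (i in seq_len(ne)) {
    f <- as.integer(rows[[i]])
    if (f[2] != 4L) {
      abort(paste0("MSH file contains non-tetrahedral element (type ", f[2],
                   "); only tet meshes are supported"))
    }
    ntags <- f[3]
    if (ntags < 1L) abort("MSH element without tags: no tissue label available")
    ids[i] <- f[4]                       # first (physical) tag = tissue id
    tets[i, ] <- f[(4 + ntags):(7 + ntags)]
  }
  list(vertices = vertices, tets = tets, ids = ids)
}

parse_vtk_legacy <- function(lines) {
  find <- function(kw) {
    i <- grep(paste0("^", kw, "\\b"), lines)
    if (!length(i)) abort(paste0("VTK file: missing ", kw, " section"))
    i[1]
  }
  ip <- find("POINTS")
  nv <- as.integer(strsplit(trimws(lines[ip]), "\\s+")[[1]][2])
  pts <- numeric(0); i <- ip + 1
  while (length(pts) < 3 * nv) {
    pts <- c(pts, scan_fields(lines[i])); i <- i + 1
  }
  vertices <- matrix(pts, ncol = 3, byrow = TRUE)
  ic <- find("CELLS")
  nt <- as.integer(strsplit(trimws(lines[ic]), "\\s+")[[1]][2])
  cell_rows <- strsplit(trimws(lines[ic + seq_len(nt)]), "\\s+")
  tets <- matrix(0L, nt, 4)
  for (k in seq_len(nt)) {
    f <- as.integer(cell_rows[[k]])
    if (f[1] != 4L) abort("VTK file contains a non-tetrahedral cell")
    tets[k, ] <- f[2:5] + 1L
  }
  it <- find("CELL_TYPES")
  types <- integer(0); i <- it + 1
  while (length(types) < nt) {
    types <- c(types, as.integer(scan_fields(lines[i]))); i <- i + 1
  }
  if (any(types != 10L)) abort("VTK file contains non-tetrahedral cell types")
  is_ <- grep("^SCALARS\\s+tissue\\b", lines)
  if (!length(is_)) abort("VTK file: missing 'tissue' cell-data field")
  ids <- integer(0); i <- is_[1] + 2    # skip LOOKUP_TABLE line
  while (length(ids) < nt) {
    ids <- c(ids, as.integer(scan_fields(lines[i]))); i <- i + 1
  }
  list(vertices = vertices, tets = tets, ids = ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
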