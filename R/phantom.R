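#' Default geometry of the synthetic layered head
#'
#' The synthetic head is a set of nested ellipsoidal tissue shells
#' (outside-in: skin, skull, CSF, grey matter, white matter core) plus a
#' cerebellum lobe carved out of the brain at the lower back. Coordinates
#' are head-centred: x = left(-)/right(+), y = back(-)/front(+), z = up,
#' in metres. Semi-axes are full ellipsoid semi-axes; shells must be
#' strictly nested outside-in.
#'
#' @return A list with elements `shells` (ordered outside-in; each a list
#'   with `tissue`, `semi_axes`, `centre`) and `overrides` (regions that
#'   relabel tets of given tissues, used for the cerebellum).
#' @export
head_config <- function() {
  list(
    shells = list(
      list(tissue = "skin",         semi_axes = c(0.075, 0.093, 0.080), centre = c(0, 0, 0)),
      list(tissue = "skull",        semi_axes = c(0.070, 0.088, 0.075), centre = c(0, 0, 0)),
      list(tissue = "csf",          semi_axes = c(0.063, 0.081, 0.068), centre = c(0, 0, 0)),
      list(tissue = "grey_matter",  semi_axes = c(0.060, 0.078, 0.065), centre = c(0, 0, 0)),
      list(tissue = "white_matter", semi_axes = c(0.056, 0.074, 0.061), centre = c(0, 0, 0))
    ),
    overrides = list(
      list(tissue = "cerebellum", semi_axes = c(0.035, 0.025, 0.022),
           centre = c(0, -0.038, -0.030), within = c("grey_matter", "white_matter"))
    )
  )
}

#' Load a phantom geometry configuration from YAML
#'
#' The YAML mirrors [head_config()]: a `shells` list (each entry `tissue`,
#' `semi_axes`, optional `centre`) ordered outside-in, and an optional
#' `overrides` list (each additionally naming the `within` tissues it may
#' relabel). Missing centres default to the origin.
#'
#' @param path YAML file path.
#' @return A configuration list usable by [build_synthetic_head()].
#' @export
load_head_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$shells)) abort("config has no 'shells' entry")
  tidy_shell <- function(s) {
    if (is.null(s$tissue) || is.null(s$semi_axes)) {
      abort("each shell needs 'tissue' and 'semi_axes'")
    }
    s$semi_axes <- as.numeric(s$semi_axes)
    s$centre <- if (is.null(s$centre)) c(0, 0, 0) else as.numeric(s$centre)
    s
  }
  list(shells = lapply(raw$shells, tidy_shell),
       overrides = lapply(raw$overrides %||% list(), tidy_shell))
}

inside_ellipsoid <- function(points, centre, semi_axes) {
  u <- sweep(points, 2, centre)
  u <- sweep(u, 2, semi_axes, "/")
  rowSums(u * u) < 1
}

check_shell <- function(shell) {
  if (any(shell$semi_axes <= 0)) {
    abort(paste0("degenerate shell '", shell$tissue,
                 "': semi-axes must all be positive"))
  }
}

#' Build a synthetic multi-tissue head phantom
#'
#' Tetrahedralizes the nested-shell head of [head_config()] by structured
#' subdivision: a regular grid of cubes with edge `target_edge` covering the
#' outer shell, each cube split into six tetrahedra (Kuhn subdivision, so
#' the mesh is conforming), keeping tetrahedra whose barycentre falls inside
#' the outer shell. Each tetrahedron is labelled with the tissue of the
#' innermost shell containing its barycentre; override regions (the
#' cerebellum lobe) then relabel brain tets they contain. Generation is
#' fully deterministic — there is no randomness in the geometry.
#'
#' @param config Geometry description as returned by [head_config()].
#' @param target_edge Cube edge length in metres (characteristic tet layer
#'   thickness); default 3 mm.
#' @param tissues Tissue dielectric table; every shell tissue must appear.
#' @return A `head_phantom` object: list with `mesh` ([tet_mesh()]),
#'   `tissues` (tibble), `brain_tissues` (character), `config`.
#' @examples
#' ph <- build_synthetic_head(target_edge = 0.009)
#' ph$mesh
#' @export
build_synthetic_head <- function(config = head_config(), target_edge = 0.003,
                                 tissues = tissue_table()) {
  stopifnot(target_edge > 0, length(config$shells) >= 1)
  validate_tissue_table(tissues)
  for (s in config$shells) check_shell(s)
  for (s in config$overrides %||% list()) check_shell(s)
  ## strict outside-in nesting (same-centre shells: semi-axes must shrink)
  if (length(config$shells) > 1) {
    for (i in 2:length(config$shells)) {
      if (!all(config$shells[[i]]$semi_axes < config$shells[[i - 1]]$semi_axes)) {
        abort("shells must be strictly ordered outside-in (semi-axes decreasing)")
      }
    }
  }
  outer <- config$shells[[1]]
  lo <- outer$centre - outer$semi_axes
  hi <- outer$centre + outer$semi_axes
  n <- pmax(1L, ceiling((hi - lo) / target_edge))
  h <- (hi - lo) / n
  grid <- build_cube_tets(lo, h, n)
  bary <- (grid$vertices[grid$tets[, 1], ] + grid$vertices[grid$tets[, 2], ] +
           grid$vertices[grid$tets[, 3], ] + grid$vertices[grid$tets[, 4], ]) / 4
  keep <- inside_ellipsoid(bary, outer$centre, outer$semi_axes)
  tets <- grid$tets[keep, , drop = FALSE]
  bary <- bary[keep, , drop = FALSE]
  label <- rep(outer$tissue, nrow(tets))
  if (length(config$shells) > 1) {
    for (i in 2:length(config$shells)) {
      s <- config$shells[[i]]
      label[inside_ellipsoid(bary, s$centre, s$semi_axes)] <- s$tissue
    }
  }
  for (s in config$overrides %||% list()) {
    inside <- inside_ellipsoid(bary, s$centre, s$semi_axes) & label %in% s$within
    label[inside] <- s$tissue
  }
  ## drop unused vertices, remap connectivity
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nrow(grid$vertices)); remap[used] <- seq_along(used)
  mesh <- tet_mesh(grid$vertices[used, , drop = FALSE],
                   matrix(remap[tets], ncol = 4), label)
  new_head_phantom(mesh, tissues, config)
}

new_head_phantom <- function(mesh, tissues, config = NULL) {
  missing <- setdiff(unique(mesh$tissue_label), tissues$name)
  if (length(missing)) {
    abort(paste0("mesh labels missing from tissue table: ",
                 paste(missing, collapse = ", ")))
  }
  if (!any(mesh$tissue_label %in% brain_tissues())) {
    abort("phantom has an empty brain region")
  }
  structure(list(mesh = mesh, tissues = tissues,
                 brain_tissues = brain_tissues(), config = config),
            class = "head_phantom")
}

#' @export
print.head_phantom <- function(x, ...) {
  cat("<head_phantom>\n")
  print(x$mesh)
  cat("  brain tets:", sum(x$mesh$tissue_label %in% x$brain_tissues), "\n")
  invisible(x)
}

## regular grid of n cubes per axis starting at lo with spacing h,
## each cube split into 6 Kuhn tetrahedra sharing the (0,0,0)-(1,1,1) diagonal
build_cube_tets <- function(lo, h, n) {
  nx <- n[1]; ny <- n[2]; nz <- n[3]
  xs <- lo[1] + h[1] * 0:nx
  ys <- lo[2] + h[2] * 0:ny
  zs <- lo[3] + h[3] * 0:nz
  vertices <- cbind(rep(xs, times = (ny + 1) * (nz + 1)),
                    rep(rep(ys, each = nx + 1), times = nz + 1),
                    rep(zs, each = (nx + 1) * (ny + 1)))
  vid <- function(i, j, k) 1L + i + (nx + 1L) * (j + (ny + 1L) * k)
  ci <- rep(0:(nx - 1L), times = ny * nz)
  cj <- rep(rep(0:(ny - 1L), each = nx), times = nz)
  ck <- rep(0:(nz - 1L), each = nx * ny)
  corner <- function(dx, dy, dz) vid(ci + dx, cj + dy, ck + dz)
  v000 <- corner(0L, 0L, 0L); v100 <- corner(1L, 0L, 0L)
  v010 <- corner(0L, 1L, 0L); v110 <- corner(1L, 1L, 0L)
  v001 <- corner(0L, 0L, 1L); v101 <- corner(1L, 0L, 1L)
  v011 <- corner(0L, 1L, 1L); v111 <- corner(1L, 1L, 1L)
  tets <- rbind(
    cbind(v000, v100, v110, v111),
    cbind(v000, v100, v101, v111),
    cbind(v000, v010, v110, v111),
    cbind(v000, v010, v011, v111),
    cbind(v000, v001, v101, v111),
    cbind(v000, v001, v011, v111)
  )
  list(vertices = vertices, tets = tets)
}

#' Indices of the brain-region tetrahedra of a phantom
#' @param phantom A `head_phantom`.
#' @return Integer vector of tet indices whose label is a brain tissue.
#' @export
brain_tet_indices <- function(phantom) {
  which(phantom$mesh$tissue_label %in% phantom$brain_tissues)
}
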