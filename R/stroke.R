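#' Stroke scenario specification
#'
#' Describes a single stroke: kind (which fixes the dielectric properties),
#' shape, centre and size. Sizes are in metres; `radius` for spheres,
#' `semi_axes` (length 3) for axis-aligned ellipsoids.
#'
#' @param kind `"ischemic"` or `"haemorrhagic"`.
#' @param centre Length-3 centre (m).
#' @param radius Sphere radius (m); mutually exclusive with `semi_axes`.
#' @param semi_axes Length-3 ellipsoid semi-axes (m).
#' @param tissues Tissue table supplying the stroke dielectric properties
#'   (rows `ischemic` / `haemorrhagic`).
#' @return A `stroke_spec` list with `kind`, `shape`, `centre`,
#'   `radius`/`semi_axes`, `properties` (one-row tibble).
#' @export
stroke_spec <- function(kind = c("ischemic", "haemorrhagic"), centre,
                        radius = NULL, semi_axes = NULL,
                        tissues = tissue_table()) {
  kind <- match.arg(kind)
  stopifnot(length(centre) == 3, xor(is.null(radius), is.null(semi_axes)))
  if (!is.null(radius) && radius <= 0) abort("stroke radius must be positive")
  if (!is.null(semi_axes) && (length(semi_axes) != 3 || any(semi_axes <= 0))) {
    abort("stroke semi-axes must be three positive lengths")
  }
  structure(list(kind = kind,
                 shape = if (is.null(radius)) "ellipsoid" else "sphere",
                 centre = as.numeric(centre), radius = radius,
                 semi_axes = semi_axes,
                 properties = tissue_props(tissues, kind)),
            class = "stroke_spec")
}

#' Sample a stroke centre inside the brain
#'
#' Draws a centre uniformly among the barycentres of brain-region
#' tetrahedra (white matter, grey matter, cerebellum).
#'
#' @param phantom A `head_phantom`.
#' @param quadrant Optional restriction to one head quadrant
#'   (`"FL"`, `"FR"`, `"BL"`, `"BR"`).
#' @param origin Head centre used for quadrant assignment.
#' @return Length-3 barycentre (m).
#' @export
sample_centre <- function(phantom, quadrant = NULL, origin = c(0, 0, 0)) {
  idx <- brain_tet_indices(phantom)
  if (!length(idx)) abort("empty brain region")
  if (!is.null(quadrant)) {
    lab <- region_label(phantom$mesh$barycentres[idx, , drop = FALSE], origin)
    idx <- idx[lab == quadrant]
    if (!length(idx)) abort(paste0("no brain tets in quadrant ", quadrant))
  }
  phantom$mesh$barycentres[idx[sample.int(length(idx), 1)], ]
}

#' Quadrant label of head positions
#'
#' Splits the head (horizontal view) into front-left/right and
#' back-left/right by the signs of (x - x0) and (y - y0): positive x is
#' right, positive y is front. Points exactly on an axis go to the
#' right/front side (>= convention).
#'
#' @param points Length-3 vector or n x 3 matrix (m).
#' @param origin Head centre (m).
#' @return Character vector of `"FL"`, `"FR"`, `"BL"`, `"BR"`.
#' @export
region_label <- function(points, origin = c(0, 0, 0)) {
  points <- matrix(points, ncol = 3)
  right <- points[, 1] >= origin[1]
  front <- points[, 2] >= origin[2]
  paste0(ifelse(front, "F", "B"), ifelse(right, "R", "L"))
}

#' Collect the tetrahedra of a stroke, with discard rules
#'
#' Selects every tetrahedron whose barycentre lies within the stroke shape
#' (distance from the centre below the radius for spheres; normalized
#' quadratic form below 1 for ellipsoids). Selected tets outside the brain
#' are discarded; if more than half of the initially selected tets fall
#' outside the brain, the whole case is rejected (`NULL`).
#'
#' @param phantom A `head_phantom`.
#' @param spec A [stroke_spec()].
#' @return Integer vector of tet indices, or `NULL` when the case is
#'   rejected (majority outside the brain, or empty selection).
#' @export
collect_tets <- function(phantom, spec) {
  bary <- phantom$mesh$barycentres
  if (spec$shape == "sphere") {
    d <- sweep(bary, 2, spec$centre)
    sel <- which(rowSums(d * d) < spec$radius^2)
  } else {
    sel <- which(inside_ellipsoid(bary, spec$centre, spec$semi_axes))
  }
  if (!length(sel)) return(NULL)
  in_brain <- phantom$mesh$tissue_label[sel] %in% phantom$brain_tissues
  if (sum(!in_brain) > length(sel) / 2) return(NULL)
  sel[in_brain]
}

#' Dielectric contrast vector of a stroke
#'
#' Per-tet complex contrast dchi_n = (eps_s - eps_b(n)) / eps_b(n) on the
#' collected tet set and 0 elsewhere, with complex permittivities at the
#' working frequency. When per-tet background properties are supplied
#' (heterogeneous models) they define eps_b.
#'
#' @param phantom A `head_phantom`.
#' @param tets Integer tet indices (from [collect_tets()]).
#' @param spec A [stroke_spec()].
#' @param per_tet Optional per-tet property tibble (see [heterogeneity()]).
#' @param sparse Return `list(idx=, values=)` instead of a full vector.
#' @return Complex vector of length N (or its sparse form).
#' @export
build_contrast <- function(phantom, tets, spec, per_tet = NULL, sparse = FALSE) {
  n <- nrow(phantom$mesh$barycentres)
  stopifnot(all(tets >= 1), all(tets <= n))
  eps_b <- permittivity_map(phantom, per_tet)[tets]
  eps_s <- complex_permittivity(spec$properties)
  vals <- (eps_s - eps_b) / eps_b
  if (sparse) return(list(idx = tets, values = vals))
  dchi <- rep(0 + 0i, n)
  dchi[tets] <- vals
  dchi
}
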