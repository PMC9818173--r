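#' Face-adjacency pairs of a tetrahedral mesh
#'
#' Identifies every pair of tetrahedra sharing a triangular face. Computed
#' once per mesh and cached on the phantom by the morphing operations.
#'
#' @param mesh A [tet_mesh()].
#' @return Integer 2-column matrix; each row a pair of tet indices sharing
#'   a face (each unordered pair listed once).
#' @export
face_adjacency <- function(mesh) {
  nt <- nrow(mesh$tets)
  ## 4 faces per tet: drop one vertex each, sort the triple
  drop1 <- mesh$tets[, c(2, 3, 4)]; drop2 <- mesh$tets[, c(1, 3, 4)]
  drop3 <- mesh$tets[, c(1, 2, 4)]; drop4 <- mesh$tets[, c(1, 2, 3)]
  faces <- rbind(drop1, drop2, drop3, drop4)
  faces <- t(apply(faces, 1, sort.int))
  tet_of <- rep(seq_len(nt), times = 4)
  o <- order(faces[, 1], faces[, 2], faces[, 3])
  f <- faces[o, , drop = FALSE]
  same <- which(f[-nrow(f), 1] == f[-1, 1] &
                f[-nrow(f), 2] == f[-1, 2] &
                f[-nrow(f), 3] == f[-1, 3])
  cbind(tet_of[o][same], tet_of[o][same + 1L])
}

phantom_adjacency <- function(phantom) {
  adj <- attr(phantom, "adjacency")
  if (is.null(adj)) adj <- face_adjacency(phantom$mesh)
  adj
}

relabel_phantom <- function(phantom, label) {
  mesh <- phantom$mesh
  mesh$tissue_label <- label
  out <- new_head_phantom(mesh, phantom$tissues, phantom$config)
  attr(out, "adjacency") <- phantom_adjacency(phantom)
  out
}

#' Expand a tissue by whole tetrahedron layers
#'
#' Each iteration assigns the chosen tissue's label to every tetrahedron
#' that shares a face with a tetrahedron of that tissue. Geometry and
#' connectivity are untouched — only labels change — so on a mesh with a
#' characteristic layer thickness of ~3 mm, two iterations move a boundary
#' by ~6 mm.
#'
#' @param phantom A `head_phantom`.
#' @param tissue Tissue label to expand.
#' @param n_layers Number of layers (0 is the identity).
#' @return The morphed `head_phantom`.
#' @export
expand_tissue <- function(phantom, tissue, n_layers) {
  stopifnot(n_layers >= 0)
  label <- phantom$mesh$tissue_label
  if (!tissue %in% label) abort(paste0("tissue '", tissue, "' not in phantom"))
  adj <- phantom_adjacency(phantom)
  for (i in seq_len(n_layers)) {
    inside <- label == tissue
    grow <- c(adj[inside[adj[, 1]] & !inside[adj[, 2]], 2],
              adj[inside[adj[, 2]] & !inside[adj[, 1]], 1])
    label[grow] <- tissue
  }
  relabel_phantom(phantom, label)
}

#' Shrink a tissue by whole tetrahedron layers
#'
#' Reduction is the dual of [expand_tissue()]: each iteration relabels the
#' boundary tetrahedra of the chosen tissue to the tissue of a face
#' neighbour (the most frequent neighbouring tissue of each boundary tet;
#' ties by table order). Fails rather than emptying the tissue.
#'
#' @inheritParams expand_tissue
#' @return The morphed `head_phantom`.
#' @export
shrink_tissue <- function(phantom, tissue, n_layers) {
  stopifnot(n_layers >= 0)
  label <- phantom$mesh$tissue_label
  if (!tissue %in% label) abort(paste0("tissue '", tissue, "' not in phantom"))
  adj <- phantom_adjacency(phantom)
  for (i in seq_len(n_layers)) {
    inside <- label == tissue
    ## boundary tets of `tissue` and the labels of their outside neighbours
    b1 <- inside[adj[, 1]] & !inside[adj[, 2]]
    b2 <- inside[adj[, 2]] & !inside[adj[, 1]]
    btet <- c(adj[b1, 1], adj[b2, 2])
    bnb <- c(label[adj[b1, 2]], label[adj[b2, 1]])
    if (!length(btet)) break
    if (sum(inside) - length(unique(btet)) < 1) {
      abort(paste0("shrinking would empty tissue '", tissue, "'"))
    }
    pick <- tapply(bnb, btet, function(v) names(sort(table(v), decreasing = TRUE))[1])
    label[as.integer(names(pick))] <- as.character(pick)
  }
  relabel_phantom(phantom, label)
}

#' Per-tet dielectric heterogeneity
#'
#' Biological tissues are not perfectly homogeneous: draws, independently
#' for each tetrahedron, permittivity and conductivity uniformly within
#' +/- `var_percent` percent of the tissue's nominal values. With
#' `per_tissue = TRUE` a single offset per tissue is drawn instead.
#'
#' @param phantom A `head_phantom`.
#' @param var_percent Half-width of the variation band, in percent (>= 0).
#' @param per_tissue One offset per tissue instead of per tet.
#' @return Tibble with one row per tet: `name`, `eps_r`, `sigma`,
#'   `frequency` (feedable to [permittivity_map()]).
#' @export
heterogeneity <- function(phantom, var_percent, per_tissue = FALSE) {
  stopifnot(var_percent >= 0)
  lab <- phantom$mesh$tissue_label
  idx <- tissue_ids(lab, phantom$tissues)
  eps0_r <- phantom$tissues$eps_r[idx]
  sig0 <- phantom$tissues$sigma[idx]
  f <- phantom$tissues$frequency[idx]
  v <- var_percent / 100
  n <- length(lab)
  if (per_tissue) {
    tl <- unique(lab)
    fe <- setNames(runif(length(tl), 1 - v, 1 + v), tl)
    fs <- setNames(runif(length(tl), 1 - v, 1 + v), tl)
    tibble::tibble(name = lab, eps_r = eps0_r * fe[lab],
                   sigma = sig0 * fs[lab], frequency = f)
  } else {
    tibble::tibble(name = lab,
                   eps_r = eps0_r * runif(n, 1 - v, 1 + v),
                   sigma = sig0 * runif(n, 1 - v, 1 + v),
                   frequency = f)
  }
}

#' Default boundary-morphing recipes
#'
#' Five two-layer boundary moves spanning the main tissue interfaces:
#' expand grey matter, CSF, skull, white matter and cerebellum. Expansions
#' are used throughout because the thin shell tissues (grey matter, CSF)
#' are only one or two cells thick and a two-layer shrink would consume
#' them.
#' @return List of recipes (`op`, `tissue`, `n_layers`).
#' @export
morph_recipes <- function() {
  list(
    list(op = "expand", tissue = "grey_matter",  n_layers = 2),
    list(op = "expand", tissue = "cerebellum",   n_layers = 2),
    list(op = "expand", tissue = "csf",          n_layers = 2),
    list(op = "expand", tissue = "skull",        n_layers = 2),
    list(op = "expand", tissue = "white_matter", n_layers = 2)
  )
}

apply_recipe <- function(phantom, recipe) {
  switch(recipe$op,
         identity = phantom,
         expand = expand_tissue(phantom, recipe$tissue, recipe$n_layers),
         shrink = shrink_tissue(phantom, recipe$tissue, recipe$n_layers),
         abort(paste0("unknown morph op: ", recipe$op)))
}

#' Family of background head models
#'
#' Crosses `n_shapes` boundary-morphed phantoms (two-layer moves from
#' [morph_recipes()]) with the per-tissue heterogeneity settings in `vars`
#' (percent), yielding `n_shapes * length(vars)` background models. All
#' models share the mesh geometry and connectivity; only labels and per-tet
#' properties differ. The degenerate call `n_shapes = 1, vars = 0` returns
#' the original phantom alone.
#'
#' @param phantom The nominal `head_phantom`.
#' @param n_shapes Number of boundary-morph recipes to use.
#' @param vars Heterogeneity percentages (0 = nominal homogeneous tissues).
#' @param recipes Morph recipe list (default [morph_recipes()]).
#' @return List of models, each a list with `id`, `recipe`, `var`,
#'   `phantom`, `per_tet` (NULL when var = 0).
#' @export
model_family <- function(phantom, n_shapes = 5, vars = c(0.3, 5.0),
                         recipes = morph_recipes()) {
  stopifnot(n_shapes >= 1)
  if (n_shapes == 1 && all(vars == 0)) {
    return(list(list(id = 1L, recipe = list(op = "identity"), var = 0,
                     phantom = phantom, per_tet = NULL)))
  }
  if (n_shapes > length(recipes)) abort("not enough morph recipes for n_shapes")
  morphed <- lapply(recipes[seq_len(n_shapes)], apply_recipe, phantom = phantom)
  out <- list(); id <- 0L
  for (i in seq_len(n_shapes)) {
    for (v in vars) {
      id <- id + 1L
      out[[id]] <- list(
        id = id, recipe = recipes[[i]], var = v, phantom = morphed[[i]],
        per_tet = if (v > 0) heterogeneity(morphed[[i]], v) else NULL
      )
    }
  }
  out
}

#' Background S-parameters of a morphed/heterogeneous model
#'
#' A non-nominal head model is itself a weak perturbation of the nominal
#' background, so its background scattering matrix is obtained through the
#' same linearized operator: S_b(model) = S_b(nominal) + S chi_model, where
#' chi_model is the per-tet contrast of the model's permittivity map
#' relative to the nominal one.
#'
#' @param op Scattering operator assembled on the nominal phantom.
#' @param phantom The nominal phantom.
#' @param model One element of [model_family()].
#' @param Sb_nominal Nominal background [sparams()].
#' @return Background-role [sparams()].
#' @export
model_background <- function(op, phantom, model, Sb_nominal) {
  eps_nom <- permittivity_map(phantom)
  eps_mod <- permittivity_map(model$phantom, model$per_tet)
  chi <- (eps_mod - eps_nom) / eps_nom
  dS <- forward(op, chi)
  sparams(unclass(Sb_nominal) + unclass(dS), role = "background")
}
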