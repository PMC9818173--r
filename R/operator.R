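#' Assemble the discretized linearized scattering operator
#'
#' Builds the M x N complex matrix S of the distorted-Born linearized map
#' from per-tetrahedron dielectric contrast to differential S-parameters,
#' with M = Ma^2 antenna pairs and N tetrahedra. Each entry is
#' S_mn = K_mn (E_p(r_n) . E_q(r_n)) dV_n, with the unconjugated dot
#' product of the background fields of the pair (p,q) mapped to row m, and
#' K_mn = -j omega eps_b(r_n) / (2 a_p a_q), where eps_b is the absolute
#' complex background permittivity (eps0 times the relative value; set
#' `relative_eps = TRUE` to use the relative value instead).
#'
#' @param mesh A [tet_mesh()] with N tets.
#' @param eps_b Per-tet complex relative background permittivity (length N),
#'   e.g. from [permittivity_map()].
#' @param array An [antenna_array()].
#' @param fields A [field_set()] over the same mesh and array.
#' @param relative_eps Use relative instead of absolute permittivity in K.
#' @return A `scattering_operator`: list with `S` (M x N complex),
#'   `index_map` (tibble m, p, q), `Ma`, `n_tets`, `frequency`.
#' @export
assemble_operator <- function(mesh, eps_b, array, fields,
                              relative_eps = FALSE) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(array, "antenna_array"),
            inherits(fields, "field_set"))
  n <- nrow(mesh$barycentres)
  if (length(eps_b) != n) abort("eps_b length does not match the mesh")
  if (fields$n != n || fields$Ma != array$Ma) {
    abort("field set is not indexed consistently with the mesh and array")
  }
  if (any(Re(eps_b) < 1) || any(Im(eps_b) > 1e-12)) {
    abort("background permittivity must have Re >= 1 and Im <= 0")
  }
  omega <- 2 * pi * fields$frequency
  scale <- if (relative_eps) 1 else EPS0
  base <- -1i * omega * (scale * as.complex(eps_b)) / 2 * mesh$volumes
  Ma <- array$Ma
  imap <- operator_index_map(Ma)
  S <- matrix(0 + 0i, Ma * Ma, n)
  for (m in seq_len(Ma * Ma)) {
    p <- imap$p[m]; q <- imap$q[m]
    Ep <- fields$E[[p]]; Eq <- fields$E[[q]]
    dot <- Ep[, 1] * Eq[, 1] + Ep[, 2] * Eq[, 2] + Ep[, 3] * Eq[, 3]
    S[m, ] <- base * dot / (array$power_waves[p] * array$power_waves[q])
  }
  structure(list(S = S, index_map = imap, Ma = Ma, n_tets = n,
                 frequency = fields$frequency),
            class = "scattering_operator")
}

#' Row index map of the scattering operator
#'
#' Row m corresponds to the ordered antenna pair (p, q) with
#' m = (p - 1) Ma + q.
#' @param Ma Antenna count.
#' @return Tibble with columns `m`, `p`, `q`.
#' @export
operator_index_map <- function(Ma) {
  tibble::tibble(m = seq_len(Ma * Ma),
                 p = rep(seq_len(Ma), each = Ma),
                 q = rep(seq_len(Ma), times = Ma))
}

#' @export
print.scattering_operator <- function(x, ...) {
  cat("<scattering_operator> ", nrow(x$S), " x ", x$n_tets,
      " (Ma = ", x$Ma, ", f = ", x$frequency / 1e9, " GHz)\n", sep = "")
  invisible(x)
}

#' Per-tet complex background permittivity of a phantom
#'
#' Maps each tetrahedron's tissue label to its complex relative
#' permittivity at the working frequency. Per-tet property tables (from
#' [heterogeneity()]) may be supplied instead of the shared tissue table.
#'
#' @param phantom A `head_phantom`.
#' @param per_tet Optional tibble with per-tet `eps_r`, `sigma`, `frequency`
#'   rows (one per tet, e.g. from [heterogeneity()]).
#' @return Complex vector, one entry per tetrahedron.
#' @export
permittivity_map <- function(phantom, per_tet = NULL) {
  if (!is.null(per_tet)) {
    stopifnot(nrow(per_tet) == nrow(phantom$mesh$barycentres))
    return(complex_permittivity(per_tet))
  }
  eps <- complex_permittivity(phantom$tissues)
  eps[tissue_ids(phantom$mesh$tissue_label, phantom$tissues)]
}

vec_to_smatrix <- function(v, Ma) matrix(v, Ma, Ma, byrow = TRUE)

#' Linear forward map: contrast to differential S-parameters
#'
#' Computes dS = S dchi exactly (plain matrix-vector product, no
#' thresholding) and reshapes the M-vector to an Ma x Ma differential
#' S-parameter matrix via the operator's index map.
#'
#' @param op A [assemble_operator()] result.
#' @param dchi Complex contrast vector of length N, or a sparse
#'   representation `list(idx =, values =)`.
#' @return Differential-role [sparams()].
#' @export
forward <- function(op, dchi) {
  stopifnot(inherits(op, "scattering_operator"))
  if (is.list(dchi)) {
    if (length(dchi$idx) != length(dchi$values)) abort("bad sparse contrast")
    v <- if (length(dchi$idx)) {
      as.vector(op$S[, dchi$idx, drop = FALSE] %*% dchi$values)
    } else {
      rep(0 + 0i, nrow(op$S))
    }
  } else {
    if (length(dchi) != op$n_tets) {
      abort(paste0("contrast length ", length(dchi),
                   " does not match operator N = ", op$n_tets))
    }
    v <- as.vector(op$S %*% dchi)
  }
  sparams(vec_to_smatrix(v, op$Ma), role = "differential")
}

#' Synthetic background S-parameters of the antenna array
#'
#' Model background (healthy-reference) scattering matrix: off-diagonal
#' entries are the scalar Green's function between antenna positions,
#' coupling * exp(-j k d) / (4 pi d), with the wavenumber of the coupling
#' medium (per-pair mean when `eps_c` is per-antenna), and the diagonal a
#' fixed reflection coefficient. Reciprocal (symmetric) by construction.
#'
#' @param array An [antenna_array()].
#' @param eps_c Coupling-medium complex relative permittivity, scalar or
#'   per-antenna.
#' @param frequency Frequency (Hz).
#' @param coupling Coupling constant scaling the Green's function.
#' @param reflection Complex diagonal reflection coefficient.
#' @return Background-role [sparams()].
#' @export
background_sparams <- function(array, eps_c = 18.42 - 0.9i, frequency = 1e9,
                               coupling = 0.02, reflection = 0.3 + 0i) {
  stopifnot(inherits(array, "antenna_array"))
  Ma <- array$Ma
  pos <- array$positions
  d <- as.matrix(stats::dist(pos))
  if (any(d[upper.tri(d)] == 0)) abort("coincident antenna positions")
  eps_ant <- rep_len(as.complex(eps_c), Ma)
  eps_pair <- (matrix(eps_ant, Ma, Ma) + matrix(eps_ant, Ma, Ma, byrow = TRUE)) / 2
  k <- matrix(wavenumber(as.vector(eps_pair), frequency), Ma, Ma)
  S <- coupling * exp(-1i * k * d) / (4 * pi * d)
  diag(S) <- reflection
  sparams(S, role = "background")
}

#' Persist / load a scattering operator (plain text)
#'
#' The operator is stored as a directory holding `meta.json` (Ma, N,
#' frequency) and `s_re.csv` / `s_im.csv` (M x N real matrices, no
#' headers).
#'
#' @param op A scattering operator.
#' @param dir Directory path (created if needed).
#' @return `write_operator()` returns `dir` invisibly; `read_operator()`
#'   the operator.
#' @export
write_operator <- function(op, dir) {
  stopifnot(inherits(op, "scattering_operator"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(Ma = op$Ma, n_tets = op$n_tets,
                            frequency = op$frequency),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  utils::write.table(Re(op$S), file.path(dir, "s_re.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(Im(op$S), file.path(dir, "s_im.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname write_operator
#' @export
read_operator <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  re <- as.matrix(read.csv(file.path(dir, "s_re.csv"), header = FALSE))
  im <- as.matrix(read.csv(file.path(dir, "s_im.csv"), header = FALSE))
  S <- matrix(complex(real = re, imaginary = im), nrow(re), ncol(re))
  structure(list(S = S, index_map = operator_index_map(meta$Ma),
                 Ma = meta$Ma, n_tets = meta$n_tets, frequency = meta$frequency),
            class = "scattering_operator")
}
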