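#' Complex wavenumber in a homogeneous medium
#'
#' k = omega * sqrt(mu0 eps0 eps_c) with the branch chosen so Im(k) <= 0:
#' under the exp(+j omega t) convention fields go as exp(-j k r) and decay
#' in a lossy medium.
#'
#' @param eps_c Complex relative permittivity (imaginary part <= 0).
#' @param frequency Frequency in Hz.
#' @return Complex wavenumber (rad/m).
#' @export
wavenumber <- function(eps_c, frequency) {
  k <- 2 * pi * frequency * sqrt(MU0 * EPS0) * sqrt(as.complex(eps_c))
  ifelse(Im(k) > 0, -k, k)
}

#' Dipole moment radiating a given power
#'
#' Returns the magnitude of the electric dipole moment (C m) whose
#' time-averaged radiated power in the (low-loss) homogeneous medium equals
#' `power`, using P = eta k^2 (I l)^2 / (12 pi) and p = I l / omega. This is
#' the package's default excitation scale, tying field amplitudes to a
#' physically meaningful 1 W drive.
#'
#' @inheritParams wavenumber
#' @param power Radiated power in W.
#' @return Dipole moment magnitude (C m).
#' @export
dipole_moment_for_power <- function(eps_c, frequency, power = 1) {
  omega <- 2 * pi * frequency
  k <- abs(wavenumber(eps_c, frequency))
  eta <- sqrt(MU0 / EPS0) / sqrt(abs(Re(eps_c)))
  Il <- sqrt(12 * pi * power / (eta * k^2))
  Il / omega
}

#' Field of an infinitesimal dipole in a homogeneous lossy medium
#'
#' Exact phasor field of a Hertzian dipole with moment vector `moment *
#' orientation` at `position`, evaluated at `points`, in a homogeneous
#' medium of complex relative permittivity `eps_c`:
#' E = exp(-jkr)/(4 pi eps) * ( k^2 (p - rhat (rhat . p)) / r
#'     + (3 rhat (rhat . p) - p) (1/r^3 + jk/r^2) ),
#' with eps the absolute complex permittivity. This is the package's
#' analytic background-field provider; externally computed field tables can
#' be supplied instead via [field_set()].
#'
#' @param position Length-3 dipole location (m).
#' @param orientation Length-3 dipole axis (normalized internally).
#' @param points n x 3 matrix of evaluation points (m).
#' @param eps_c Complex relative permittivity of the medium.
#' @param frequency Frequency (Hz).
#' @param moment Dipole moment magnitude (C m); default: 1 W radiated power.
#' @return n x 3 complex matrix of E-field values (V/m).
#' @export
dipole_field <- function(position, orientation, points, eps_c, frequency,
                         moment = dipole_moment_for_power(eps_c, frequency)) {
  points <- matrix(points, ncol = 3)
  orientation <- orientation / sqrt(sum(orientation^2))
  d <- sweep(points, 2, position)
  r <- sqrt(rowSums(d * d))
  if (any(r == 0)) {
    abort("evaluation point coincides with the dipole position (field singular)")
  }
  rhat <- d / r
  k <- wavenumber(eps_c, frequency)
  eps_abs <- EPS0 * as.complex(eps_c)
  p <- moment * orientation
  rp <- as.vector(rhat %*% p)                 # rhat . p
  trans <- -outer(rp, rep(1, 3)) * rhat       # transverse part minus p added below
  trans <- sweep(trans, 2, p, "+")            # p - rhat (rhat.p)
  long <- 3 * outer(rp, rep(1, 3)) * rhat
  long <- sweep(long, 2, p, "-")              # 3 rhat (rhat.p) - p
  pref <- exp(-1i * k * r) / (4 * pi * eps_abs)
  (pref * k^2 / r) * trans + (pref * (1 / r^3 + 1i * k / r^2)) * long
}

#' Background field set over a mesh
#'
#' Evaluates (or wraps) the background electric field of every antenna at
#' every tetrahedron barycentre. With the default analytic provider the
#' medium is homogeneous with the coupling-medium permittivity; `eps_c` may
#' be a single value or one value per antenna (used for non-nominal coupling
#' bricks). Alternatively pass a precomputed list `E` of Ma complex n x 3
#' matrices (e.g. imported full-wave fields) and the provider is bypassed.
#'
#' @param array An [antenna_array()].
#' @param mesh A [tet_mesh()] (fields evaluated at barycentres).
#' @param eps_c Complex relative permittivity of the medium: scalar or
#'   length-Ma vector (per-antenna coupling brick).
#' @param frequency Frequency (Hz).
#' @param E Optional externally computed fields: list of Ma matrices
#'   (n_tets x 3, complex). When given, `eps_c` is ignored for evaluation.
#' @return A `field_set`: list with `E` (list of Ma n x 3 complex matrices),
#'   `Ma`, `n`, `frequency`.
#' @export
field_set <- function(array, mesh, eps_c = 18.42 - 0.9i, frequency = 1e9,
                      E = NULL) {
  stopifnot(inherits(array, "antenna_array"))
  n <- nrow(mesh$barycentres)
  if (is.null(E)) {
    eps_ant <- rep_len(as.complex(eps_c), array$Ma)
    E <- lapply(seq_len(array$Ma), function(p) {
      dipole_field(array$positions[p, ], array$orientations[p, ],
                   mesh$barycentres, eps_ant[p], frequency)
    })
  } else {
    ok <- length(E) == array$Ma &&
      all(vapply(E, function(m) is.matrix(m) && nrow(m) == n && ncol(m) == 3,
                 logical(1)))
    if (!ok) abort("externally supplied E must be a list of Ma (n x 3) matrices")
  }
  if (!all(vapply(E, function(m) all(is.finite(Re(m)) & is.finite(Im(m))),
                  logical(1)))) {
    abort("field set contains non-finite entries")
  }
  structure(list(E = E, Ma = array$Ma, n = n, frequency = frequency),
            class = "field_set")
}
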