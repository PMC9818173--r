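#' Scattering-parameter matrix
#'
#' A square complex Ma x Ma matrix of scattering parameters S_pq (p the
#' receiver, q the transmitter) with a role tag: `"background"` (healthy
#' reference), `"differential"` (scenario minus background), `"test"`
#' (scenario under test) or `"calibrated"`.
#'
#' @param S Square complex matrix.
#' @param role Character role tag.
#' @return An `sparams` object (matrix with class and `role` attribute).
#' @export
sparams <- function(S, role = c("background", "differential", "test", "calibrated")) {
  role <- match.arg(role)
  S <- as.matrix(S)
  stopifnot(nrow(S) == ncol(S))
  if (!all(is.finite(Re(S)) & is.finite(Im(S)))) abort("non-finite S-parameters")
  structure(S * (1 + 0i), class = "sparams", role = role)
}

sp_role <- function(x) attr(x, "role")

#' @export
print.sparams <- function(x, ...) {
  cat("<sparams> ", nrow(x), "x", ncol(x), " role=", sp_role(x),
      " mean|S|=", format(mean(abs(x)), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Tidy an S-parameter matrix into a long tibble
#'
#' @param x An [sparams()] object.
#' @param ... Unused.
#' @return Tibble with columns `p`, `q`, `re`, `im`, `amplitude`, `role`.
#' @export
tidy.sparams <- function(x, ...) {
  Ma <- nrow(x)
  tibble::tibble(
    p = rep(seq_len(Ma), times = Ma),
    q = rep(seq_len(Ma), each = Ma),
    re = as.vector(Re(x)), im = as.vector(Im(x)),
    amplitude = as.vector(abs(x)), role = sp_role(x)
  )
}

#' Write / read S-parameters as Touchstone-like CSV
#'
#' Plain CSV with columns `p,q,re,im` (one row per antenna pair) and the
#' role stored in a `role` column.
#' @param x An [sparams()] object.
#' @param path File path.
#' @return `write_sparams()` returns `path` invisibly; `read_sparams()` an
#'   [sparams()].
#' @export
write_sparams <- function(x, path) {
  df <- tidy.sparams(x)
  write.csv(df[c("p", "q", "re", "im", "role")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sparams
#' @export
read_sparams <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  Ma <- max(df$p, df$q)
  S <- matrix(0 + 0i, Ma, Ma)
  S[cbind(df$p, df$q)] <- complex(real = df$re, imaginary = df$im)
  sparams(S, role = df$role[1])
}

#' Add differential S-parameters to a background set
#'
#' S_t = S_b + dS elementwise: the scenario-under-test scattering
#' parameters are the background ones plus the differential contribution.
#'
#' @param background Background [sparams()].
#' @param dS Differential [sparams()] (same dimension).
#' @return Test-role [sparams()].
#' @export
total_sparams <- function(background, dS) {
  if (!all(dim(background) == dim(dS))) {
    abort("background and differential S-parameter shapes differ")
  }
  sparams(unclass(background) + unclass(dS), role = "test")
}

#' Born linearization error metric
#'
#' Per antenna pair, eta_pq = 20 log10 |S_ref - S_lin| (dB). Pairs where the
#' two sets agree exactly would give -Inf and are reported at a configurable
#' floor.
#'
#' @param S_ref Reference S-parameters (e.g. full-wave or perturbed system).
#' @param S_lin Linearized/nominal S-parameters.
#' @param floor_db Value replacing -Inf (default -300 dB).
#' @return Numeric Ma x Ma matrix of errors in dB.
#' @export
born_error <- function(S_ref, S_lin, floor_db = -300) {
  if (!all(dim(S_ref) == dim(S_lin))) abort("shape mismatch")
  eta <- 20 * log10(abs(unclass(S_ref) - unclass(S_lin)))
  eta[!is.finite(eta)] <- floor_db
  pmax(eta, floor_db)
}
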