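#' Conformal antenna array over the upper head
#'
#' Generates a helmet-like array of `Ma` antennas on a spherical cap above
#' the head, arranged in rings of equal polar angle (default 24 antennas in
#' three rings of eight). Each antenna is an infinitesimal dipole whose axis
#' is tangential to the cap (along the local polar direction) and radiates a
#' unit power wave by default.
#'
#' @param Ma Number of antennas (must be divisible by the number of rings).
#' @param radius Cap radius in metres (outside the skin shell).
#' @param ring_angles Polar angles of the rings, degrees from the +z axis.
#' @param power_waves Power wave amplitude a_p per antenna (sqrt(W));
#'   recycled to length `Ma`.
#' @return An `antenna_array`: list with `Ma`, `positions` (Ma x 3, m),
#'   `orientations` (Ma x 3 unit vectors), `power_waves` (complex length Ma).
#' @examples
#' arr <- antenna_array()
#' arr$Ma
#' @export
antenna_array <- function(Ma = 24, radius = 0.105,
                          ring_angles = c(25, 50, 75), power_waves = 1) {
  stopifnot(Ma >= 2, radius > 0, Ma %% length(ring_angles) == 0)
  per_ring <- Ma / length(ring_angles)
  theta <- rep(ring_angles * pi / 180, each = per_ring)
  ## stagger alternate rings by half a step to avoid aligned columns
  phi <- as.vector(vapply(seq_along(ring_angles), function(r) {
    2 * pi * (0:(per_ring - 1)) / per_ring + (r %% 2) * pi / per_ring
  }, numeric(per_ring)))
  positions <- radius * cbind(sin(theta) * cos(phi),
                              sin(theta) * sin(phi),
                              cos(theta))
  orientations <- cbind(cos(theta) * cos(phi),
                        cos(theta) * sin(phi),
                        -sin(theta))
  pw <- as.complex(rep_len(power_waves, Ma))
  if (any(pw == 0)) abort("power waves must be non-zero")
  structure(list(Ma = as.integer(Ma), positions = positions,
                 orientations = orientations, power_waves = pw),
            class = "antenna_array")
}

#' @export
print.antenna_array <- function(x, ...) {
  cat("<antenna_array> Ma =", x$Ma, "on cap radius",
      format(sqrt(sum(x$positions[1, ]^2)), digits = 4), "m\n")
  invisible(x)
}
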