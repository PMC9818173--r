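#' Configured contrast-noise levels
#'
#' Default dB levels of the S-parameter noise produced from contrast-domain
#' perturbations: -110, -105, -95 and -90 dB. The level L is interpreted as
#' the mean per-element power of the noise dS, i.e. mean |dS|^2 = 10^(L/10)
#' (the lowest level is comparable to the noise floor of a medium-quality
#' vector network analyser).
#'
#' @return Numeric vector of dB levels.
#' @export
noise_levels <- function() c(-110, -105, -95, -90)

#' Pick a noise level uniformly at random
#' @param levels Candidate dB levels.
#' @return One element of `levels`.
#' @export
pick_level <- function(levels = noise_levels()) {
  levels[sample.int(length(levels), 1)]
}

rcnorm <- function(n) complex(real = rnorm(n), imaginary = rnorm(n)) / sqrt(2)

#' Contrast-domain noise mapped through the operator
#'
#' Draws i.i.d. circular complex Gaussian contrast noise dchi over the
#' tetrahedra, maps it to dS = S dchi, and scales both by the single factor
#' that makes the realized mean per-element power of dS equal 10^(L/10)
#' exactly.
#'
#' @param op A scattering operator.
#' @param level_db Noise level in dB.
#' @return List with `dchi` (length-N complex), `dS` (differential
#'   [sparams()]), `level_db`.
#' @export
contrast_noise <- function(op, level_db) {
  stopifnot(inherits(op, "scattering_operator"))
  dchi0 <- rcnorm(op$n_tets)
  dS0 <- as.vector(op$S %*% dchi0)
  pw <- mean(abs(dS0)^2)
  if (pw == 0) abort("all-zero operator: target noise level unreachable")
  c0 <- sqrt(10^(level_db / 10) / pw)
  list(dchi = c0 * dchi0,
       dS = sparams(vec_to_smatrix(c0 * dS0, op$Ma), role = "differential"),
       level_db = level_db)
}

#' Precomputed sampler for operator-mapped noise
#'
#' For Gaussian dchi the distribution of S dchi is complex Gaussian with
#' covariance S S^H; factoring that M x M Gram matrix once (Hermitian
#' eigendecomposition) lets bulk dataset generation draw dS directly in
#' O(M^2) per record instead of O(M N), with exactly the same distribution
#' and the same realized-power normalization as [contrast_noise()].
#'
#' @param op A scattering operator.
#' @return A `noise_model` (factor matrix + Ma).
#' @export
noise_model <- function(op) {
  G <- op$S %*% Conj(t(op$S))
  if (all(abs(G) == 0)) abort("all-zero operator: target noise level unreachable")
  e <- eigen(G, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)))
  structure(list(L = L, Ma = op$Ma), class = "noise_model")
}

#' Draw one dS noise vector from a noise model
#' @param nm A [noise_model()].
#' @param level_db Noise level in dB.
#' @return Complex vector of length Ma^2 with mean |dS|^2 = 10^(level/10).
#' @export
sample_ds_noise <- function(nm, level_db) {
  dS0 <- as.vector(nm$L %*% rcnorm(ncol(nm$L)))
  dS0 * sqrt(10^(level_db / 10) / mean(abs(dS0)^2))
}

#' Non-nominal system: perturbed coupling-brick permittivities
#'
#' Emulates manufacturing inaccuracy of the antenna coupling bricks: each
#' antenna's brick relative permittivity is drawn from a normal
#' distribution with mean equal to the nominal value (18.42) and the given
#' standard deviation (0.03 for "System A", 2.00 for "System B"). Draws at
#' or below 1 are redrawn so the permittivity stays physical. The perturbed
#' values feed the field provider and background S-parameter generator.
#'
#' @param array An [antenna_array()] (sets the number of bricks).
#' @param std Standard deviation of the per-brick permittivity.
#' @param nominal Nominal brick relative permittivity.
#' @param sigma_s Brick conductivity (S/m) used to form the complex value.
#' @param frequency Frequency (Hz).
#' @return A `perturbed_system`: list with `eps_r` (per antenna), `eps_c`
#'   (complex per antenna), `nominal`, `std`.
#' @export
perturb_system <- function(array, std, nominal = 18.42, sigma_s = 0.05,
                           frequency = 1e9) {
  stopifnot(std >= 0)
  eps_r <- rnorm(array$Ma, mean = nominal, sd = std)
  while (any(bad <- eps_r <= 1)) {
    eps_r[bad] <- rnorm(sum(bad), mean = nominal, sd = std)
  }
  loss <- sigma_s / (2 * pi * frequency * EPS0)
  structure(list(eps_r = eps_r,
                 eps_c = complex(real = eps_r, imaginary = -loss),
                 nominal = nominal, std = std, frequency = frequency),
            class = "perturbed_system")
}

#' Calibrate noisy perturbed-system measurements to the nominal system
#'
#' Per antenna pair, the calibrated scenario-under-test S-parameters are
#' S_t_cal = S_b / (S_b_tilde + dS1) * (S_t_tilde + dS2), where S_b is the
#' nominal-system background, S_b_tilde / S_t_tilde the perturbed-system
#' background and test sets, and dS1, dS2 independent noise draws.
#'
#' @param Sb_nominal Nominal background [sparams()].
#' @param Sb_tilde Perturbed-system background [sparams()].
#' @param St_tilde Perturbed-system test [sparams()].
#' @param dS1,dS2 Noise matrices (complex Ma x Ma, or 0).
#' @return Calibrated-role [sparams()].
#' @export
calibrate <- function(Sb_nominal, Sb_tilde, St_tilde, dS1 = 0, dS2 = 0) {
  if (!all(dim(Sb_nominal) == dim(Sb_tilde)) ||
      !all(dim(Sb_nominal) == dim(St_tilde))) {
    abort("S-parameter shapes differ")
  }
  den <- unclass(Sb_tilde) + dS1
  if (any(den == 0)) {
    bad <- which(den == 0, arr.ind = TRUE)[1, ]
    abort(paste0("calibration denominator is zero for antenna pair (",
                 bad[1], ", ", bad[2], ")"))
  }
  sparams(unclass(Sb_nominal) / den * (unclass(St_tilde) + dS2),
          role = "calibrated")
}
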