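#' Physical constants in the package unit system
#'
#' All internal computation is done in meV (energy), Angstrom (length) and
#' picosecond (time).  In this system the reduced Planck constant and the
#' Boltzmann constant are numerically tame, and `hbar * D * Q^2` is directly
#' an energy in meV when `D` is in A^2/ps and `Q` in 1/A.
#'
#' @format A named list with components:
#' \describe{
#'   \item{hbar}{reduced Planck constant, 0.6582119569 meV ps}
#'   \item{kB}{Boltzmann constant, 0.0861733326 meV/K}
#' }
#' @examples
#' qens_constants$hbar / 0.017  # correlation time (ps) of a 17 ueV line
#' @export
qens_constants <- list(
  hbar = 0.6582119569,
  kB   = 0.08617333262
)

#' Convert a diffusion coefficient from cm^2/s to A^2/ps
#'
#' Diffusivities are quoted in cm^2/s at the reporting boundary (the
#' convention of the membrane literature) but carried internally in A^2/ps:
#' 1 A^2/ps = 1e-16 cm^2 / 1e-12 s = 1e-4 cm^2/s.
#'
#' @param d Diffusivity in cm^2/s. Must be non-negative.
#' @return Diffusivity in A^2/ps.
#' @seealso [diffusivity_A2ps_to_cm2s()]
#' @examples
#' diffusivity_cm2s_to_A2ps(11.6e-7)  # 0.0116 A^2/ps
#' @export
diffusivity_cm2s_to_A2ps <- function(d) {
  if (any(!is.finite(d)) || any(d < 0)) {
    abort("diffusivity must be finite and non-negative", class = "qens_domain_error")
  }
  d * 1e4
}

#' Convert a diffusion coefficient from A^2/ps to cm^2/s
#'
#' @param d Diffusivity in A^2/ps. Must be non-negative.
#' @return Diffusivity in cm^2/s.
#' @export
diffusivity_A2ps_to_cm2s <- function(d) {
  if (any(!is.finite(d)) || any(d < 0)) {
    abort("diffusivity must be finite and non-negative", class = "qens_domain_error")
  }
  d * 1e-4
}

#' Correlation time corresponding to a quasielastic half-width
#'
#' A Lorentzian quasielastic line of half-width-at-half-maximum `gamma`
#' corresponds to an exponential relaxation with correlation time
#' `tau = hbar / gamma`; equivalently a relaxation process of time `tau`
#' peaks in the dynamic susceptibility at energy transfer `hbar / tau`.
#'
#' @param gamma HWHM in meV, strictly positive.
#' @return Correlation time in ps.
#' @examples
#' hwhm_to_timescale(0.017)  # ~38.7 ps, the resolution-limited timescale
#' @export
hwhm_to_timescale <- function(gamma) {
  if (any(!is.finite(gamma)) || any(gamma <= 0)) {
    abort("hwhm must be finite and > 0", class = "qens_domain_error")
  }
  qens_constants$hbar / gamma
}
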