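#' Unit-area Lorentzian line shape
#'
#' `L(Gamma, E) = (1/pi) * Gamma / (Gamma^2 + E^2)`, the quasielastic line of
#' a simple exponential relaxation; `Gamma` is the half-width at
#' half-maximum in meV and the integral over the whole energy axis is 1.
#'
#' @param energy Energy transfer(s) in meV.
#' @param hwhm Half-width at half-maximum in meV, > 0.
#' @return Intensity per meV, same length as `energy`.
#' @examples
#' lorentzian(0, 0.01)            # peak value 1/(pi * Gamma)
#' lorentzian(0.01, 0.01)         # half the peak value
#' @export
lorentzian <- function(energy, hwhm) {
  if (!is.finite(hwhm) || hwhm <= 0) {
    abort("hwhm must be finite and > 0", class = "qens_domain_error")
  }
  (1 / pi) * hwhm / (hwhm^2 + energy^2)
}

#' Fickian lateral-diffusion half-width
#'
#' Continuous (Fickian) diffusion broadens the elastic line into a
#' Lorentzian whose half-width grows quadratically with Q and passes through
#' the origin: `Gamma_lat = hbar * D_lat * Q^2` (meV, with `D_lat` in
#' A^2/ps and `Q` in 1/A).
#'
#' @param q Wave-vector transfer(s) in 1/A, >= 0.
#' @param d_lat Lateral diffusion coefficient in A^2/ps, >= 0.
#' @return Half-width(s) in meV.
#' @examples
#' fick_hwhm(1.8, 0.0116)  # ~0.0247 meV, inside the instrument window
#' @export
fick_hwhm <- function(q, d_lat) {
  if (any(q < 0) || d_lat < 0) {
    abort("q and d_lat must be >= 0", class = "qens_domain_error")
  }
  qens_constants$hbar * d_lat * q^2
}

#' Elastic incoherent structure factor of a partially mobile sphere
#'
#' The elastic fraction of the internal-motion scattering when a fraction
#' `p_immobile` of hydrogen atoms is static on the observation timescale
#' and the rest diffuse within a sphere of radius R:
#' `A(Q) = p_x + (1 - p_x) * [3 j_1(QR) / (QR)]^2`.
#' The `Q -> 0` limit is handled analytically (`A(0) = 1`).
#'
#' @param q Wave-vector transfer(s) in 1/A, >= 0.
#' @param radius Sphere radius in A, > 0.
#' @param p_immobile Immobile fraction in \[0, 1\].
#' @return `A(Q)` in \[0, 1\], same length as `q`.
#' @examples
#' sphere_eisf(c(0, 1.0, 1.6), radius = 2.8, p_immobile = 0.41)
#' @export
sphere_eisf <- function(q, radius, p_immobile) {
  if (!is.finite(radius) || radius <= 0) {
    abort("radius must be > 0", class = "qens_domain_error")
  }
  if (p_immobile < 0 || p_immobile > 1) {
    abort("p_immobile must lie in [0, 1]", class = "qens_domain_error")
  }
  if (any(q < 0)) abort("q must be >= 0", class = "qens_domain_error")
  qr <- q * radius
  form <- ifelse(qr < 1e-8, 1, (3 * sph_bessel_j(1, qr) / pmax(qr, 1e-300))^2)
  p_immobile + (1 - p_immobile) * form
}

#' Composite membrane scattering law (before resolution convolution)
#'
#' The measured membrane signal is the convolution of the lateral and
#' internal scattering laws.  With a single effective internal Lorentzian,
#' Lorentzian closure under convolution gives the two-component form
#' \deqn{S(Q,E) = scale\,[A(Q) L(\Gamma_{lat}, E) +
#'   (1-A(Q)) L(\Gamma_{lat}+\Gamma_{int}, E)] + background,}
#' i.e. the broad component carries the SUM of the two half-widths — the
#' exact convolution of the two Lorentzians, so no numerical convolution is
#' needed at the model level.  The narrow component is the image of the
#' internal elastic line broadened by lateral diffusion.
#'
#' @param energy Energy grid in meV.
#' @param params Named list or one-row data frame with `a_q` (elastic
#'   fraction in \[0,1\]), `gamma_lat`, `gamma_int` (HWHMs in meV, > 0),
#'   `scale` (>= 0) and `background` (>= 0).
#' @return Model intensity on `energy`.
#' @examples
#' p <- list(a_q = 0.6, gamma_lat = 0.008, gamma_int = 0.05,
#'           scale = 1, background = 0)
#' s <- composite_sqw(seq(-0.3, 1, by = 0.005), p)
#' @export
composite_sqw <- function(energy, params) {
  p <- as.list(params)
  if (p$a_q < 0 || p$a_q > 1) {
    abort("a_q must lie in [0, 1]", class = "qens_domain_error")
  }
  if (p$scale < 0 || p$background < 0) {
    abort("scale and background must be >= 0", class = "qens_domain_error")
  }
  p$scale * (p$a_q * lorentzian(energy, p$gamma_lat) +
             (1 - p$a_q) * lorentzian(energy, p$gamma_lat + p$gamma_int)) +
    p$background
}

resolution_kernel <- function(resolution, h, q = NULL) {
  if (resolution$kind == "gaussian") {
    half <- ceiling(6 * resolution$sigma / h)
    offs <- (-half:half) * h
    k <- exp(-offs^2 / (2 * resolution$sigma^2))
  } else {
    sp <- resolution$spectra
    if (!is.null(q)) {
      qa <- unique(sp$q)
      qi <- qa[which.min(abs(qa - q))]
      if (abs(qi - q) > 1e-6) {
        abort(sprintf("measured resolution has no spectrum at Q = %g", q),
              class = "qens_validation_error")
      }
      sp <- sp[sp$q == qi, ]
    }
    half <- ceiling(max(abs(range(sp$energy))) / h)
    offs <- (-half:half) * h
    k <- approx(sp$energy, sp$intensity, xout = offs, rule = 1)$y
    k[is.na(k)] <- 0
    k <- pmax(k, 0)
  }
  list(k = k / sum(k), half = length(k) %/% 2)
}

#' Convolve a model spectrum with the instrument resolution
#'
#' Discrete convolution of a sampled quasielastic continuum with the
#' resolution line shape, plus `elastic_weight` times the resolution shape
#' itself — the image of the elastic delta line, which is never represented
#' as a grid spike.  The continuum is linearly extended by zero outside its
#' grid; for high-accuracy work evaluate the model through
#' [convolve_model_fn()] instead, which oversamples before convolving.
#'
#' @param energy Uniform energy grid in meV.
#' @param intensity Model continuum sampled on `energy`.
#' @param resolution A [resolution_function()].
#' @param elastic_weight Weight of the elastic delta line (default 0).
#' @param q Q value used to select a measured-resolution spectrum.
#' @return Convolved intensity on `energy`.
#' @examples
#' res <- resolution_function()
#' e <- seq(-0.3, 0.3, by = 0.002)
#' delta_image <- convolve_resolution(e, rep(0, length(e)), res,
#'                                    elastic_weight = 1)
#' @export
convolve_resolution <- function(energy, intensity, resolution,
                                elastic_weight = 0, q = NULL) {
  de <- check_uniform_grid(energy)
  kr <- resolution_kernel(resolution, de, q = q)
  y <- c(rep(0, kr$half), intensity, rep(0, kr$half))
  conv <- stats::convolve(y, rev(kr$k), type = "open")
  # 'open' convolution of length N+M-1; central part aligned with y
  start <- kr$half + 1
  out <- conv[(start + kr$half):(start + kr$half + length(energy) - 1)]
  out + elastic_weight * elastic_line(energy, resolution, de, q = q)
}

elastic_line <- function(energy, resolution, de, q = NULL) {
  kr <- resolution_kernel(resolution, de, q = q)
  offs <- (-kr$half:kr$half) * de
  approx(offs, kr$k / de, xout = energy, rule = 1, yright = 0, yleft = 0)$y
}

check_uniform_grid <- function(energy) {
  de <- diff(energy)
  if (length(de) < 1 || any(abs(de - de[1]) > 1e-9 * abs(de[1]))) {
    abort("energy grid must be uniform", class = "qens_validation_error")
  }
  de[1]
}

#' Resolution-convolved model evaluation with oversampling
#'
#' Evaluates a continuum model function on a 4x (configurable) oversampled
#' grid extended past the data window by the kernel support, convolves by
#' direct summation with the sampled resolution kernel, and decimates back
#' to the data grid.  This avoids FFT wrap-around on the asymmetric energy
#' window and keeps the discretization error of a Lorentzian (x) Gaussian
#' well below 1e-4 relative.
#'
#' @param energy Uniform target grid in meV.
#' @param fn Function of energy returning continuum intensity (unit-area
#'   components recommended; add flat backgrounds after convolution).
#' @param resolution A [resolution_function()].
#' @param elastic_weight Weight of the elastic delta line (default 0).
#' @param oversample Integer oversampling factor (default 4).
#' @param q Q value used to select a measured-resolution spectrum.
#' @return Convolved intensity on `energy`.
#' @export
convolve_model_fn <- function(energy, fn, resolution, elastic_weight = 0,
                              oversample = 4, q = NULL) {
  de <- check_uniform_grid(energy)
  h <- de / oversample
  kr <- resolution_kernel(resolution, h, q = q)
  n_pad <- kr$half
  e_ext <- seq(energy[1] - n_pad * h,
               by = h,
               length.out = (length(energy) - 1) * oversample + 2 * n_pad + 1)
  y <- fn(e_ext)
  conv <- stats::convolve(y, rev(kr$k), type = "open")
  start <- 2 * n_pad + 1   # index of e_ext[n_pad + 1] = energy[1] in 'conv'
  idx <- start + seq(0, by = oversample, length.out = length(energy))
  out <- conv[idx]
  if (elastic_weight != 0) {
    out <- out + elastic_weight * elastic_line(energy, resolution, h, q = q)
  }
  out
}

#' Forward model of a measured per-Q spectrum
#'
#' The composite membrane scattering law of [composite_sqw()] convolved with
#' the instrument resolution; the flat background is added after
#' convolution (a constant is invariant under unit-area convolution, and
#' this avoids edge artifacts).
#'
#' @inheritParams composite_sqw
#' @inheritParams convolve_model_fn
#' @return Measurable model intensity on `energy`.
#' @export
qens_model_spectrum <- function(energy, params, resolution, oversample = 4,
                                q = NULL) {
  p <- as.list(params)
  fn <- function(e) {
    p$scale * (p$a_q * lorentzian(e, p$gamma_lat) +
               (1 - p$a_q) * lorentzian(e, p$gamma_lat + p$gamma_int))
  }
  convolve_model_fn(energy, fn, resolution, elastic_weight = 0,
                    oversample = oversample, q = q) + p$background
}
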