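perq_par_names <- c("a_q", "gamma_lat", "gamma_int", "scale", "background")
perq_lower <- c(a_q = 0, gamma_lat = 1e-4, gamma_int = 1e-4, scale = 0, background = 0)
perq_upper <- c(a_q = 1, gamma_lat = 0.5, gamma_int = 0.5, scale = Inf, background = Inf)

default_perq_init <- function(energy, intensity, q, d0_init = 0.01) {
  bg <- max(min(intensity), 0)
  area <- max(trapz_area(energy, intensity - bg), 1e-6)
  c(a_q = 0.5,
    gamma_lat = min(max(fick_hwhm(q, d0_init), 2e-3), 0.4),
    gamma_int = 0.05,
    scale = area,
    background = bg)
}

numeric_jacobian <- function(res_fn, par) {
  r0 <- res_fn(par)
  J <- matrix(0, length(r0), length(par))
  for (j in seq_along(par)) {
    h <- max(1e-7, 1e-7 * abs(par[j]))
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- max(pm[j] - h, 0)
    J[, j] <- (res_fn(pp) - res_fn(pm)) / (pp[j] - pm[j])
  }
  J
}

param_covariance <- function(res_fn, par) {
  J <- numeric_jacobian(res_fn, par)
  jtj <- crossprod(J)
  cov <- tryCatch(solve(jtj), error = function(e) {
    # ridge fallback for parameters pinned at a bound
    solve(jtj + diag(1e-10 * max(diag(jtj)), ncol(jtj)))
  })
  cov
}

#' Fit the resolution-convolved composite model to one Q spectrum
#'
#' Error-weighted least squares (`chi^2 = sum[(data - model)/sigma]^2`) of
#' the two-Lorentzian membrane model convolved with the instrument
#' resolution, over the five parameters elastic fraction `a_q` (bounded to
#' \[0,1\]), `gamma_lat` and `gamma_int` (bounded to \[1e-4, 0.5\] meV),
#' `scale` and flat `background`, using bounded Levenberg-Marquardt.
#' The broad component structurally carries width
#' `gamma_lat + gamma_int > gamma_lat`, which resolves the label-exchange
#' degeneracy of a two-Lorentzian mixture; the lateral width is initialized
#' from Fick's law with a configurable prior diffusivity.  On
#' non-convergence a small set of deterministic restarts is tried; failure
#' is reported through `converged = FALSE`, never as an error.
#'
#' @param spec Data frame for a single Q with columns `energy`,
#'   `intensity`, `uncertainty` (and optionally `q`).
#' @param resolution A [resolution_function()].
#' @param q Wave-vector transfer in 1/A (taken from `spec$q` if absent).
#' @param init Optional named vector of starting values
#'   (`a_q`, `gamma_lat`, `gamma_int`, `scale`, `background`).
#' @param d0_init Prior lateral diffusivity (A^2/ps) used to initialize
#'   `gamma_lat`.
#' @param oversample Convolution oversampling factor.
#' @return A one-row tibble with the fitted parameters, their 1-sigma
#'   covariance errors (`*_se`), `chi2_reduced` and `converged`.
#' @export
fit_per_q <- function(spec, resolution, q = NULL, init = NULL,
                      d0_init = 0.01, oversample = 4) {
  df <- tibble::as_tibble(spec)
  if (is.null(q)) {
    if (!"q" %in% names(df)) abort("supply q or a q column", class = "qens_validation_error")
    q <- unique(df$q)
    if (length(q) != 1) abort("fit_per_q expects a single-Q spectrum", class = "qens_validation_error")
  }
  if (nrow(df) < 50) {
    abort("need at least 50 energy points per spectrum", class = "qens_validation_error")
  }
  if (mean(df$uncertainty > 0) < 0.9) {
    abort("need positive uncertainties on at least 90% of points",
          class = "qens_validation_error")
  }
  sigma <- ifelse(df$uncertainty > 0, df$uncertainty,
                  stats::median(df$uncertainty[df$uncertainty > 0]))
  res_fn <- function(par) {
    par <- setNames(pmin(pmax(par, perq_lower), perq_upper), perq_par_names)
    m <- qens_model_spectrum(df$energy, as.list(par), resolution,
                             oversample = oversample, q = q)
    (df$intensity - m) / sigma
  }
  auto0 <- default_perq_init(df$energy, df$intensity, q, d0_init)
  start0 <- if (is.null(init)) auto0 else {
    setNames(as.numeric(init[perq_par_names]), perq_par_names)
  }
  starts <- list(start0)
  if (!is.null(init)) starts <- c(starts, list(auto0))
  alt <- auto0; alt["a_q"] <- 0.3; alt["gamma_int"] <- 0.1
  alt2 <- auto0; alt2["a_q"] <- 0.7; alt2["gamma_int"] <- 0.02
  starts <- c(starts, list(alt, alt2))

  n_free <- max(nrow(df) - length(perq_par_names), 1)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = perq_lower, upper = perq_upper,
                         fn = res_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    # a local minimum leaves structured residuals; accept early only a fit
    # that is good in the absolute chi-square sense
    if (best$info %in% 1:4 && best$deviance / n_free < 1.5) break
  }
  n_par <- length(perq_par_names)
  if (is.null(best)) {
    out <- as.list(setNames(rep(NA_real_, n_par), perq_par_names))
    out <- c(out, as.list(setNames(rep(NA_real_, n_par),
                                   paste0(perq_par_names, "_se"))))
    return(tibble::tibble(q = q, !!!out, chi2_reduced = NA_real_,
                          converged = FALSE))
  }
  par <- setNames(pmin(pmax(best$par, perq_lower), perq_upper), perq_par_names)
  cov <- param_covariance(res_fn, par)
  se <- sqrt(pmax(diag(cov), 0))
  chi2_red <- best$deviance / max(nrow(df) - n_par, 1)
  converged <- best$info %in% 1:4 && is.finite(chi2_red)
  tibble::tibble(
    q = q,
    !!!as.list(par),
    !!!as.list(setNames(se, paste0(perq_par_names, "_se"))),
    chi2_reduced = chi2_red,
    converged = converged
  )
}

#' Per-Q fits across a whole dataset
#'
#' Runs [fit_per_q()] independently for every Q group (the per-Q fits share
#' no parameters) and collects the results.
#'
#' @param ds A `qens_dataset`.
#' @inheritParams fit_per_q
#' @return A tibble of class `qens_perq_fit`, one row per Q.
#' @export
fit_dataset <- function(ds, resolution, d0_init = 0.01, oversample = 4) {
  df <- tibble::as_tibble(ds)
  out <- df |>
    dplyr::group_split(.data$q) |>
    purrr::map(~ fit_per_q(.x, resolution, d0_init = d0_init,
                           oversample = oversample)) |>
    dplyr::bind_rows()
  class(out) <- unique(c("qens_perq_fit", class(out)))
  attr(out, "temperature") <- qens_temperature(ds)
  out
}

weighted_origin_fit <- function(x, y, sigma) {
  w <- 1 / sigma^2
  sw <- sum(w * x^2)
  est <- sum(w * x * y) / sw
  se <- sqrt(1 / sw)
  n <- length(x)
  chi2_red <- if (n > 1) sum(w * (y - est * x)^2) / (n - 1) else NA_real_
  if (is.finite(chi2_red) && chi2_red > 1) se <- se * sqrt(chi2_red)
  list(estimate = est, se = se, chi2_reduced = chi2_red, n = n)
}

#' Lateral diffusion coefficient from Fickian half-widths
#'
#' Error-weighted linear fit of the lateral half-widths against
#' `hbar * Q^2` through the origin; the slope is the lateral diffusion
#' coefficient.  The closed-form weighted normal-equations solution is
#' used: `D = sum(w x Gamma) / sum(w x^2)` with `x = hbar Q^2`,
#' `w = 1/sigma^2`.  The standard error comes from the weighted-fit
#' covariance, inflated by `sqrt(chi2_red)` when `chi2_red > 1`.
#'
#' @param hwhm_lat Data frame with columns `q` (1/A), `gamma` (meV) and
#'   `sigma` (1-sigma error on `gamma`, meV).  At least 4 points.
#' @return A list of class `qens_fick_fit` with `d_lat` (A^2/ps),
#'   `d_lat_se`, `d_lat_cm2s`, `d_lat_cm2s_se`, `chi2_reduced`, `n`.
#' @export
fit_dlat <- function(hwhm_lat) {
  df <- tibble::as_tibble(hwhm_lat)
  if (nrow(df) < 4) {
    abort("need at least 4 Q points to fit D_lat", class = "qens_validation_error")
  }
  f <- weighted_origin_fit(qens_constants$hbar * df$q^2, df$gamma, df$sigma)
  structure(list(
    d_lat = f$estimate, d_lat_se = f$se,
    d_lat_cm2s = diffusivity_A2ps_to_cm2s(f$estimate),
    d_lat_cm2s_se = diffusivity_A2ps_to_cm2s(f$se),
    chi2_reduced = f$chi2_reduced, n = f$n
  ), class = "qens_fick_fit")
}

#' Immobile fraction and confinement radius from the elastic fraction
#'
#' Weighted least-squares fit of the partially mobile sphere EISF
#' `A(Q) = p_x + (1 - p_x)[3 j_1(QR)/(QR)]^2` to per-Q elastic fractions,
#' over `p_x` in \[0,1\] and `R` in \[0.5, 10\] A.  The objective can have
#' local minima in R, so the fit is multi-started from
#' R = 1, 2, 3, 5 and 8 A; the lowest chi-squared wins and ties go to the
#' smaller radius.  A flat elastic fraction (no Q dependence) carries no
#' geometric information and is flagged non-identifiable.
#'
#' @param eisf_points Data frame with columns `q`, `a` (elastic fraction)
#'   and `sigma`.  At least 5 points.
#' @return A list of class `qens_eisf_fit` with `p_immobile`, `radius`,
#'   their `*_se`, `chi2_reduced`, `n`, `identifiable`.
#' @export
fit_eisf <- function(eisf_points) {
  df <- tibble::as_tibble(eisf_points)
  if (nrow(df) < 5) {
    abort("need at least 5 Q points to fit the EISF", class = "qens_validation_error")
  }
  if (diff(range(df$a)) < 1e-6) {
    return(structure(list(
      p_immobile = mean(df$a), p_immobile_se = NA_real_,
      radius = NA_real_, radius_se = NA_real_,
      chi2_reduced = NA_real_, n = nrow(df), identifiable = FALSE
    ), class = "qens_eisf_fit"))
  }
  lower <- c(p = 0, r = 0.5)
  upper <- c(p = 1, r = 10)
  res_fn <- function(par) {
    par <- pmin(pmax(par, lower), upper)
    (df$a - sphere_eisf(df$q, par[["r"]], par[["p"]])) / df$sigma
  }
  best <- NULL
  for (r0 in c(1, 2, 3, 5, 8)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(p = 0.5, r = r0), lower = lower, upper = upper,
                         fn = res_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-13, ptol = 1e-13)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) ||
        fit$deviance < best$deviance - 1e-12 ||
        (abs(fit$deviance - best$deviance) <= 1e-12 &&
         fit$par[["r"]] < best$par[["r"]])) {
      best <- fit
    }
  }
  if (is.null(best)) {
    abort("EISF fit failed from every start", class = "qens_numerical_error")
  }
  par <- pmin(pmax(best$par, lower), upper)
  cov <- param_covariance(res_fn, par)
  se <- sqrt(pmax(diag(cov), 0))
  chi2_red <- best$deviance / max(nrow(df) - 2, 1)
  if (is.finite(chi2_red) && chi2_red > 1) se <- se * sqrt(chi2_red)
  structure(list(
    p_immobile = par[["p"]], p_immobile_se = se[1],
    radius = par[["r"]], radius_se = se[2],
    chi2_reduced = chi2_red, n = nrow(df), identifiable = TRUE
  ), class = "qens_eisf_fit")
}

#' Internal diffusion coefficient from confined-diffusion half-widths
#'
#' Fits the numerically computed confined-diffusion half-width curve to the
#' observed internal broadenings by weighted least squares over the
#' diffusion coefficient, holding the immobile fraction and radius at
#' their EISF-fit values (the immobile fraction scales out of the width).
#' Because the half-width is exactly linear in D at fixed R, the bounded
#' one-dimensional minimization has the closed-form solution of a weighted
#' through-origin regression of `Gamma` on `h(Q) = vd_hwhm(Q, 1, R)`,
#' clipped to D in \[1e-4, 10\] A^2/ps.
#'
#' @param hwhm_int Data frame with columns `q`, `gamma` (meV), `sigma`.
#'   At least 4 points.
#' @param p_immobile Immobile fraction, recorded as held fixed.
#' @param radius Confinement radius in A, held fixed, > 0.
#' @param eig Eigenvalue table.
#' @return A list of class `qens_dint_fit` with `d_int` (A^2/ps),
#'   `d_int_se`, `d_int_cm2s`, `d_int_cm2s_se`, `chi2_reduced`, `n`,
#'   `fixed` (the (p_x, R) provenance) and `wide_uncertainty` flag.
#' @export
fit_dint <- function(hwhm_int, p_immobile, radius,
                     eig = vd_default_eigensystem()) {
  df <- tibble::as_tibble(hwhm_int)
  if (nrow(df) < 4) {
    abort("need at least 4 Q points to fit D_int", class = "qens_validation_error")
  }
  if (!is.finite(radius) || radius <= 0) {
    abort("radius must be > 0", class = "qens_domain_error")
  }
  h <- vd_hwhm(df$q, d_int = 1, radius = radius, eig = eig)
  f <- weighted_origin_fit(h, df$gamma, df$sigma)
  d <- min(max(f$estimate, 1e-4), 10)
  structure(list(
    d_int = d, d_int_se = f$se,
    d_int_cm2s = diffusivity_A2ps_to_cm2s(d),
    d_int_cm2s_se = diffusivity_A2ps_to_cm2s(f$se),
    chi2_reduced = f$chi2_reduced, n = f$n,
    fixed = list(p_immobile = p_immobile, radius = radius, source = "eisf_fit"),
    wide_uncertainty = is.finite(f$se) && f$se / d > 0.5
  ), class = "qens_dint_fit")
}
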