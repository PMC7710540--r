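#' Full two-stage QENS membrane analysis
#'
#' Orchestrates the complete analysis: optional solvent subtraction;
#' independent per-Q fits of the resolution-convolved composite model
#' (stage 1); then extraction of the physical membrane parameters
#' (stage 2) — the lateral diffusion coefficient from a Fick-law fit of
#' the narrow widths, the immobile fraction and confinement radius from
#' the elastic fractions, and the internal diffusion coefficient from the
#' confined-diffusion half-width curve with (p_x, R) held at their
#' EISF-fit values.  Stage-2 weights are the stage-1 covariance errors.
#' The run is fully deterministic for given inputs and configuration.
#'
#' @param sample A `qens_dataset`.
#' @param solvent Optional solvent `qens_dataset` to subtract.
#' @param resolution A [resolution_function()].
#' @param solvent_weight Weight for [subtract_solvent()] (default 0.95).
#' @param d0_init Prior lateral diffusivity (A^2/ps) for stage-1
#'   initialization.
#' @param oversample Convolution oversampling factor.
#' @param eig Eigenvalue table for the confined-diffusion model.
#' @return A list of class `qens_membrane_fit` with components `per_q`
#'   (stage-1 tibble), `fick_fit`, `eisf_fit`, `dint_fit`, `membrane`
#'   (tidy parameter tibble in reporting units), `temperature`, `label`.
#' @examples
#' \donttest{
#' sim <- generate_dataset(preset("liver_37C", noise_level = 0))
#' fit <- run_pipeline(sim)
#' glance(fit)
#' }
#' @export
run_pipeline <- function(sample, solvent = NULL,
                         resolution = resolution_function(),
                         solvent_weight = 0.95, d0_init = 0.01,
                         oversample = 4, eig = vd_default_eigensystem()) {
  if (is.null(sample) || nrow(sample) == 0) {
    abort("pipeline: empty sample dataset", class = "qens_validation_error")
  }
  reduced <- if (!is.null(solvent)) {
    subtract_solvent(sample, solvent, solvent_weight)
  } else sample

  per_q <- fit_dataset(reduced, resolution, d0_init = d0_init,
                       oversample = oversample)
  ok <- per_q[per_q$converged, ]
  if (nrow(ok) < 4) {
    abort("pipeline: fewer than 4 converged per-Q fits", class = "qens_numerical_error")
  }

  fick <- fit_dlat(tibble::tibble(q = ok$q, gamma = ok$gamma_lat,
                                  sigma = pmax(ok$gamma_lat_se, 1e-12)))
  eisf <- fit_eisf(tibble::tibble(q = ok$q, a = ok$a_q,
                                  sigma = pmax(ok$a_q_se, 1e-12)))
  dint <- fit_dint(tibble::tibble(q = ok$q, gamma = ok$gamma_int,
                                  sigma = pmax(ok$gamma_int_se, 1e-12)),
                   p_immobile = eisf$p_immobile, radius = eisf$radius,
                   eig = eig)

  membrane <- tibble::tibble(
    term = c("d_lat", "p_immobile", "radius", "d_int"),
    estimate = c(fick$d_lat_cm2s, eisf$p_immobile, eisf$radius, dint$d_int_cm2s),
    std.error = c(fick$d_lat_cm2s_se, eisf$p_immobile_se, eisf$radius_se,
                  dint$d_int_cm2s_se),
    unit = c("cm^2/s", "fraction", "A", "cm^2/s")
  )

  structure(list(
    per_q = per_q, fick_fit = fick, eisf_fit = eisf, dint_fit = dint,
    membrane = membrane,
    temperature = qens_temperature(sample),
    label = qens_label(sample)
  ), class = "qens_membrane_fit")
}

#' Format a value with its parenthetical uncertainty
#'
#' Renders `2.83 +/- 0.02` in the compact tabular convention `"2.83 (2)"`:
#' the parenthesized digits are the 1-sigma error in units of the last
#' quoted digit.
#'
#' @param x Central value.
#' @param se 1-sigma uncertainty.
#' @return A character scalar.
#' @examples
#' format_value_unc(2.8, 0.2)    # "2.8 (2)"
#' format_value_unc(12.3, 0.4)   # "12.3 (4)"
#' @export
format_value_unc <- function(x, se) {
  if (!is.finite(se) || se <= 0) return(format(x))
  digits <- max(0, -floor(log10(se)))
  err_digit <- round(se * 10^digits)
  if (err_digit >= 10) {
    digits <- digits - 1
    err_digit <- round(se * 10^digits)
  }
  sprintf("%.*f (%d)", digits, round(x, digits), err_digit)
}

#' @export
print.qens_membrane_fit <- function(x, ...) {
  cat("QENS membrane analysis", if (nzchar(x$label)) paste0("(", x$label, ")"),
      "at", x$temperature, "K\n")
  cat(sprintf("  D_lat  = %s x 1e-7 cm^2/s\n",
              format_value_unc(x$fick_fit$d_lat_cm2s * 1e7,
                               x$fick_fit$d_lat_cm2s_se * 1e7)))
  cat(sprintf("  p_x    = %s\n",
              format_value_unc(x$eisf_fit$p_immobile, x$eisf_fit$p_immobile_se)))
  cat(sprintf("  R      = %s A\n",
              format_value_unc(x$eisf_fit$radius, x$eisf_fit$radius_se)))
  cat(sprintf("  D_int  = %s x 1e-6 cm^2/s\n",
              format_value_unc(x$dint_fit$d_int_cm2s * 1e6,
                               x$dint_fit$d_int_cm2s_se * 1e6)))
  cat(sprintf("  per-Q fits: %d/%d converged, median chi2_red = %.3g\n",
              sum(x$per_q$converged), nrow(x$per_q),
              stats::median(x$per_q$chi2_reduced, na.rm = TRUE)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.qens_membrane_fit <- function(x, ...) {
  x$membrane
}

#' @exportS3Method generics::glance
glance.qens_membrane_fit <- function(x, ...) {
  tibble::tibble(
    d_lat_cm2s = x$fick_fit$d_lat_cm2s,
    p_immobile = x$eisf_fit$p_immobile,
    radius_A = x$eisf_fit$radius,
    d_int_cm2s = x$dint_fit$d_int_cm2s,
    n_q = nrow(x$per_q),
    n_converged = sum(x$per_q$converged),
    temperature = x$temperature
  )
}

#' @exportS3Method generics::tidy
tidy.qens_perq_fit <- function(x, ...) {
  df <- tibble::as_tibble(x)
  est <- df |>
    dplyr::select("q", dplyr::all_of(perq_par_names)) |>
    tidyr::pivot_longer(-"q", names_to = "term", values_to = "estimate")
  se <- df |>
    dplyr::select("q", dplyr::all_of(paste0(perq_par_names, "_se"))) |>
    tidyr::pivot_longer(-"q", names_to = "term", values_to = "std.error") |>
    dplyr::mutate(term = sub("_se$", "", .data$term))
  est |>
    dplyr::left_join(se, by = c("q", "term")) |>
    dplyr::left_join(dplyr::select(df, "q", "chi2_reduced", "converged"),
                     by = "q")
}
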