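#' Plot the spectra of a QENS dataset
#'
#' Intensity versus energy transfer, one colour per Q, on a log intensity
#' scale (the standard way quasielastic wings are inspected).
#'
#' @param ds A `qens_dataset`.
#' @param log_y Use a log10 intensity axis (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_spectra <- function(ds, log_y = TRUE) {
  df <- tibble::as_tibble(ds)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$energy, .data$intensity,
                                        colour = factor(signif(.data$q, 3)))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "energy transfer (meV)", y = "S(Q, E) (arb. units)",
                  colour = expression(Q ~ (ring(A)^{-1})),
                  title = qens_label(ds)) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a dynamic-susceptibility spectrum
#'
#' chi''(E) on log-log axes; relaxation processes appear as maxima, and a
#' minimum between two maxima is the model-free signature of two distinct
#' processes.
#'
#' @param chi Tibble from [susceptibility_transform()].
#' @return A ggplot object.
#' @export
plot_susceptibility <- function(chi) {
  df <- dplyr::filter(tibble::as_tibble(chi), .data$energy > 0, .data$chi > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$energy, .data$chi)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "energy transfer (meV)",
                  y = expression(chi * minute * minute * (E))) +
    ggplot2::theme_minimal()
}

#' Diagnostic plots for stage-1 per-Q fits
#'
#' @param object A `qens_perq_fit` tibble from [fit_dataset()].
#' @param ... Unused.
#' @return A ggplot object: half-widths and elastic fraction versus Q with
#'   1-sigma error bars.
#' @exportS3Method ggplot2::autoplot
autoplot.qens_perq_fit <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$term %in% c("a_q", "gamma_lat", "gamma_int"))
  ggplot2::ggplot(df, ggplot2::aes(.data$q, .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$estimate - .data$std.error,
      ymax = .data$estimate + .data$std.error)) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = expression(Q ~ (ring(A)^{-1})), y = NULL) +
    ggplot2::theme_minimal()
}

#' Overview plot of a fitted membrane analysis
#'
#' Three panels: lateral half-widths against `hbar Q^2` with the fitted
#' Fick line, the elastic fraction with the fitted sphere EISF, and the
#' internal half-widths with the fitted confined-diffusion curve.
#'
#' @param object A `qens_membrane_fit` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.qens_membrane_fit <- function(object, ...) {
  pq <- tibble::as_tibble(object$per_q)
  qfine <- seq(min(pq$q), max(pq$q), length.out = 80)
  hbar <- qens_constants$hbar
  panels <- dplyr::bind_rows(
    tibble::tibble(panel = "Gamma_lat (meV)", q = pq$q, y = pq$gamma_lat,
                   se = pq$gamma_lat_se),
    tibble::tibble(panel = "A(Q)", q = pq$q, y = pq$a_q, se = pq$a_q_se),
    tibble::tibble(panel = "Gamma_int (meV)", q = pq$q, y = pq$gamma_int,
                   se = pq$gamma_int_se)
  )
  curves <- dplyr::bind_rows(
    tibble::tibble(panel = "Gamma_lat (meV)", q = qfine,
                   y = hbar * object$fick_fit$d_lat * qfine^2),
    tibble::tibble(panel = "A(Q)", q = qfine,
                   y = sphere_eisf(qfine, object$eisf_fit$radius,
                                   object$eisf_fit$p_immobile)),
    tibble::tibble(panel = "Gamma_int (meV)", q = qfine,
                   y = vd_hwhm(qfine, object$dint_fit$d_int,
                               object$eisf_fit$radius))
  )
  ggplot2::ggplot(panels, ggplot2::aes(.data$q, .data$y)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$y - .data$se,
                                          ymax = .data$y + .data$se)) +
    ggplot2::geom_line(data = curves, colour = "steelblue") +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = expression(Q ~ (ring(A)^{-1})), y = NULL,
                  title = object$label) +
    ggplot2::theme_minimal()
}
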