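#' Construct a QENS dataset
#'
#' A QENS dataset is a long-format tibble with one row per (Q, energy) point
#' and columns `q` (wave-vector transfer, 1/A), `energy` (energy transfer,
#' meV), `intensity` (arbitrary units) and `uncertainty` (1-sigma counting
#' errors).  Sample temperature (K) and a free-text label travel as
#' attributes, readable with [qens_temperature()] and [qens_label()].
#'
#' Validation enforces the instrument sanity bounds: every Q in
#' \[0.3, 2.5\] 1/A (the backscattering detector bank spans roughly
#' 0.5-1.8 1/A), a strictly increasing energy grid of at least 8 points per
#' Q, equal-length columns and non-negative uncertainties.
#'
#' @param data Data frame with columns `q`, `energy`, `intensity`,
#'   `uncertainty`.
#' @param temperature Sample temperature in K (scalar, > 0).
#' @param label Free-text label, e.g. `"liver"`, `"liver+IL"`, `"D2O"`.
#' @return A tibble of class `qens_dataset`.
#' @examples
#' grid <- make_instrument_grid(q_values = c(0.7, 1.2))
#' ds <- qens_dataset(grid, temperature = 310.15, label = "demo")
#' qens_temperature(ds)
#' @export
qens_dataset <- function(data, temperature, label = "") {
  data <- tibble::as_tibble(data)
  required <- c("q", "energy", "intensity", "uncertainty")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("dataset is missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "qens_validation_error")
  }
  if (nrow(data) == 0) {
    abort("dataset has no rows", class = "qens_validation_error")
  }
  if (!is.numeric(temperature) || length(temperature) != 1 ||
      !is.finite(temperature) || temperature <= 0) {
    abort("temperature must be a positive scalar in K", class = "qens_validation_error")
  }
  qs <- unique(data$q)
  if (any(qs < 0.3 | qs > 2.5)) {
    abort("all q must lie within [0.3, 2.5] 1/A", class = "qens_validation_error")
  }
  for (qi in qs) {
    e <- data$energy[data$q == qi]
    if (length(e) < 8) {
      abort(sprintf("spectrum at Q = %g has fewer than 8 energy points", qi),
            class = "qens_validation_error")
    }
    if (any(diff(e) <= 0)) {
      abort(sprintf("energy grid at Q = %g is not strictly increasing", qi),
            class = "qens_validation_error")
    }
  }
  if (any(data$uncertainty < 0)) {
    abort("uncertainties must be >= 0", class = "qens_validation_error")
  }
  data <- dplyr::arrange(data, .data$q, .data$energy)
  attr(data, "temperature") <- as.numeric(temperature)
  attr(data, "label") <- as.character(label)
  class(data) <- unique(c("qens_dataset", class(data)))
  data
}

#' @rdname qens_dataset
#' @param ds A `qens_dataset`.
#' @export
qens_temperature <- function(ds) attr(ds, "temperature")

#' @rdname qens_dataset
#' @export
qens_label <- function(ds) attr(ds, "label")

#' Re-attach qens_dataset metadata after dplyr manipulation
#'
#' dplyr verbs return plain tibbles; this restores the class and the
#' temperature/label attributes from a template dataset.
#'
#' @param data A data frame derived from `template`.
#' @param template The original `qens_dataset`.
#' @return A `qens_dataset`.
#' @keywords internal
#' @export
qens_rewrap <- function(data, template) {
  qens_dataset(data,
               temperature = qens_temperature(template),
               label = qens_label(template))
}

#' Instrument grid skeleton
#'
#' Builds an empty-intensity dataset matching a backscattering-spectrometer
#' configuration: a uniform energy-transfer grid and a set of grouped Q
#' values.  The defaults emulate the IRIS PG(002) window: energy transfer
#' from -0.3 to +1.0 meV and 10 equally spaced Q groups covering
#' 0.5-1.8 1/A.
#'
#' @param emin,emax Energy window in meV; `emin < 0 < emax`.
#' @param n_e Number of energy points (>= 64).
#' @param q_values Strictly increasing Q values in 1/A.
#' @return A tibble with columns `q`, `energy`, `intensity` (0) and
#'   `uncertainty` (0), one block per Q.
#' @examples
#' grid <- make_instrument_grid()
#' dplyr::count(grid, q)
#' @export
make_instrument_grid <- function(emin = -0.3, emax = 1.0, n_e = 261,
                                 q_values = default_q_grid()) {
  if (!(emin < 0 && emax > 0)) {
    abort("energy window must satisfy emin < 0 < emax", class = "qens_validation_error")
  }
  if (n_e < 64) {
    abort("n_e must be >= 64", class = "qens_validation_error")
  }
  if (length(q_values) == 0 || any(diff(q_values) <= 0)) {
    abort("q_values must be non-empty and strictly increasing", class = "qens_validation_error")
  }
  energy <- seq(emin, emax, length.out = n_e)
  tidyr::expand_grid(q = q_values, energy = energy) |>
    dplyr::mutate(intensity = 0, uncertainty = 0)
}

#' @rdname make_instrument_grid
#' @param n_q Number of Q groups.
#' @param qmin,qmax Q range in 1/A.
#' @export
default_q_grid <- function(n_q = 10, qmin = 0.5, qmax = 1.8) {
  seq(qmin, qmax, length.out = n_q)
}

#' Resolution function
#'
#' The instrument resolution is either an analytic Gaussian of given FWHM
#' (default 0.017 meV, i.e. 17 ueV) or a measured elastic-scatterer
#' (vanadium) line shape supplied as a spectrum per Q.  All model spectra
#' are convolved with it before comparison with data.
#'
#' @param kind `"gaussian"` or `"measured"`.
#' @param fwhm Gaussian full width at half maximum in meV (for
#'   `kind = "gaussian"`).
#' @param spectra For `kind = "measured"`: a data frame with columns `q`,
#'   `energy`, `intensity` giving the measured line shape per Q.
#' @return An object of class `qens_resolution`.
#' @examples
#' res <- resolution_function()          # IRIS-like 17 ueV Gaussian
#' res$sigma                              # in meV
#' @export
resolution_function <- function(kind = c("gaussian", "measured"),
                                fwhm = 0.017, spectra = NULL) {
  kind <- match.arg(kind)
  if (kind == "gaussian") {
    if (!is.finite(fwhm) || fwhm <= 0) {
      abort("gaussian resolution fwhm must be > 0", class = "qens_validation_error")
    }
    out <- list(kind = "gaussian", fwhm = fwhm,
                sigma = fwhm / (2 * sqrt(2 * log(2))))
  } else {
    if (is.null(spectra) || !all(c("q", "energy", "intensity") %in% names(spectra))) {
      abort("measured resolution needs a data frame with q, energy, intensity",
            class = "qens_validation_error")
    }
    spectra <- tibble::as_tibble(spectra)
    areas <- spectra |>
      dplyr::group_by(.data$q) |>
      dplyr::summarise(area = trapz_area(.data$energy, .data$intensity))
    if (any(!is.finite(areas$area) | areas$area <= 0)) {
      abort("measured resolution must integrate to a finite positive area per Q",
            class = "qens_validation_error")
    }
    out <- list(kind = "measured", spectra = spectra)
  }
  structure(out, class = "qens_resolution")
}

trapz_area <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
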