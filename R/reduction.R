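#' Subtract a weighted solvent signal
#'
#' Removes the solvent (D2O buffer) contribution from a solution
#' measurement: `I_out = I_sample - weight * I_solvent` per (Q, energy)
#' point, with uncertainties combined in quadrature.  Negative residuals
#' are retained, not clamped, so downstream least-squares fits stay
#' unbiased.
#'
#' @param sample,solvent `qens_dataset`s on identical (Q, energy) grids.
#' @param weight Solvent weight fraction in \[0, 1\].
#' @return A `qens_dataset` with the sample's metadata.
#' @examples
#' # see generate_dataset(): a synthetic sample built as membrane +
#' # 0.95 * solvent subtracts back to the pure membrane signal
#' @export
subtract_solvent <- function(sample, solvent, weight) {
  if (!is.numeric(weight) || weight < 0 || weight > 1) {
    abort("weight must lie in [0, 1]", class = "qens_validation_error")
  }
  qs <- unique(sample$q)
  qv <- unique(solvent$q)
  bad <- qs[!vapply(qs, function(x) any(abs(qv - x) < 1e-9), logical(1))]
  if (length(bad) > 0 || nrow(sample) != nrow(solvent)) {
    abort(paste0("sample/solvent grid mismatch at Q = ",
                 paste(signif(bad, 6), collapse = ", ")),
          class = "qens_validation_error")
  }
  if (any(abs(sample$energy - solvent$energy) > 1e-9)) {
    abort("sample and solvent energy grids differ", class = "qens_validation_error")
  }
  out <- dplyr::mutate(tibble::as_tibble(sample),
    intensity = .data$intensity - weight * solvent$intensity,
    uncertainty = sqrt(.data$uncertainty^2 + (weight * solvent$uncertainty)^2)
  )
  qens_rewrap(out, sample)
}

#' Normalize a spectrum to its peak value
#'
#' Divides intensity and uncertainty by the intensity at the grid point
#' closest to zero energy transfer, so the normalized spectrum equals 1 at
#' that point.  Applied per Q when given a multi-Q dataset.  Idempotent.
#'
#' @param spec Data frame with `energy`, `intensity`, `uncertainty` (and
#'   optionally `q` for per-Q application).
#' @return Same shape, normalized.
#' @export
peak_normalize <- function(spec) {
  normalize_one <- function(df) {
    i0 <- which.min(abs(df$energy))
    s0 <- df$intensity[i0]
    if (!is.finite(s0) || s0 <= 0) {
      abort("non-positive intensity at E ~ 0; cannot peak-normalize",
            class = "qens_normalization_error")
    }
    dplyr::mutate(df,
      intensity = .data$intensity / s0,
      uncertainty = .data$uncertainty / s0
    )
  }
  is_ds <- inherits(spec, "qens_dataset")
  df <- tibble::as_tibble(spec)
  out <- if ("q" %in% names(df) && length(unique(df$q)) > 1) {
    df |>
      dplyr::group_by(.data$q) |>
      dplyr::group_modify(~ normalize_one(.x)) |>
      dplyr::ungroup()
  } else {
    normalize_one(df)
  }
  if (is_ds) qens_rewrap(out, spec) else out
}

#' Average a dataset over Q
#'
#' Unweighted mean of the intensity across the Q groups at each energy
#' point; uncertainties propagate as root-mean-square over sqrt(N).  All
#' spectra must share the energy grid.
#'
#' @param ds A `qens_dataset` (or data frame with `q`, `energy`,
#'   `intensity`, `uncertainty`).
#' @return A tibble with columns `energy`, `intensity`, `uncertainty`.
#' @export
q_average <- function(ds) {
  df <- tibble::as_tibble(ds)
  grids <- df |>
    dplyr::group_by(.data$q) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop")
  if (length(unique(grids$n)) != 1) {
    abort("spectra have inconsistent energy grids", class = "qens_validation_error")
  }
  e_by_q <- split(df$energy, df$q)
  e0 <- e_by_q[[1]]
  if (!all(vapply(e_by_q, function(e) max(abs(e - e0)) < 1e-9, logical(1)))) {
    abort("spectra have inconsistent energy grids", class = "qens_validation_error")
  }
  df |>
    dplyr::group_by(.data$energy) |>
    dplyr::summarise(
      uncertainty = sqrt(mean(.data$uncertainty^2)) / sqrt(dplyr::n()),
      intensity = mean(.data$intensity),
      .groups = "drop"
    ) |>
    dplyr::select("energy", "intensity", "uncertainty")
}

#' Dynamic-susceptibility transform
#'
#' Converts a Q-averaged intensity S(E) into the imaginary part of the
#' dynamic susceptibility by dividing by the Bose population factor in its
#' high-temperature approximation `n_B(E) ~ kB T / E` (valid for
#' `E << kB T`, amply satisfied in a +/- 1 meV window at physiological
#' temperatures): `chi''(E) = S(E) * E / (kB T)`.  Defined on the
#' energy-gain side `E >= 0`; the transform forces `chi''(0) = 0`.
#' A relaxation process of correlation time tau peaks at `E = hbar / tau`,
#' so the number of susceptibility maxima counts the relaxation processes
#' without any model fitting; two processes show two maxima separated by a
#' minimum.
#'
#' @param spec Data frame with `energy` (meV) and `intensity` columns
#'   (typically from [q_average()]).
#' @param temperature Temperature in K, > 0.
#' @param full_bose If `TRUE`, use the full Bose factor
#'   `1/(exp(E/kBT) - 1)` instead of the approximation.
#' @return A tibble with columns `energy` (E >= 0 points) and `chi`.
#' @export
susceptibility_transform <- function(spec, temperature, full_bose = FALSE) {
  if (!is.numeric(temperature) || temperature <= 0) {
    abort("temperature must be > 0", class = "qens_domain_error")
  }
  df <- tibble::as_tibble(spec) |>
    dplyr::filter(.data$energy >= 0)
  kbt <- qens_constants$kB * temperature
  chi <- if (full_bose) {
    ifelse(df$energy == 0, 0,
           df$intensity * (exp(df$energy / kbt) - 1))
  } else {
    df$intensity * df$energy / kbt
  }
  tibble::tibble(energy = df$energy, chi = chi, temperature = temperature)
}
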