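#' Ground-truth presets for the four measured membrane conditions
#'
#' Returns generator ground truth corresponding to the four experimental
#' conditions of the study (pristine liver-extract membrane and membrane
#' with the ionic liquid, at 37 and 57 degrees C), using the published
#' fitted values as the true parameters:
#'
#' | preset         | D_lat (1e-7 cm2/s) | p_x  | R (A) | D_int (1e-6 cm2/s) | T (K)  |
#' |----------------|--------------------|------|-------|--------------------|--------|
#' | liver_37C      | 11.6               | 0.41 | 2.8   | 12.3               | 310.15 |
#' | liver_IL_37C   | 13.3               | 0.43 | 2.8   | 14.9               | 310.15 |
#' | liver_57C      | 18.2               | 0.35 | 2.9   | 15.0               | 330.15 |
#' | liver_IL_57C   | 21.5               | 0.39 | 3.0   | 18.4               | 330.15 |
#'
#' @param name Preset name.
#' @param noise_level Relative counting-noise scale (fraction of the peak;
#'   see [generate_dataset()]).  Default 0.01.
#' @param seed Integer RNG seed.
#' @param mode `"effective"` (single effective internal Lorentzian of
#'   numerically computed width) or `"full"` (complete multi-Lorentzian
#'   internal scattering law).
#' @return A `qens_truth` list with diffusivities already converted to
#'   A^2/ps (`d_lat`, `d_int`), `p_immobile`, `radius` (A), `temperature`
#'   (K), `solvent_weight`, `noise_level`, `seed`, `mode`, `scale`,
#'   `background`.
#' @examples
#' preset("liver_37C")$d_lat   # 0.0116 A^2/ps
#' @export
preset <- function(name, noise_level = 0.01, seed = 1L,
                   mode = c("effective", "full")) {
  mode <- match.arg(mode)
  tab <- list(
    liver_37C    = list(d_lat7 = 11.6, p = 0.41, r = 2.8, d_int6 = 12.3, t = 310.15),
    liver_IL_37C = list(d_lat7 = 13.3, p = 0.43, r = 2.8, d_int6 = 14.9, t = 310.15),
    liver_57C    = list(d_lat7 = 18.2, p = 0.35, r = 2.9, d_int6 = 15.0, t = 330.15),
    liver_IL_57C = list(d_lat7 = 21.5, p = 0.39, r = 3.0, d_int6 = 18.4, t = 330.15)
  )
  if (!name %in% names(tab)) {
    abort(paste0("unknown preset '", name, "'; available: ",
                 paste(names(tab), collapse = ", ")),
          class = "qens_lookup_error")
  }
  p <- tab[[name]]
  qens_truth(
    d_lat = diffusivity_cm2s_to_A2ps(p$d_lat7 * 1e-7),
    p_immobile = p$p,
    radius = p$r,
    d_int = diffusivity_cm2s_to_A2ps(p$d_int6 * 1e-6),
    temperature = p$t,
    label = name,
    noise_level = noise_level,
    seed = seed,
    mode = mode
  )
}

#' @rdname preset
#' @param d_lat,d_int Diffusivities in A^2/ps.
#' @param p_immobile Immobile hydrogen fraction in \[0, 1\].
#' @param radius Confinement radius in A.
#' @param temperature Sample temperature in K.
#' @param label Free-text label.
#' @param solvent_weight Solvent fraction used when a solvent component is
#'   generated (default 0.95, a 5 percent w/w suspension surrogate).
#' @param scale Overall intensity scale.
#' @param background Flat background level.
#' @export
qens_truth <- function(d_lat, p_immobile, radius, d_int, temperature,
                       label = "synthetic", solvent_weight = 0.95,
                       noise_level = 0.01, seed = 1L,
                       mode = c("effective", "full"),
                       scale = 1, background = 0) {
  mode <- match.arg(mode)
  stopifnot(d_lat > 0, d_int > 0, radius > 0,
            p_immobile >= 0, p_immobile <= 1, temperature > 0,
            noise_level >= 0, scale > 0, background >= 0)
  structure(list(
    d_lat = d_lat, p_immobile = p_immobile, radius = radius, d_int = d_int,
    temperature = temperature, label = label,
    solvent_weight = solvent_weight, noise_level = noise_level,
    seed = as.integer(seed), mode = mode, scale = scale,
    background = background
  ), class = "qens_truth")
}

with_preserved_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic backscattering QENS dataset with known ground truth
#'
#' Emulates a grouped, reduced backscattering measurement of a lipid
#' membrane suspension: per Q group, the elastic fraction comes from the
#' partially mobile sphere EISF, the lateral width from Fick's law, and the
#' internal broadening either from the numerically computed effective
#' confined-diffusion half-width (`mode = "effective"`, the forward model
#' matched by the fitting stage) or from the complete multi-Lorentzian
#' confined-diffusion law (`mode = "full"`).  The model is convolved with
#' the instrument resolution, a flat background is added, and Gaussian
#' counting noise with standard deviation
#' `noise_level * sqrt(I(E) * I_peak)` is applied — the high-count limit of
#' Poisson statistics, normalized so the peak error is `noise_level` of the
#' peak intensity.  With `noise_level = 0` no noise is added and the quoted
#' uncertainties fall back to the 1 percent profile so weighted fits remain
#' defined.
#'
#' @param truth A `qens_truth` (see [preset()] / [qens_truth()]).
#' @param grid Instrument skeleton from [make_instrument_grid()].
#' @param resolution A [resolution_function()].
#' @param include_solvent If `TRUE`, also generate a broad-Lorentzian
#'   solvent (D2O surrogate, HWHM 0.1 meV) dataset, and add
#'   `truth$solvent_weight` times it to the sample so the pair exercises
#'   [subtract_solvent()].
#' @param eig Eigenvalue table for the confined-diffusion model.
#' @param oversample Convolution oversampling factor.
#' @return If `include_solvent` is `FALSE`, a `qens_dataset`; otherwise a
#'   list with elements `sample`, `solvent` and `truth`.
#' @examples
#' ds <- generate_dataset(preset("liver_37C", noise_level = 0),
#'                        grid = make_instrument_grid(n_e = 101,
#'                          q_values = c(0.6, 1.2)))
#' @export
generate_dataset <- function(truth, grid = make_instrument_grid(),
                             resolution = resolution_function(),
                             include_solvent = FALSE,
                             eig = vd_default_eigensystem(),
                             oversample = 4) {
  if (!inherits(truth, "qens_truth")) {
    abort("truth must be a qens_truth object", class = "qens_validation_error")
  }
  q_values <- unique(grid$q)
  energy <- grid$energy[grid$q == q_values[1]]

  model_q <- function(qi) {
    a_q <- sphere_eisf(qi, truth$radius, truth$p_immobile)
    g_lat <- fick_hwhm(qi, truth$d_lat)
    if (truth$mode == "effective") {
      g_int <- vd_hwhm(qi, truth$d_int, truth$radius, eig = eig)
      qens_model_spectrum(energy,
        list(a_q = a_q, gamma_lat = g_lat, gamma_int = g_int,
             scale = truth$scale, background = truth$background),
        resolution, oversample = oversample)
    } else {
      # full confined-diffusion law: elastic weight plus every quasielastic
      # mode, each broadened by the lateral Lorentzian (Lorentzian closure)
      modes <- vd_qe_modes(qi, truth$d_int, truth$radius, eig)
      w_el <- a_q  # p + (1-p)*EISF by construction of sphere_eisf
      p <- truth$p_immobile
      fn <- function(e) {
        y <- w_el * lorentzian(e, g_lat)
        for (k in seq_len(nrow(modes))) {
          y <- y + (1 - p) * modes$weight[k] *
            lorentzian(e, g_lat + modes$gamma[k])
        }
        truth$scale * y
      }
      convolve_model_fn(energy, fn, resolution, oversample = oversample) +
        truth$background
    }
  }

  clean <- purrr::map(q_values, model_q)
  solvent_clean <- NULL
  if (include_solvent) {
    solvent_one <- convolve_model_fn(energy,
      function(e) truth$scale * lorentzian(e, 0.1),
      resolution, oversample = oversample)
    solvent_clean <- purrr::map(q_values, ~solvent_one)
    clean <- purrr::map2(clean, solvent_clean,
                         ~ .x + truth$solvent_weight * .y)
  }

  err_level <- max(truth$noise_level, 0.01)
  build <- function(clean_list, seed_offset, label) {
    rows <- with_preserved_rng(truth$seed + seed_offset, {
      purrr::map2(q_values, clean_list, function(qi, y) {
        peak <- max(y)
        sigma <- err_level * sqrt(pmax(y, 0) * peak)
        noisy <- if (truth$noise_level > 0) {
          y + stats::rnorm(length(y), 0,
                           truth$noise_level * sqrt(pmax(y, 0) * peak))
        } else y
        tibble::tibble(q = qi, energy = energy, intensity = noisy,
                       uncertainty = sigma)
      })
    })
    qens_dataset(dplyr::bind_rows(rows), temperature = truth$temperature,
                 label = label)
  }

  sample_ds <- build(clean, 0L, truth$label)
  if (!include_solvent) return(sample_ds)
  list(
    sample = sample_ds,
    solvent = build(solvent_clean, 104729L, "D2O"),
    truth = truth
  )
}
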