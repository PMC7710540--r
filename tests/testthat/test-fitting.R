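res_gauss <- qensmem::resolution_function()

one_q_spectrum <- function(q, params, noise = 0, seed = 1, n_e = 181) {
  e <- seq(-0.3, 1.0, length.out = n_e)
  clean <- qensmem::qens_model_spectrum(e, params, res_gauss, q = q)
  peak <- max(clean)
  sigma <- pmax(noise, 0.01) * sqrt(pmax(clean, 0) * peak)
  set.seed(seed)
  y <- if (noise > 0) clean + rnorm(length(e), 0, noise * sqrt(pmax(clean, 0) * peak)) else clean
  tibble::tibble(q = q, energy = e, intensity = y, uncertainty = sigma)
}

truth_params <- list(a_q = 0.44, gamma_lat = 0.0114, gamma_int = 0.0604,
                     scale = 1.3, background = 0.02)

test_that("per-Q fit recovers noiseless model parameters to 0.1%", {
  spec <- one_q_spectrum(1.22, truth_params)
  fit <- fit_per_q(spec, res_gauss)
  expect_true(fit$converged)
  for (p in c("a_q", "gamma_lat", "gamma_int", "scale")) {
    expect_equal(fit[[p]], truth_params[[p]], tolerance = 1e-3)
  }
})

test_that("per-Q fit recovers noisy parameters within 3 sigma", {
  spec <- one_q_spectrum(1.22, truth_params, noise = 0.01, seed = 42)
  fit <- fit_per_q(spec, res_gauss)
  expect_true(fit$converged)
  expect_true(is.finite(fit$chi2_reduced))
  for (p in c("a_q", "gamma_lat", "gamma_int")) {
    expect_lt(abs(fit[[p]] - truth_params[[p]]), 3 * fit[[paste0(p, "_se")]])
  }
})

test_that("swapped width initialization converges back to the labeled ordering", {
  spec <- one_q_spectrum(1.22, truth_params)
  swapped <- c(a_q = 0.44, gamma_lat = 0.0604, gamma_int = 0.0114,
               scale = 1.3, background = 0.02)
  fit <- fit_per_q(spec, res_gauss, init = swapped)
  expect_true(fit$converged)
  expect_lt(fit$gamma_lat, fit$gamma_int)
  expect_equal(fit$gamma_lat, truth_params$gamma_lat, tolerance = 1e-3)
  expect_equal(fit$gamma_int, truth_params$gamma_int, tolerance = 1e-3)
})

test_that("per-Q fit input validation", {
  spec <- one_q_spectrum(1.22, truth_params, n_e = 181)
  expect_error(fit_per_q(spec[1:40, ], res_gauss), class = "qens_validation_error")
  bad <- dplyr::mutate(spec, uncertainty = 0)
  expect_error(fit_per_q(bad, res_gauss), class = "qens_validation_error")
})

test_that("Fick fit equals the closed-form oracle and inverts exact data", {
  q <- seq(0.5, 1.8, length.out = 8)
  d_true <- 0.0116
  exact <- tibble::tibble(q = q, gamma = fick_hwhm(q, d_true), sigma = 1e-4)
  f <- fit_dlat(exact)
  expect_equal(f$d_lat, d_true, tolerance = 1e-12)
  expect_equal(f$d_lat_cm2s, 11.6e-7, tolerance = 1e-10)

  # independently coded normal-equations oracle on perturbed data
  set.seed(7)
  pert <- dplyr::mutate(exact,
    gamma = gamma * (1 + 0.05 * rnorm(length(q))),
    sigma = 0.05 * gamma)
  f2 <- fit_dlat(pert)
  x <- qens_constants$hbar * pert$q^2
  w <- 1 / pert$sigma^2
  oracle <- solve(t(x * w) %*% x, t(x * w) %*% pert$gamma)[1, 1]
  expect_equal(f2$d_lat, oracle, tolerance = 1e-10)
  expect_lt(abs(f2$d_lat - d_true), 3 * f2$d_lat_se)

  expect_error(fit_dlat(exact[1:3, ]), class = "qens_validation_error")
})

test_that("EISF fit recovers geometry, flags flat input, handles noise", {
  q <- qensmem::default_q_grid()
  pts <- tibble::tibble(q = q, a = sphere_eisf(q, 2.8, 0.41), sigma = 0.005)
  f <- fit_eisf(pts)
  expect_true(f$identifiable)
  expect_equal(f$p_immobile, 0.41, tolerance = 1e-3)
  expect_equal(f$radius, 2.8, tolerance = 1e-3)

  flat <- tibble::tibble(q = q, a = 1, sigma = 0.005)
  expect_false(fit_eisf(flat)$identifiable)

  set.seed(11)
  noisy <- dplyr::mutate(pts, a = pmin(a + 0.02 * rnorm(length(q)), 1))
  fn <- fit_eisf(dplyr::mutate(noisy, sigma = 0.02))
  expect_lt(abs(fn$p_immobile - 0.41), 3 * fn$p_immobile_se)
  expect_lt(abs(fn$radius - 2.8), 3 * fn$radius_se)

  expect_error(fit_eisf(pts[1:4, ]), class = "qens_validation_error")
})

test_that("internal-diffusion fit inverts the numerical half-width curve", {
  q <- qensmem::default_q_grid()
  d_true <- 0.123
  gam <- vd_hwhm(q, d_true, 2.8)
  pts <- tibble::tibble(q = q, gamma = gam, sigma = 0.002)
  f <- fit_dint(pts, p_immobile = 0.41, radius = 2.8)
  expect_equal(f$d_int, d_true, tolerance = 5e-3)
  expect_equal(f$fixed$source, "eisf_fit")

  # widths are linear in D: doubling Gamma doubles the fit
  f2 <- fit_dint(dplyr::mutate(pts, gamma = 2 * gamma), 0.41, 2.8)
  expect_equal(f2$d_int, 2 * f$d_int, tolerance = 1e-9)

  set.seed(3)
  noisy <- dplyr::mutate(pts, gamma = gamma * (1 + 0.05 * rnorm(length(q))),
                         sigma = 0.05 * gamma)
  f3 <- fit_dint(noisy, 0.41, 2.8)
  expect_lt(abs(f3$d_int - d_true), 3 * f3$d_int_se)

  expect_error(fit_dint(pts[1:3, ], 0.41, 2.8), class = "qens_validation_error")
  expect_error(fit_dint(pts, 0.41, -2), class = "qens_domain_error")
})

test_that("pipeline inverts a noiseless synthetic dataset within 1%", {
  tr <- preset("liver_37C", noise_level = 0)
  sim <- generate_dataset(tr, grid = small_grid())
  fit <- run_pipeline(sim)
  expect_equal(fit$fick_fit$d_lat, tr$d_lat, tolerance = 0.01)
  expect_equal(fit$eisf_fit$p_immobile, tr$p_immobile, tolerance = 0.01)
  expect_equal(fit$eisf_fit$radius, tr$radius, tolerance = 0.01)
  expect_equal(fit$dint_fit$d_int, tr$d_int, tolerance = 0.01)
  # internal motion is the faster process at every converged Q
  ok <- fit$per_q[fit$per_q$converged, ]
  expect_true(all(ok$gamma_int > ok$gamma_lat))
  # tidy/glance accessors
  td <- tidy(fit)
  expect_equal(td$term, c("d_lat", "p_immobile", "radius", "d_int"))
  expect_equal(glance(fit)$n_converged, nrow(fit$per_q))
})

test_that("pipeline with solvent component subtracts and recovers within 2%", {
  tr <- preset("liver_37C", noise_level = 0)
  pair <- generate_dataset(tr, grid = small_grid(), include_solvent = TRUE)
  fit <- run_pipeline(pair$sample, solvent = pair$solvent,
                      solvent_weight = tr$solvent_weight)
  expect_equal(fit$fick_fit$d_lat, tr$d_lat, tolerance = 0.02)
  expect_equal(fit$eisf_fit$p_immobile, tr$p_immobile, tolerance = 0.02)
  expect_equal(fit$eisf_fit$radius, tr$radius, tolerance = 0.02)
  expect_equal(fit$dint_fit$d_int, tr$d_int, tolerance = 0.02)
})

test_that("pipeline rejects empty input without partial output", {
  expect_error(run_pipeline(NULL), class = "qens_validation_error")
})
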