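test_that("Lorentzian line shape: peak, half-height and area", {
  g <- 0.02
  expect_equal(lorentzian(0, g), 1 / (pi * g))
  expect_equal(lorentzian(g, g), 0.5 / (pi * g))
  e <- seq(-50 * g, 50 * g, length.out = 20001)
  area <- sum(lorentzian(e, g)) * (e[2] - e[1])
  expect_equal(area, 2 / pi * atan(50), tolerance = 1e-4)
  expect_error(lorentzian(0, 0), class = "qens_domain_error")
})

test_that("Fickian half-width is quadratic through the origin", {
  expect_equal(fick_hwhm(0, 0.0116), 0)
  expect_equal(fick_hwhm(1.0, 0.0116), 7.635e-3, tolerance = 1e-4)
  expect_equal(fick_hwhm(1.8, 0.0116), 0.02474, tolerance = 1e-4)
  expect_error(fick_hwhm(-1, 0.01), class = "qens_domain_error")
})

test_that("sphere EISF limits and zero", {
  expect_equal(sphere_eisf(0, 2.8, 0.2), 1)
  expect_equal(sphere_eisf(c(0.4, 1.1, 2.0), 3.0, 1), rep(1, 3))
  root <- 4.493409458
  for (px in c(0, 0.41, 0.9)) {
    expect_equal(sphere_eisf(root / 2.8, 2.8, px), px, tolerance = 1e-9)
  }
  a <- sphere_eisf(seq(0, 2, by = 0.05), 2.8, 0.41)
  expect_true(all(a >= 0 & a <= 1))
  expect_error(sphere_eisf(1, -2, 0.5), class = "qens_domain_error")
})

test_that("composite law reduces to single Lorentzians at the A extremes", {
  e <- seq(-0.3, 0.3, by = 0.002)
  p1 <- list(a_q = 1, gamma_lat = 0.01, gamma_int = 0.05, scale = 2, background = 0)
  expect_equal(composite_sqw(e, p1), 2 * lorentzian(e, 0.01))
  p0 <- list(a_q = 0, gamma_lat = 0.01, gamma_int = 0.05, scale = 2, background = 0)
  expect_equal(composite_sqw(e, p0), 2 * lorentzian(e, 0.06))
})

test_that("composite law: symmetry, area and width monotonicity", {
  e <- seq(-2, 2, by = 0.001)
  p <- list(a_q = 0.6, gamma_lat = 0.008, gamma_int = 0.04, scale = 1.7,
            background = 0.05)
  s <- composite_sqw(e, p)
  expect_equal(s, rev(s))
  area <- sum(s) * (e[2] - e[1])
  expect_equal(area, p$scale + p$background * diff(range(e)), tolerance = 0.02)
  # increasing the internal width strictly lowers the peak
  p_wide <- modifyList(p, list(gamma_int = 0.08))
  expect_lt(composite_sqw(0, p_wide), composite_sqw(0, p))
  expect_error(composite_sqw(e, modifyList(p, list(a_q = 1.2))),
               class = "qens_domain_error")
})

test_that("convolution with a delta reproduces the resolution line shape", {
  res <- resolution_function()
  e <- seq(-0.3, 0.3, by = 0.002)
  d <- convolve_resolution(e, rep(0, length(e)), res, elastic_weight = 1)
  expect_equal(max(d), dnorm(0, sd = res$sigma), tolerance = 1e-6)
  expect_equal(sum(d) * (e[2] - e[1]), 1, tolerance = 1e-6)
})

test_that("convolution smooths, preserves area and is linear", {
  res <- resolution_function()
  e <- seq(-0.5, 0.5, by = 0.002)
  lor <- lorentzian(e, 0.01)
  conv <- convolve_model_fn(e, function(x) lorentzian(x, 0.01), res)
  expect_lt(max(conv), min(max(lor), dnorm(0, sd = res$sigma)))
  expect_equal(sum(conv) / sum(lor), 1, tolerance = 0.01)
  f1 <- convolve_resolution(e, lorentzian(e, 0.02), res)
  f2 <- convolve_resolution(e, lorentzian(e, 0.1), res)
  f12 <- convolve_resolution(e, 2 * lorentzian(e, 0.02) + 3 * lorentzian(e, 0.1), res)
  expect_equal(f12, 2 * f1 + 3 * f2, tolerance = 1e-12)
})

test_that("oversampled convolution matches a dense-quadrature Voigt oracle", {
  res <- resolution_function(fwhm = 0.017)
  e <- seq(-0.3, 1.0, length.out = 261)
  conv <- convolve_model_fn(e, function(x) lorentzian(x, 0.01), res)
  inner <- abs(e) <= 0.3
  voigt <- vapply(e[inner], function(ee) {
    integrate(function(x) lorentzian(x, 0.01) * dnorm(ee - x, sd = res$sigma),
              -Inf, Inf, rel.tol = 1e-10)$value
  }, numeric(1))
  expect_true(all(abs(conv[inner] - voigt) / voigt < 1e-4))
})

test_that("measured resolution requires a matching Q spectrum", {
  van <- tibble::tibble(q = 0.7, energy = seq(-0.1, 0.1, by = 0.001),
                        intensity = dnorm(seq(-0.1, 0.1, by = 0.001), sd = 0.007))
  res <- resolution_function("measured", spectra = van)
  e <- seq(-0.3, 0.3, by = 0.002)
  out <- convolve_resolution(e, rep(0, length(e)), res, elastic_weight = 1, q = 0.7)
  expect_equal(sum(out) * 0.002, 1, tolerance = 0.01)
  expect_error(
    convolve_resolution(e, rep(0, length(e)), res, elastic_weight = 1, q = 1.5),
    class = "qens_validation_error")
  expect_error(resolution_function("gaussian", fwhm = -1),
               class = "qens_validation_error")
})
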