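test_that("eigenvalues are roots of j_l' with the exact ground mode", {
  eig <- vd_eigenvalues(3, 3)
  expect_equal(eig$x[eig$l == 0 & eig$n == 0], 0)
  # frozen values from independent bisection of j_l'(x) = 0
  expect_equal(eig$x[eig$l == 1 & eig$n == 1], 2.081575978, tolerance = 1e-8)
  expect_equal(eig$x[eig$l == 0 & eig$n == 1], 4.493409458, tolerance = 1e-8)
  expect_equal(eig$x[eig$l == 2 & eig$n == 1], 3.342093657, tolerance = 1e-8)
  nz <- eig[!(eig$l == 0 & eig$n == 0), ]
  expect_true(all(abs(mapply(sph_bessel_j_deriv, nz$l, nz$x)) <= 1e-10))
  for (lv in unique(nz$l)) {
    xs <- nz$x[nz$l == lv][order(nz$n[nz$l == lv])]
    expect_true(all(diff(xs) > 0))
  }
  expect_false(is.unsorted(eig$x))
  expect_error(vd_eigenvalues(-1, 1), class = "qens_domain_error")
})

test_that("mode weights reproduce the closed-form elastic fraction", {
  for (qr in c(0.5, 2, 4.2)) {
    sf <- vd_structure_factors(qr)
    expect_equal(sf$a[sf$l == 0 & sf$n == 0],
                 (3 * sph_bessel_j(1, qr) / qr)^2, tolerance = 1e-10)
  }
  sf0 <- vd_structure_factors(0)
  expect_equal(sf0$a[sf0$l == 0 & sf0$n == 0], 1)
  expect_true(all(sf0$a[!(sf0$l == 0 & sf0$n == 0)] < 1e-12))
  # elastic fraction vanishes where j_1 has its first zero
  root <- vd_eigenvalues(0, 1)$x[2]   # j_0' = -j_1
  sfr <- vd_structure_factors(root)
  expect_lt(sfr$a[sfr$l == 0 & sfr$n == 0], 1e-9)
  expect_error(vd_structure_factors(-1), class = "qens_domain_error")
})

test_that("completeness sum rule holds to 1e-3 over the instrument QR range", {
  for (qr in seq(0, 5.4, by = 0.45)) {
    sf <- vd_structure_factors(qr)
    qe <- sf[!(sf$l == 0 & sf$n == 0), ][1:100, ]
    total <- sf$a[sf$l == 0 & sf$n == 0] + sum((2 * qe$l + 1) * qe$a)
    expect_gte(total, 1 - 1e-3)
    expect_lte(total, 1 + 1e-6)
  }
})

test_that("scattering law is normalized and degenerates correctly", {
  frozen <- vd_sqw(1.0, seq(-1, 1, by = 0.01), d_int = 0.123, radius = 2.8,
                   p_immobile = 1)
  expect_equal(frozen$elastic_weight, 1)
  expect_true(all(frozen$quasielastic == 0))

  # adaptive-quadrature normalization oracle at QR <= 5.4
  for (q in c(0.5, 1.9)) {
    m <- vd_sqw(q, 0, d_int = 0.123, radius = 2.8, p_immobile = 0.41)
    f <- function(e) vd_sqw(q, e, 0.123, 2.8, 0.41)$quasielastic
    area <- integrate(f, -Inf, Inf, rel.tol = 1e-8)$value
    expect_equal(m$elastic_weight + area, 1, tolerance = 2e-3)
  }
  expect_error(vd_sqw(1, 0, -1, 2.8, 0.5), class = "qens_domain_error")
  expect_error(vd_sqw(1, 0, 0.1, 2.8, 1.5), class = "qens_domain_error")
})

test_that("spectral ISF matches a reflecting-sphere random walk", {
  radius <- 2.8; d <- 0.123; q <- 2 / radius
  times <- c(0.05, 0.2, 1) * radius^2 / d
  mc <- mc_sphere_isf(q, radius, d, times, n_walkers = 2e4, n_steps = 400,
                      seed = 11)
  spectral <- vd_isf(q, times, d, radius)
  expect_true(all(abs(spectral - mc$isf) < 3 * mc$se + 0.01))
})

test_that("numerical half-width has the confined plateau and scaling laws", {
  d <- 0.123; r <- 2.8
  x11 <- 2.081575978
  plateau <- hbar * x11^2 * d / r^2
  expect_equal(vd_hwhm(0.05 / r, d, r), plateau, tolerance = 0.01)

  # linear in D (scale covariance)
  h1 <- vd_hwhm(1.2, d, r)
  expect_equal(vd_hwhm(1.2, 3 * d, r), 3 * h1, tolerance = 1e-9)

  # depends on (Q, R) only through QR and D/R^2 (shape covariance)
  s <- 2
  expect_equal(vd_hwhm(1.2 / s, d, s * r) * s^2, h1, tolerance = 1e-9)

  # monotone non-decreasing in Q
  hs <- vd_hwhm(seq(0.1, 2.0, by = 0.1), d, r)
  expect_true(all(diff(hs) >= -1e-12))

  expect_error(vd_hwhm(-1, d, r), class = "qens_domain_error")
})

test_that("half-width approaches the free-diffusion law slowly from below", {
  # Monte-Carlo-validated value: Gamma/(hbar D Q^2) = 0.785 at QR = 12,
  # rising monotonically toward 1 at larger QR
  d <- 0.123; r <- 2.8
  eig <- vd_eigenvalues(40, 15)
  ratio12 <- vd_hwhm(12 / r, d, r, eig = eig, n_terms = nrow(eig)) /
    (hbar * d * (12 / r)^2)
  expect_equal(ratio12, 0.785, tolerance = 0.01)
  ratio20 <- vd_hwhm(20 / r, d, r, eig = eig, n_terms = nrow(eig)) /
    (hbar * d * (20 / r)^2)
  expect_gt(ratio20, ratio12)
})

test_that("eigenvalue table exports as TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_eigensystem_tsv(vd_eigenvalues(2, 2), path)
  tab <- read.delim(path)
  expect_equal(names(tab), c("l", "n", "x_nl"))
  expect_equal(nrow(tab), 7)
})
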