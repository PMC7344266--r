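test_that("flat relative uncertainty scales |Rrs| per band", {
  s <- spectrum(c(443, 555), c(0.010, 0.002))
  expect_equal(flat_u(s, 0.05)$values, c(5.0e-4, 1.0e-4))
  expect_equal(flat_u(s, 0)$values, c(0, 0))
  expect_equal(flat_u(spectrum(490, 0.008), 0.10)$values, 8.0e-4)
  # applied to |Rrs| for rare negative bands
  sn <- spectrum(c(443, 555), c(-0.001, 0.002))
  expect_equal(flat_u(sn, 0.05)$values, c(5.0e-5, 1.0e-4))
  expect_error(flat_u(s, -0.1), "non-negative")
})

test_that("surface lookup is bilinear with chl extrapolation above the grid", {
  surf <- rel_uncertainty_surface(c(0.1, 0.2), c(443, 555),
                                  rbind(c(0.02, 0.04), c(0.06, 0.08)))
  s1 <- spectrum(499, 0.01)   # wavelength midpoint
  expect_equal(surface_u(surf, s1, 0.15)$values, 0.05 * 0.01)
  # grid hit returns the table value
  expect_equal(surface_u(surf, spectrum(443, 0.01), 0.1)$values, 2e-4)
  # linear extrapolation above the top chl level
  surf2 <- rel_uncertainty_surface(c(0.1, 0.2), c(443, 555),
                                   rbind(c(0.02, 0.02), c(0.04, 0.04)))
  expect_equal(surface_u(surf2, spectrum(443, 0.01), 0.3)$values, 6e-4)
  # clamped below the bottom level
  expect_equal(surface_u(surf2, spectrum(443, 0.01), 0.01)$values, 2e-4)
  # wavelength is never extrapolated
  expect_error(surface_u(surf, spectrum(412, 0.01), 0.1), "extrapolated")
})

test_that("surface lookup is continuous in chl and reduces to flat_u", {
  surf <- rel_uncertainty_surface(c(0.1, 0.2, 0.5), c(412, 710),
                                  rbind(c(0.02, 0.04), c(0.06, 0.08),
                                        c(0.07, 0.09)))
  s <- spectrum(c(500, 600), c(0.004, 0.002))
  eps <- 1e-9
  for (lvl in c(0.2, 0.5)) {
    lo <- surface_u(surf, s, lvl - eps)$values
    hi <- surface_u(surf, s, lvl + eps)$values
    expect_equal(lo, hi, tolerance = 1e-6)
  }
  flat_surf <- rel_uncertainty_surface(c(0.1, 0.2), c(412, 710),
                                       matrix(0.05, 2, 2))
  expect_equal(surface_u(flat_surf, s, 0.13)$values, flat_u(s, 0.05)$values)
})

test_that("build_covariance forms V_ij = corr * u_i u_j and validates corr", {
  u <- spectrum(c(443, 555), c(1e-4, 2e-4), "u_Rrs")
  V <- build_covariance(u)
  expect_equal(V$matrix, diag(c(1e-8, 4e-8)), ignore_attr = TRUE)

  ones <- matrix(1, 2, 2)
  V1 <- build_covariance(spectrum(c(443, 555), c(1e-4, 1e-4), "u_Rrs"), ones)
  expect_equal(as.numeric(V1$matrix), rep(1e-8, 4))

  anti <- matrix(c(1, -1, -1, 1), 2)
  V2 <- build_covariance(u, anti)
  expect_equal(V2$matrix[1, 2], -1e-4 * 2e-4)

  expect_error(build_covariance(u, matrix(c(1, 0.5, 0.2, 1), 2)), "symmetric")
  expect_error(build_covariance(u, matrix(c(2, 0, 0, 2), 2)), "diagonal")
  expect_error(build_covariance(u, matrix(c(1, 1.5, 1.5, 1), 2)),
               "\\[-1, 1\\]")
})

test_that("valid correlation matrices always yield valid covariances", {
  set.seed(11)
  for (k in 1:20) {
    n <- 5
    A <- matrix(rnorm(n * n), n)
    S <- crossprod(A) + diag(1e-6, n)
    corr <- stats::cov2cor(S)
    u <- spectrum(sort(runif(n, 400, 700)), runif(n, 1e-5, 1e-3), "u_Rrs")
    expect_s3_class(build_covariance(u, corr), "spectral_covariance")
  }
})

test_that("the bundled synthetic surface fixture loads and evaluates", {
  path <- system.file("extdata",
                      "synthetic_rrs_relative_uncertainty_surface.csv",
                      package = "fofmoc")
  surf <- read_uncertainty_surface_csv(path)
  expect_equal(surf$wavelengths, default_band_centers())
  s <- fixture_rrs()
  u <- surface_u(surf, s, 0.08)
  expect_true(all(u$values > 0))
  # relative uncertainty grows toward the red in the fixture
  rel <- u$values / abs(s$values)
  expect_true(all(diff(rel) > 0))
})
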