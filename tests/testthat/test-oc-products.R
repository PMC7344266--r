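test_that("band-ratio chlorophyll selects the maximum ratio band", {
  s <- fixture_rrs()
  # ratio-independent polynomial
  r <- chl_br(s, ocx_coefficients(poly = c(0.5, 0, 0, 0, 0)))
  expect_equal(r$value, 10^0.5)

  wl <- c(443, 490, 510, 555)
  s2 <- spectrum(wl, c(0.004, 0.006, 0.003, 0.003), "Rrs")
  r2 <- chl_br(s2, ocx_coefficients(blue_bands = c(443, 490, 510)))
  expect_equal(r2$active_blue, 490)
  expect_equal(r2$gradient[3], 0)  # inactive blue band carries no gradient

  s3 <- spectrum(wl, c(0.004, 0.006, 0.003, -0.01), "Rrs")
  expect_error(chl_br(s3), "non-positive")
})

test_that("line-height chlorophyll has its closed-form gradient", {
  s_flat <- spectrum(c(443, 555, 665), c(0.003, 0.003, 0.003), "Rrs")
  lh <- lh_chl_coefficients()
  r <- chl_lh(s_flat, lh)
  expect_equal(r$ci, 0)
  expect_equal(r$value, 10^lh$b0)

  # exactly linear spectrum has zero line height
  s_lin <- spectrum(c(443, 555, 665), 0.001 + 1e-5 * (c(443, 555, 665) - 443))
  expect_equal(chl_lh(s_lin, lh)$ci, 0, tolerance = 1e-15)

  w <- (555 - 443) / (665 - 443)
  r2 <- chl_lh(spectrum(c(443, 555, 665), c(0.004, 0.0035, 0.002)), lh)
  fac <- log(10) * lh$b1 * r2$value
  expect_equal(r2$gradient, c(-(1 - w) * fac, fac, -w * fac))
})

test_that("blended chlorophyll interpolates between branches", {
  w <- blend_window(0.15, 0.2)
  batch <- fixture_batch(40, seed = 9)
  lhv <- vapply(batch, function(s) chl_lh(s)$value, numeric(1))
  lo <- batch[lhv <= w$t_low]
  hi <- batch[lhv >= w$t_high]
  mid <- batch[lhv > w$t_low & lhv < w$t_high]
  if (length(lo)) {
    r <- chl_blend(lo[[1]], w = w)
    expect_identical(r$branch, "LH")
    expect_equal(r$value, chl_lh(lo[[1]])$value)
  }
  if (length(hi)) {
    r <- chl_blend(hi[[1]], w = w)
    expect_identical(r$branch, "BR")
    expect_equal(r$value, chl_br(hi[[1]])$value)
  }
  if (length(mid)) {
    r <- chl_blend(mid[[1]], w = w)
    expect_identical(r$branch, "blended")
    expect_equal(r$value,
                 r$alpha * r$chl_br + (1 - r$alpha) * r$chl_lh)
    expect_equal(r$alpha, (r$chl_lh - w$t_low) / (w$t_high - w$t_low))
  }
})

test_that("blended chlorophyll is continuous in Rrs across window edges", {
  # scale a base spectrum so chl_lh crosses each edge; value must be
  # continuous in the scale factor
  base <- fixture_rrs()
  w <- blend_window(0.15, 0.2)
  for (edge in c(w$t_low, w$t_high)) {
    f <- function(scl) {
      chl_blend(spectrum(base$wavelengths, base$values * scl), w = w)$value
    }
    # find a scale where chl_lh is near the edge
    g <- function(scl) chl_lh(spectrum(base$wavelengths,
                                       base$values * scl))$value - edge
    scl0 <- uniroot(g, c(0.05, 6))$root
    eps <- 1e-7
    expect_equal(f(scl0 - eps), f(scl0 + eps), tolerance = 1e-4)
  }
})

test_that("Kd490 has the pure-water floor and consistent gradient", {
  s <- fixture_rrs()
  r0 <- kd490(s, kd490_coefficients(poly = rep(0, 5)))
  expect_equal(r0$value, 0.0166 + 1)
  r <- kd490(s)
  expect_equal(propagate_uncorrelated(r$gradient, flat_u(s, 0)$values), 0)
})

test_that("POC power law and its constant relative uncertainty", {
  s <- fixture_rrs()
  i1 <- nearest_band(s, 443); i2 <- nearest_band(s, 555)
  v <- s$values; v[i1] <- v[i2]          # unit ratio
  expect_equal(poc(spectrum(s$wavelengths, v))$value, 203.2)
  v[i1] <- 2 * v[i2]                     # ratio 2
  expect_equal(poc(spectrum(s$wavelengths, v))$value, 203.2 * 2^-1.034)

  # constancy of the propagated relative uncertainty across spectra
  rel <- vapply(fixture_batch(25, seed = 13), function(sp) {
    r <- poc(sp)
    100 * propagate_uncorrelated(r$gradient, flat_u(sp, 0.05)$values) /
      r$value
  }, numeric(1))
  expect_equal(rel, rep(abs(-1.034) * sqrt(2) * 5, 25), tolerance = 1e-12)

  expect_error(poc(spectrum(c(443, 555), c(-0.001, 0.002))), "positive")
})

test_that("nflh is the linear height above the baseline", {
  b <- nflh_bands(667, 678, 748)
  wl <- c(667, 678, 748)
  expect_equal(nflh(spectrum(wl, c(1, 1, 1), "nLw"), b)$value, 0)
  r <- nflh(spectrum(wl, c(1.0, 1.2, 0.8), "nLw"), b)
  expect_equal(r$value, 1.2 - (1.0 - 0.2 * 11 / 81), tolerance = 1e-12)
  expect_equal(r$value, 0.2271605, tolerance = 1e-6)
  # gradient is the constant coefficient vector of the linear form
  w <- 11 / 81
  expect_equal(r$gradient, c(-(1 - w), 1, -w))
})

test_that("every analytic gradient matches central differences", {
  batch <- fixture_batch(30, seed = 21)
  models <- list(
    chl_br = function(s) chl_br(s),
    chl_lh = function(s) chl_lh(s),
    kd490 = function(s) kd490(s),
    poc = function(s) poc(s),
    nflh = function(s) nflh(s)  # linear; exercised on Rrs values directly
  )
  for (s in batch) {
    for (nm in names(models)) {
      res <- models[[nm]](s)
      gn <- numeric_gradient(models[[nm]], s)
      expect_lt(grad_relerr(res$gradient, gn), 1e-6)
    }
    # blended chl away from window edges
    r <- chl_blend(s)
    lhv <- chl_lh(s)$value
    if (min(abs(lhv - c(0.15, 0.2))) > 1e-3) {
      gn <- numeric_gradient(function(x) chl_blend(x), s)
      expect_lt(grad_relerr(r$gradient, gn), 1e-5)
    }
  }
})

test_that("product uncertainties scale exactly with flat relative uncertainty", {
  s <- fixture_batch(5, seed = 31)[[3]]
  models <- product_models_for_tests()
  for (m in models) {
    res <- m(s)
    u1 <- propagate_uncorrelated(res$gradient, flat_u(s, 0.01)$values)
    u5 <- propagate_uncorrelated(res$gradient, flat_u(s, 0.05)$values)
    u10 <- propagate_uncorrelated(res$gradient, flat_u(s, 0.10)$values)
    expect_equal(u5, 5 * u1, tolerance = 1e-12)
    expect_equal(u10, 10 * u1, tolerance = 1e-12)
  }
})

test_that("Rrs to nLw conversion multiplies by the solar irradiance table", {
  s <- fixture_rrs()
  nlw <- rrs_to_nlw(s)
  f0 <- default_solar_irradiance()
  expect_equal(nlw$values, s$values * f0$values)
  expect_identical(nlw$quantity_tag, "nLw")
  expect_identical(rrs_to_nlw(flat_u(s, 0.05))$quantity_tag, "u_nLw")
})
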