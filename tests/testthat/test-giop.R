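unit_cfg <- function(a0 = 0.1, bb0 = 0.01) {
  # degenerate configuration with constant water terms and unit shapes,
  # so forward-model arithmetic is transparent
  wl <- default_band_centers()
  giop_config(fit_bands = wl[wl <= 655],
              aphi_star = spectrum(wl, rep(1, 16), "a"),
              aw = spectrum(wl, rep(a0, 16), "a"),
              bbw = spectrum(wl, rep(bb0, 16), "bb"))
}

test_that("the air-water reflectance transform and its inverse round-trip", {
  expect_equal(rrs_from_Rrs(0), 0)
  expect_equal(rrs_from_Rrs(0.01), 0.01 / 0.537)
  expect_equal(rrs_from_Rrs(0.01), 0.0186220, tolerance = 1e-5)
  x <- seq(0, 0.05, length.out = 41)
  expect_equal(Rrs_from_rrs(rrs_from_Rrs(x)), x, tolerance = 1e-12)
  # derivative matches central differences
  h <- 1e-7
  num <- (rrs_from_Rrs(0.01 + h) - rrs_from_Rrs(0.01 - h)) / (2 * h)
  expect_equal(drrs_dRrs(0.01), num, tolerance = 1e-8)
})

test_that("forward model reproduces direct arithmetic", {
  cfg <- unit_cfg()
  # a = 0.1, bb = 0.01 -> u = 1/11
  r <- giop_forward(c(0, 0, 0), gamma = 1, cfg)
  u <- 1 / 11
  expect_equal(r$values, rep(0.0949 * u + 0.0794 * u^2, length(cfg$fit_bands)))
  expect_equal(r$values[1], 0.0092835, tolerance = 1e-5)
  # with the quadratic term off, rrs = g1 * u exactly
  cfg2 <- giop_config(fit_bands = cfg$fit_bands, g2 = 0,
                      aphi_star = spectrum(default_band_centers(), rep(1, 16), "a"),
                      aw = spectrum(default_band_centers(), rep(0.1, 16), "a"),
                      bbw = spectrum(default_band_centers(), rep(0.01, 16), "bb"))
  expect_equal(giop_forward(c(0, 0, 0), 1, cfg2)$values,
               rep(0.0949 / 11, length(cfg2$fit_bands)))
  # water-only spectrum is strictly positive for the default config
  expect_true(all(giop_forward(c(0, 0, 0), 1, giop_config())$values > 0))
})

test_that("the backscattering-slope rule is deterministic and monotone", {
  cfg <- giop_config()
  rrs <- giop_forward(c(0.1, 0.01, 1e-3), 1, cfg)
  g1 <- gamma_from_rrs(rrs, cfg)$gamma
  expect_identical(gamma_from_rrs(rrs, cfg)$gamma, g1)
  # degenerate rule (p2 = 0) returns the constant p1
  cfgc <- giop_config(gamma_rule = list(p1 = 1.5, p2 = 0, p3 = 0.9,
                                        bands = c(443, 555)))
  expect_equal(gamma_from_rrs(rrs, cfgc)$gamma, 1.5)
  # monotone in the band ratio over a dense grid
  gam <- vapply(seq(0.2, 5, length.out = 60), function(rho) {
    s <- spectrum(c(443, 555), c(rho * 0.004, 0.004), "rrs")
    gamma_from_rrs(s, cfg)$gamma
  }, numeric(1))
  expect_true(all(diff(gam) > 0))
  # analytic gradient matches central differences
  s <- spectrum(c(443, 555), c(0.006, 0.004), "rrs")
  gn <- numeric_gradient(function(x) gamma_from_rrs(x, cfg)$gamma, s)
  expect_lt(grad_relerr(gamma_from_rrs(s, cfg)$gradient, gn), 1e-6)
})

test_that("analytic Jacobian matches central differences and scales with g", {
  cfg <- giop_config()
  x <- c(0.3, 0.012, 1.2e-3)
  gamma <- 1.1
  J <- giop_jacobian(x, gamma, cfg)
  for (k in 1:3) {
    h <- max(1e-6 * abs(x[k]), 1e-10)
    xp <- x; xp[k] <- x[k] + h
    xm <- x; xm[k] <- x[k] - h
    num <- (giop_forward(xp, gamma, cfg)$values -
              giop_forward(xm, gamma, cfg)$values) / (2 * h)
    expect_lt(max(abs(J[, k] - num)) / max(abs(J[, k])), 1e-6)
  }
  # the dg exponential factor is 1 at the reference band
  i443 <- nearest_band(cfg$fit_bands, 443)
  expect_equal(exp(-cfg$S_dg * (cfg$fit_bands[i443] - cfg$ref_band)), 1)
  # doubling g1, g2 doubles the Jacobian
  cfg2 <- giop_config(g1 = 2 * 0.0949, g2 = 2 * 0.0794)
  expect_equal(giop_jacobian(x, gamma, cfg2), 2 * J, tolerance = 1e-12)
})

test_that("noiseless inversion recovers the generating amplitudes", {
  gen <- generate_rrs(synth_config(n = 50, seed = 17))
  for (i in seq_len(50)) {
    st <- giop_invert(gen$spectra[[i]])
    expect_true(st$converged)
    tr <- unlist(gen$truth[i, c("x_phi", "x_dg", "x_bp")])
    expect_lt(max(abs(st$x - tr) / tr), 1e-3)
    expect_lt(max(abs(st$residuals)), 1e-9)
  }
})

test_that("degenerate input yields a flagged state, not an error", {
  wl <- default_band_centers()
  st <- giop_invert(spectrum(wl, rep(-0.001, 16), "Rrs"))
  expect_false(st$converged)
  expect_true(all(is.na(st$x)))
})

test_that("the Gauss-Markov sandwich reduces to textbook forms", {
  # 1 band, 1 parameter
  Ex <- param_covariance(matrix(2), matrix(0.25))
  expect_equal(drop(Ex), 0.25 / 4)
  # 2 bands, 1 parameter, averaging: u = sigma / sqrt(2)
  Ex2 <- param_covariance(cbind(c(1, 1)), diag(0.09, 2))
  expect_equal(sqrt(drop(Ex2)), 0.3 / sqrt(2))
  # scaling V by k^2 scales u by k
  J <- cbind(c(1, 2, 3), c(0.5, -1, 2))
  V <- diag(3) * 1e-6
  expect_equal(param_covariance(J, 4 * V), 4 * param_covariance(J, V))
  # V = sigma^2 I equals sigma^2 (J'J)^-1
  s2 <- 2.5e-7
  expect_equal(param_covariance(J, diag(s2, 3)), s2 * solve(crossprod(J)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(param_covariance(cbind(c(1, 1), c(1, 1)), diag(2)),
               "rank|condition")
})

test_that("E_x diagonals are non-negative for PSD covariances", {
  set.seed(23)
  gen <- generate_rrs(synth_config(n = 1, seed = 23))
  st <- giop_invert(gen$spectra[[1]])
  for (k in 1:10) {
    n <- length(st$cfg$fit_bands)
    A <- matrix(rnorm(n * n), n)
    V <- crossprod(A) * 1e-10
    Ex <- param_covariance(st$J, V)
    expect_true(all(diag(Ex) >= -1e-20))
  }
})

test_that("misfit uncertainty vanishes for a perfect fit and is homogeneous", {
  gen <- generate_rrs(synth_config(n = 1, seed = 29))
  st <- giop_invert(gen$spectra[[1]])
  um <- misfit_uncertainty(st)
  expect_lt(max(um / st$x), 1e-8)
  # doubling the residuals doubles the misfit uncertainty
  st2 <- st
  st2$residuals <- 2 * st$residuals + 1e-7
  st$residuals <- st$residuals + 5e-8
  expect_equal(as.numeric(misfit_uncertainty(st2)),
               2 * as.numeric(misfit_uncertainty(st)), tolerance = 1e-10)
})

test_that("derived IOPs obey additivity and propagate covariance terms", {
  gen <- generate_rrs(synth_config(n = 1, seed = 31))
  st <- giop_invert(gen$spectra[[1]])
  u <- flat_u(spectrum(st$cfg$fit_bands, st$Rrs_fit), 0.05)
  iops <- derived_iops(st, u)
  v <- stats::setNames(iops$value, iops$product)
  expect_equal(v[["a_nw"]], v[["a_phi"]] + v[["a_dg"]], tolerance = 1e-12)
  # u(a_nw)^2 = u(a_phi)^2 + u(a_dg)^2 + 2 cov term
  Ex <- attr(iops, "E_x_data")
  s443 <- st$cfg$aphi[nearest_band(st$cfg$fit_bands, 443)]
  u_ <- stats::setNames(iops$u_data, iops$product)
  expect_equal(u_[["a_nw"]]^2,
               u_[["a_phi"]]^2 + u_[["a_dg"]]^2 + 2 * s443 * Ex[1, 2],
               tolerance = 1e-12)
  # unit shape makes u(a_phi) = u(x_phi)
  cfgu <- unit_cfg()
  rrs <- giop_forward(c(0.05, 0.005, 8e-4), 1.2, cfgu)
  stu <- giop_invert(Rrs_from_rrs(rrs), cfgu)
  iu <- derived_iops(stu, flat_u(Rrs_from_rrs(rrs), 0.05))
  Exu <- attr(iu, "E_x_data")
  expect_equal(iu$u_data[iu$product == "a_phi"], sqrt(Exu[1, 1]))
})

test_that("backscattering shift follows the power law with full covariance", {
  r <- bbp_shift(1e-3, gamma = 0, lambda = 470, u_b = 2e-4)
  expect_equal(r$value, 1e-3)
  expect_equal(r$u, 2e-4)
  expect_equal(bbp_shift(1e-3, 1, 470)$value, 440 / 470 * 1e-3)
  expect_equal(bbp_shift(1e-3, 1, 470)$value, 9.3617e-4, tolerance = 1e-4)
  # negative amplitude-slope covariance reduces the combined uncertainty
  # (both partials positive for lambda > lambda_ref ... sign check below)
  with_cov <- bbp_shift(1e-3, 1, 470, u_b = 1e-4, u_gamma = 0.2,
                        cov_bg = -1.64e-6)
  no_cov <- bbp_shift(1e-3, 1, 470, u_b = 1e-4, u_gamma = 0.2)
  # d/db > 0, d/dgamma < 0 at 470 > 440, so negative cov increases u
  expect_gt(with_cov$u, no_cov$u)
  expect_error(bbp_shift(1e-3, 1, -5), "positive")
})
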