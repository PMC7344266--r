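#' Semi-analytical reflectance inversion (GIOP-style)
#'
#' Default-configuration spectral-matching inversion of sub-surface
#' remote-sensing reflectance for three amplitudes:
#' `x_phi` (phytoplankton absorption amplitude, chlorophyll-like, mg m^-3
#' when the shape is chl-specific), `x_dg` (detrital + dissolved absorption
#' at 443 nm, m^-1) and `x_bp` (particulate backscattering at 443 nm,
#' m^-1). Forward model:
#' \deqn{a_i = a_{w,i} + x_\phi a^*_{\phi,i} + x_{dg} e^{-S(\lambda_i-443)}}
#' \deqn{b_{b,i} = b_{bw,i} + x_{bp} (443/\lambda_i)^\gamma}
#' \deqn{u_i = b_{b,i}/(a_i + b_{b,i}), \quad
#'       r_{rs,i} = g_1 u_i + g_2 u_i^2}
#' The spectral slope `gamma` is fixed from the observed reflectance ratio
#' before fitting (it is not a free parameter), and the unweighted
#' least-squares fit is performed by Levenberg-Marquardt.
#'
#' @name giop
NULL

# approximate literature-style defaults on the 16-band grid -------------------

default_water_absorption <- function() {
  # pure-water absorption, m^-1 (approximate clear-water table)
  spectrum(default_band_centers(),
           c(0.00456, 0.00494, 0.00707, 0.00960, 0.01160, 0.01500,
             0.03250, 0.04470, 0.05960, 0.09400, 0.27550, 0.32890,
             0.38000, 0.42900, 0.45900, 0.84000),
           "a")
}

default_water_backscatter <- function() {
  # pure-seawater backscattering, m^-1, power-law in wavelength
  wl <- default_band_centers()
  spectrum(wl, 0.0011428 * (500 / wl)^4.24, "bb")
}

default_aphi_shape <- function() {
  # chl-specific phytoplankton absorption shape, normalized to 443 nm
  # (m^2 mg^-1 at 443 via the 0.055 amplitude of typical open-ocean waters)
  shape <- c(0.84, 0.92, 1.00, 0.93, 0.87, 0.76, 0.55, 0.38, 0.25,
             0.18, 0.16, 0.15, 0.18, 0.22, 0.24, 0.04)
  spectrum(default_band_centers(), 0.055 * shape, "a")
}

#' GIOP configuration
#'
#' @param fit_bands wavelengths used in the fit (nm); default the 412-655 nm
#'   subset of the 16-band grid.
#' @param g1,g2 coefficients of the quadratic reflectance model (sr^-1).
#' @param S_dg spectral slope of detrital/dissolved absorption (nm^-1).
#' @param aphi_star chl-specific phytoplankton absorption shape
#'   ([spectrum], m^2 mg^-1).
#' @param aw,bbw pure-water absorption and backscattering tables
#'   ([spectrum], m^-1).
#' @param gamma_rule parameters of the backscattering-slope rule
#'   `gamma = p1 * (1 - p2 * exp(-p3 * rrs(b1)/rrs(b2)))` (QAA-style);
#'   list with `p1`, `p2`, `p3`, `bands = c(b1, b2)`.
#' @param lm list of Levenberg-Marquardt controls: `maxiter`, `ftol`,
#'   `xtol`, and start `x0 = c(x_phi, x_dg, x_bp)`.
#' @param ref_band reference wavelength (nm) of the amplitudes; 443.
#' @return Object of class `giop_config`.
#' @export
giop_config <- function(fit_bands = default_band_centers()[default_band_centers() <= 655],
                        g1 = 0.0949, g2 = 0.0794,
                        S_dg = 0.018,
                        aphi_star = default_aphi_shape(),
                        aw = default_water_absorption(),
                        bbw = default_water_backscatter(),
                        gamma_rule = list(p1 = 2.0, p2 = 1.2, p3 = 0.9,
                                          bands = c(443, 555)),
                        lm = list(maxiter = 200, ftol = 1e-10, xtol = 1e-10,
                                  x0 = c(0.1, 0.01, 1e-3)),
                        ref_band = 443) {
  stopifnot(g1 > 0, g2 >= 0, S_dg > 0)
  pick <- function(sp) {
    i <- vapply(fit_bands, function(w) nearest_band(sp, w, 3), integer(1))
    sp$values[i]
  }
  cfg <- list(fit_bands = fit_bands, g1 = g1, g2 = g2, S_dg = S_dg,
              aphi = pick(aphi_star), aw = pick(aw), bbw = pick(bbw),
              gamma_rule = gamma_rule, lm = lm, ref_band = ref_band)
  class(cfg) <- "giop_config"
  cfg
}

#' Air-water interface transform between Rrs and rrs
#'
#' `rrs = Rrs / (0.52 + 1.7 Rrs)`, the standard above- to sub-surface
#' reflectance transform; its exact derivative
#' `drrs/dRrs = 0.52/(0.52 + 1.7 Rrs)^2` is used to chain gradients, and
#' the closed-form inverse `Rrs = 0.52 rrs / (1 - 1.7 rrs)` is provided.
#'
#' @param R [spectrum] of Rrs (or numeric vector).
#' @return `rrs_from_Rrs()` returns a [spectrum] of rrs (or numeric);
#'   `drrs_dRrs()` the elementwise derivative; `Rrs_from_rrs()` the inverse.
#' @export
rrs_from_Rrs <- function(R) {
  v <- spectral_values(R)
  out <- v / (0.52 + 1.7 * v)
  if (is_spectrum(R)) spectrum(R$wavelengths, out, "rrs") else out
}

#' @rdname rrs_from_Rrs
#' @export
drrs_dRrs <- function(R) {
  v <- spectral_values(R)
  0.52 / (0.52 + 1.7 * v)^2
}

#' @rdname rrs_from_Rrs
#' @param r [spectrum] of rrs (or numeric vector).
#' @export
Rrs_from_rrs <- function(r) {
  v <- spectral_values(r)
  out <- 0.52 * v / (1 - 1.7 * v)
  if (is_spectrum(r)) spectrum(r$wavelengths, out, "Rrs") else out
}

#' Backscattering spectral slope from a reflectance ratio
#'
#' QAA-style rule `gamma = p1 (1 - p2 exp(-p3 * rho))` with `rho` the
#' ratio of sub-surface reflectance at the two configured bands
#' (default 443/555). Also returns the analytic gradient of `gamma` with
#' respect to the rrs vector, for propagating radiometric uncertainty into
#' `u(gamma)`.
#'
#' @param rrs [spectrum] of sub-surface reflectance.
#' @param cfg a [giop_config] (only `gamma_rule` is used).
#' @param tol band-matching tolerance (nm).
#' @return List with `gamma` and `gradient` (w.r.t. the rrs vector).
#' @export
gamma_from_rrs <- function(rrs, cfg = giop_config(), tol = 3) {
  gr <- cfg$gamma_rule
  i1 <- nearest_band(rrs, gr$bands[1], tol)
  i2 <- nearest_band(rrs, gr$bands[2], tol)
  r1 <- rrs$values[i1]; r2 <- rrs$values[i2]
  if (r1 <= 0 || r2 <= 0)
    stop("gamma rule requires positive rrs at both bands", call. = FALSE)
  rho <- r1 / r2
  gamma <- gr$p1 * (1 - gr$p2 * exp(-gr$p3 * rho))
  dg_drho <- gr$p1 * gr$p2 * gr$p3 * exp(-gr$p3 * rho)
  g <- numeric(length(rrs$wavelengths))
  g[i1] <- dg_drho / r2
  g[i2] <- -dg_drho * rho / r2
  list(gamma = gamma, gradient = g)
}

# total absorption / backscattering at the fit bands for parameters x
giop_iops_at_bands <- function(x, gamma, cfg) {
  lam <- cfg$fit_bands
  a <- cfg$aw + x[1] * cfg$aphi + x[2] * exp(-cfg$S_dg * (lam - cfg$ref_band))
  bb <- cfg$bbw + x[3] * (cfg$ref_band / lam)^gamma
  list(a = a, bb = bb)
}

#' GIOP forward reflectance model
#'
#' @param x numeric `c(x_phi, x_dg, x_bp)`, all >= 0.
#' @param gamma backscattering spectral slope (dimensionless).
#' @param cfg a [giop_config].
#' @return [spectrum] of modeled rrs on the fit bands.
#' @export
giop_forward <- function(x, gamma, cfg = giop_config()) {
  io <- giop_iops_at_bands(x, gamma, cfg)
  denom <- io$a + io$bb
  if (any(denom <= 0))
    stop("total absorption + backscattering non-positive", call. = FALSE)
  u <- io$bb / denom
  spectrum(cfg$fit_bands, cfg$g1 * u + cfg$g2 * u^2, "rrs")
}

#' Analytic Jacobian of the GIOP forward model
#'
#' `d rrs_i / d x_k` for the three amplitudes, band by band. Verified in the
#' test suite against central differences.
#'
#' @inheritParams giop_forward
#' @return `length(fit_bands) x 3` matrix, columns `x_phi`, `x_dg`, `x_bp`.
#' @export
giop_jacobian <- function(x, gamma, cfg = giop_config()) {
  lam <- cfg$fit_bands
  io <- giop_iops_at_bands(x, gamma, cfg)
  a <- io$a; bb <- io$bb
  tot <- a + bb
  u <- bb / tot
  drrs_du <- cfg$g1 + 2 * cfg$g2 * u
  du_da <- -bb / tot^2
  du_dbb <- a / tot^2
  J <- cbind(
    x_phi = drrs_du * du_da * cfg$aphi,
    x_dg  = drrs_du * du_da * exp(-cfg$S_dg * (lam - cfg$ref_band)),
    x_bp  = drrs_du * du_dbb * (cfg$ref_band / lam)^gamma
  )
  rownames(J) <- lam
  J
}

#' Invert a reflectance spectrum for the GIOP amplitudes
#'
#' Converts Rrs to rrs, fixes `gamma` from the observed rrs ratio, then
#' minimizes the unweighted sum of squared rrs residuals over
#' `(x_phi, x_dg, x_bp) >= 0` by Levenberg-Marquardt (analytic Jacobian).
#' Non-convergence or undefined inputs return a state with
#' `converged = FALSE` rather than an error, mirroring per-pixel product
#' failure masking.
#'
#' @param R [spectrum] of Rrs containing the fit bands.
#' @param cfg a [giop_config].
#' @return Object of class `giop_state`: `x` (named amplitudes), `gamma`,
#'   `residuals` (observed - modeled rrs, sr^-1), `J` (Jacobian at the
#'   optimum), `rrs_obs`, `converged`, `message`, and `Rrs_fit` (the input
#'   values at the fit bands).
#' @export
giop_invert <- function(R, cfg = giop_config()) {
  stopifnot(is_spectrum(R))
  idx <- vapply(cfg$fit_bands, function(w) nearest_band(R, w, 3), integer(1))
  Rfit <- R$values[idx]
  rrs_obs <- rrs_from_Rrs(Rfit)
  fail <- function(msg) {
    structure(list(x = c(x_phi = NA_real_, x_dg = NA_real_, x_bp = NA_real_),
                   gamma = NA_real_, residuals = rep(NA_real_, length(Rfit)),
                   J = NULL, rrs_obs = rrs_obs, Rrs_fit = Rfit, cfg = cfg,
                   converged = FALSE, message = msg),
              class = "giop_state")
  }
  rrs_sp <- spectrum(cfg$fit_bands, rrs_obs, "rrs")
  gmb <- cfg$gamma_rule$bands
  ok <- tryCatch({
    r1 <- rrs_obs[nearest_band(rrs_sp, gmb[1], 3)]
    r2 <- rrs_obs[nearest_band(rrs_sp, gmb[2], 3)]
    r1 > 0 && r2 > 0
  }, error = function(e) FALSE)
  if (!ok) return(fail("non-positive rrs at gamma-rule bands"))
  gamma <- gamma_from_rrs(rrs_sp, cfg)$gamma

  resid_fn <- function(x) rrs_obs - giop_forward(x, gamma, cfg)$values
  jac_fn <- function(x) -giop_jacobian(x, gamma, cfg)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = cfg$lm$x0, lower = c(0, 0, 0),
                       fn = resid_fn, jac = jac_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = cfg$lm$maxiter,
                         ftol = cfg$lm$ftol, ptol = cfg$lm$xtol)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("Levenberg-Marquardt failed"))
  x <- stats::setNames(fit$par, c("x_phi", "x_dg", "x_bp"))
  converged <- fit$info %in% 1:4
  structure(list(x = x, gamma = gamma,
                 residuals = resid_fn(x),
                 J = giop_jacobian(x, gamma, cfg),
                 rrs_obs = rrs_obs, Rrs_fit = Rfit, cfg = cfg,
                 converged = converged, message = fit$message),
            class = "giop_state")
}

#' @export
print.giop_state <- function(x, ...) {
  cat("<giop_state>", if (x$converged) "converged" else
    paste("NOT converged:", x$message), "\n")
  print(x$x)
  cat("gamma:", x$gamma, " max|resid|:",
      if (all(is.na(x$residuals))) NA else max(abs(x$residuals)), "\n")
  invisible(x)
}

#' Parameter error covariance from the Jacobian (Gauss-Markov sandwich)
#'
#' Propagates a reflectance error covariance `V` (radiometric, or the
#' residual-based misfit covariance) into the parameter error covariance
#' \deqn{E_x = (J^T J)^{-1} J^T V J (J^T J)^{-1},}
#' the generalization of `J^{-1} V (J^T)^{-1}` to a non-square Jacobian
#' (it reduces to that form when `J` is square). Parameter uncertainties
#' are the square roots of the diagonal.
#'
#' @param J band-by-parameter Jacobian matrix.
#' @param V [spectral_covariance] (or matrix) over the fit bands, in rrs
#'   units (sr^-2).
#' @return `3 x 3` (or `p x p`) covariance matrix `E_x`.
#' @export
param_covariance <- function(J, V) {
  J <- as.matrix(J)
  m <- if (is_spectral_covariance(V)) V$matrix else as.matrix(V)
  if (nrow(m) != nrow(J))
    stop("covariance and Jacobian band dimensions differ", call. = FALSE)
  JtJ <- crossprod(J)
  cn <- kappa(JtJ, exact = TRUE)
  if (!is.finite(cn) || cn > 1e12)
    stop(sprintf("Jacobian is rank-deficient (condition number %.3g)", cn),
         call. = FALSE)
  G <- solve(JtJ, t(J))            # (J'J)^-1 J'
  Ex <- G %*% m %*% t(G)
  Ex <- (Ex + t(Ex)) / 2
  dimnames(Ex) <- list(colnames(J), colnames(J))
  Ex
}

#' Model-misfit parameter uncertainty
#'
#' Treats the least-squares residuals at the optimum as an estimate of
#' model imperfection: `E_rrs = diag(residual_i^2)` is substituted for the
#' radiometric covariance in [param_covariance()], and the per-parameter
#' misfit uncertainties are the square roots of the diagonal of the
#' resulting `E_x`.
#'
#' @param state a converged [giop_invert()] result.
#' @return Named numeric `u_misfit` for `x_phi`, `x_dg`, `x_bp`, with the
#'   full matrix as attribute `E_x`.
#' @export
misfit_uncertainty <- function(state) {
  stopifnot(inherits(state, "giop_state"))
  if (!state$converged)
    stop("misfit uncertainty requires a converged state", call. = FALSE)
  E_rrs <- diag(state$residuals^2, length(state$residuals))
  Ex <- param_covariance(state$J, E_rrs)
  structure(sqrt(pmax(diag(Ex), 0)), E_x = Ex)
}

#' Derived IOPs at the reference band with uncertainties
#'
#' From a converged inversion: `a_phi,443 = x_phi * aphi*(443)`,
#' `a_dg,443 = x_dg`, `b_bp,443 = x_bp`, and
#' `a_nw,443 = a_phi,443 + a_dg,443`. Radiometric ("data") uncertainty is
#' obtained by chaining the Rrs covariance through the exact
#' `drrs/dRrs` derivative and the Gauss-Markov sandwich; the `a_nw`
#' combination includes the `x_phi`-`x_dg` covariance. Misfit uncertainty
#' (from [misfit_uncertainty()]) is reported alongside.
#'
#' @param state a converged [giop_invert()] result.
#' @param V_Rrs [spectral_covariance] of Rrs over the fit bands (sr^-2), or
#'   a [spectrum] of u(Rrs) treated as uncorrelated.
#' @return A data.frame with one row per product (`a_phi`, `a_dg`, `b_bp`,
#'   `a_nw`, all at the reference band): `value`, `u_data`, `u_misfit`
#'   (m^-1). The parameter covariance matrices are attached as attributes
#'   `E_x_data` and `E_x_misfit`.
#' @export
derived_iops <- function(state, V_Rrs) {
  stopifnot(inherits(state, "giop_state"))
  if (!state$converged)
    stop("derived IOPs require a converged state", call. = FALSE)
  cfg <- state$cfg
  nb <- length(cfg$fit_bands)
  if (is_spectrum(V_Rrs)) {
    i <- vapply(cfg$fit_bands, function(w) nearest_band(V_Rrs, w, 3),
                integer(1))
    VR <- diag(V_Rrs$values[i]^2, nb)
  } else {
    VR <- if (is_spectral_covariance(V_Rrs)) V_Rrs$matrix else as.matrix(V_Rrs)
    if (nrow(VR) != nb)
      stop("V_Rrs does not match the fit bands", call. = FALSE)
  }
  d <- drrs_dRrs(state$Rrs_fit)
  V_rrs <- VR * tcrossprod(d)                 # D V D with D = diag(d)
  Ex <- param_covariance(state$J, V_rrs)
  um <- misfit_uncertainty(state)
  Ex_m <- attr(um, "E_x")

  s443 <- cfg$aphi[nearest_band(cfg$fit_bands, cfg$ref_band, 3)]
  # linear map from (x_phi, x_dg, x_bp) to (a_phi, a_dg, b_bp, a_nw) at 443
  A <- rbind(a_phi = c(s443, 0, 0),
             a_dg  = c(0, 1, 0),
             b_bp  = c(0, 0, 1),
             a_nw  = c(s443, 1, 0))
  vals <- drop(A %*% state$x)
  u_of <- function(E) sqrt(pmax(diag(A %*% E %*% t(A)), 0))
  out <- data.frame(product = rownames(A), value = vals,
                    u_data = u_of(Ex), u_misfit = u_of(Ex_m),
                    row.names = NULL)
  attr(out, "E_x_data") <- Ex
  attr(out, "E_x_misfit") <- Ex_m
  out
}

#' Shift particulate backscattering to another wavelength
#'
#' `b_bp(lambda) = b_ref * (lambda_ref/lambda)^gamma`, with first-order
#' uncertainty including the backscattering-slope term and the
#' amplitude-slope covariance:
#' \deqn{u^2 = (\partial/\partial b_{ref})^2 u^2(b_{ref})
#'   + (\partial/\partial\gamma)^2 u^2(\gamma)
#'   + 2 (\partial/\partial b_{ref})(\partial/\partial\gamma)
#'     \,\mathrm{cov}(b_{ref},\gamma)}
#' where `d/db_ref = (lambda_ref/lambda)^gamma` and
#' `d/dgamma = value * ln(lambda_ref/lambda)`.
#'
#' @param b_ref backscattering amplitude at `lambda_ref` (m^-1), >= 0.
#' @param gamma spectral slope.
#' @param lambda target wavelength (nm), > 0.
#' @param lambda_ref reference wavelength (nm); 440 by convention for the
#'   IOP-based POC model.
#' @param u_b,u_gamma 1-sigma uncertainties of `b_ref` and `gamma`.
#' @param cov_bg covariance of `b_ref` and `gamma` (m^-1); a typical
#'   GIOP-derived estimate is -1.64e-6 m^-1 nm^-1.
#' @return List with `value` and `u` (m^-1).
#' @export
bbp_shift <- function(b_ref, gamma, lambda, lambda_ref = 440,
                      u_b = 0, u_gamma = 0, cov_bg = 0) {
  if (lambda <= 0 || lambda_ref <= 0)
    stop("wavelengths must be positive", call. = FALSE)
  if (b_ref < 0) stop("b_ref must be non-negative", call. = FALSE)
  ratio <- lambda_ref / lambda
  value <- b_ref * ratio^gamma
  d_db <- ratio^gamma
  d_dg <- value * log(ratio)
  v <- d_db^2 * u_b^2 + d_dg^2 * u_gamma^2 + 2 * d_db * d_dg * cov_bg
  list(value = value, u = sqrt(max(v, 0)))
}
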