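#' Ocean-color product algorithms with analytic gradients
#'
#' Each forward algorithm returns its derived value together with the
#' analytic gradient with respect to the input reflectance (or radiance)
#' vector, ready to feed [propagate_uncorrelated()] /
#' [propagate_covariance()]. Gradients are full-length vectors aligned with
#' the input spectrum's grid, zero on unused bands.
#'
#' @name oc-products
NULL

# evaluate a0 + a1 x + ... + a4 x^4 and its derivative
poly_eval <- function(coef, x) {
  k <- seq_along(coef) - 1
  sum(coef * x^k)
}
poly_deriv <- function(coef, x) {
  k <- seq_along(coef) - 1
  sum(coef[-1] * k[-1] * x^(k[-1] - 1))
}

#' Band-ratio algorithm coefficient sets
#'
#' Constructors for the configurable coefficient sets of the product
#' algorithms. Default polynomial coefficients follow the standard NASA
#' reprocessing values for a SeaWiFS-like band set (OC4 for the band-ratio
#' chlorophyll, the color-index line-height chlorophyll, KD2S for Kd490);
#' they are configuration, not results, and are overridable.
#'
#' @param blue_bands candidate blue band centers (nm); the maximum ratio
#'   governs.
#' @param green_band green reference band center (nm).
#' @param poly polynomial coefficients a0..a4 applied to
#'   `log10(max blue/green ratio)`.
#' @return A coefficients object for the matching algorithm.
#' @export
ocx_coefficients <- function(blue_bands = c(443, 490, 510),
                             green_band = 555,
                             poly = c(0.3272, -2.9940, 2.7218,
                                      -1.2259, -0.5683)) {
  stopifnot(length(poly) == 5)
  structure(list(blue_bands = blue_bands, green_band = green_band,
                 poly = as.numeric(poly)), class = "ocx_coefficients")
}

#' @rdname ocx_coefficients
#' @param ci_bands blue/green/red band centers of the color-index line
#'   height (ascending).
#' @param b0,b1 intercept and slope of `log10(Chl) = b0 + b1 * CI`.
#' @export
lh_chl_coefficients <- function(ci_bands = c(443, 555, 665),
                                b0 = -0.4909, b1 = 191.6590) {
  stopifnot(length(ci_bands) == 3, !is.unsorted(ci_bands, strictly = TRUE))
  structure(list(ci_bands = ci_bands, b0 = b0, b1 = b1),
            class = "lh_chl_coefficients")
}

#' @rdname ocx_coefficients
#' @param t_low,t_high blend-window edges (mg m^-3): below `t_low` the
#'   line-height value is used, above `t_high` the band-ratio value, and a
#'   linear blend in between.
#' @export
blend_window <- function(t_low = 0.15, t_high = 0.2) {
  stopifnot(0 < t_low, t_low < t_high)
  structure(list(t_low = t_low, t_high = t_high), class = "blend_window")
}

#' @rdname ocx_coefficients
#' @param floor additive floor of the Kd490 algorithm (m^-1), the pure-water
#'   attenuation 0.0166.
#' @export
kd490_coefficients <- function(blue_bands = 490, green_band = 555,
                               poly = c(-0.8515, -1.8263, 1.8714,
                                        -2.4414, -0.0615),
                               floor = 0.0166) {
  stopifnot(length(poly) == 5)
  structure(list(blue_bands = blue_bands, green_band = green_band,
                 poly = as.numeric(poly), floor = floor),
            class = "kd490_coefficients")
}

#' @rdname ocx_coefficients
#' @param a_poc,b_poc power-law coefficients of `POC = a_poc * X^b_poc`,
#'   with `X = Rrs(443)/Rrs(555)`; published values 203.2 and -1.034.
#' @param blue,green POC ratio bands (nm).
#' @export
poc_coefficients <- function(a_poc = 203.2, b_poc = -1.034,
                             blue = 443, green = 555) {
  stopifnot(a_poc > 0)
  structure(list(a_poc = a_poc, b_poc = b_poc, blue = blue, green = green),
            class = "poc_coefficients")
}

#' @rdname ocx_coefficients
#' @param left,peak,right fluorescence line-height baseline and peak bands
#'   (nm). The default 665/678/710 fits the package's 16-band grid; the
#'   MODIS-style triplet 667/678/748 is equally valid where those bands
#'   exist.
#' @export
nflh_bands <- function(left = 665, peak = 678, right = 710) {
  stopifnot(left < peak, peak < right)
  structure(list(left = left, peak = peak, right = right),
            class = "nflh_bands")
}

#' Band-ratio chlorophyll (maximum blue-green ratio)
#'
#' `chi = log10(max_b Rrs(b)/Rrs(green))`, `Chl = 10^(a0 + a1 chi + ... +
#' a4 chi^4)`. The gradient is nonzero only on the active (maximal) blue
#' band and the green band; at an exact ratio tie the shortest wavelength
#' is chosen and a discontinuity flag is raised.
#'
#' @param s [spectrum] of Rrs.
#' @param c an [ocx_coefficients].
#' @param tol band-matching tolerance (nm).
#' @return List with `value` (mg m^-3), `gradient` (full-length, sr), the
#'   `active_blue` band center (nm) and `tie` flag.
#' @export
chl_br <- function(s, c = ocx_coefficients(), tol = 3) {
  stopifnot(is_spectrum(s))
  ib <- vapply(c$blue_bands, function(b) nearest_band(s, b, tol), integer(1))
  ig <- nearest_band(s, c$green_band, tol)
  Rg <- s$values[ig]
  ratios <- s$values[ib] / Rg
  mx <- max(ratios)
  if (!is.finite(mx) || mx <= 0 || Rg <= 0)
    stop("non-positive maximum band ratio; band-ratio chlorophyll undefined",
         call. = FALSE)
  k <- which(ratios == mx)          # ties -> shortest wavelength
  tie <- length(k) > 1
  k <- k[1]
  ia <- ib[k]
  chi <- log10(mx)
  value <- 10^poly_eval(c$poly, chi)
  dP <- poly_deriv(c$poly, chi)
  g <- numeric(length(s$wavelengths))
  # d value / d Rrs = value * dP(chi) * dchi/dRrs * ln10; dchi/dR = 1/(ln10 R)
  g[ia] <- value * dP / s$values[ia]
  g[ig] <- g[ig] - value * dP / Rg
  list(value = value, gradient = g,
       active_blue = s$wavelengths[ia], tie = tie)
}

#' Line-height (color-index) chlorophyll
#'
#' `CI = Rrs(green) - [Rrs(blue) + w (Rrs(red) - Rrs(blue))]` with
#' `w = (lambda_g - lambda_b)/(lambda_r - lambda_b)`;
#' `Chl = 10^(b0 + b1 CI)`. The model is log-linear in a linear functional
#' of the spectrum, so the gradient follows by the chain rule.
#'
#' @param s [spectrum] of Rrs.
#' @param c an [lh_chl_coefficients].
#' @param tol band-matching tolerance (nm).
#' @return List with `value` (mg m^-3) and `gradient`.
#' @export
chl_lh <- function(s, c = lh_chl_coefficients(), tol = 3) {
  stopifnot(is_spectrum(s))
  i <- vapply(c$ci_bands, function(b) nearest_band(s, b, tol), integer(1))
  lam <- s$wavelengths[i]
  w <- (lam[2] - lam[1]) / (lam[3] - lam[1])
  ci <- s$values[i[2]] - (s$values[i[1]] + w * (s$values[i[3]] - s$values[i[1]]))
  value <- 10^(c$b0 + c$b1 * ci)
  g <- numeric(length(s$wavelengths))
  fac <- log(10) * c$b1 * value
  g[i[1]] <- -(1 - w) * fac
  g[i[2]] <- fac
  g[i[3]] <- -w * fac
  list(value = value, gradient = g, ci = ci)
}

#' Blended chlorophyll product
#'
#' The standard chlorophyll product blends the line-height and band-ratio
#' estimates: below `t_low` the line-height value is used; above `t_high`
#' the band-ratio value; in between a linear mix
#' `alpha Chl_BR + (1 - alpha) Chl_LH` with
#' `alpha = (Chl_LH - t_low)/(t_high - t_low)`. Because `alpha` itself
#' depends on `Chl_LH`, the gradient inside the window carries the
#' `d alpha / d Rrs` cross terms in addition to the convex combination of
#' the branch gradients.
#'
#' @param s [spectrum] of Rrs.
#' @param ocx an [ocx_coefficients].
#' @param lh an [lh_chl_coefficients].
#' @param w a [blend_window].
#' @param tol band-matching tolerance (nm).
#' @return List with `value`, `gradient`, `branch` (`"LH"`, `"BR"` or
#'   `"blended"`), `alpha`, and the branch values.
#' @export
chl_blend <- function(s, ocx = ocx_coefficients(),
                      lh = lh_chl_coefficients(),
                      w = blend_window(), tol = 3) {
  rl <- chl_lh(s, lh, tol)
  if (rl$value <= w$t_low)
    return(list(value = rl$value, gradient = rl$gradient, branch = "LH",
                alpha = 0, chl_lh = rl$value, chl_br = NA_real_))
  rb <- chl_br(s, ocx, tol)
  if (rl$value >= w$t_high)
    return(list(value = rb$value, gradient = rb$gradient, branch = "BR",
                alpha = 1, chl_lh = rl$value, chl_br = rb$value))
  span <- w$t_high - w$t_low
  alpha <- (rl$value - w$t_low) / span
  value <- alpha * rb$value + (1 - alpha) * rl$value
  # d value = alpha gBR + (1 - alpha) gLH + (BR - LH) * gLH / span
  g <- alpha * rb$gradient + (1 - alpha) * rl$gradient +
    (rb$value - rl$value) / span * rl$gradient
  list(value = value, gradient = g, branch = "blended", alpha = alpha,
       chl_lh = rl$value, chl_br = rb$value)
}

#' Diffuse attenuation coefficient at 490 nm
#'
#' `Kd490 = floor + 10^(c0 + c1 chi + ... + c4 chi^4)` with
#' `chi = log10(max blue/green Rrs ratio)`; the 0.0166 m^-1 floor is the
#' pure-water contribution. Active-band selection as in [chl_br()].
#'
#' @param s [spectrum] of Rrs.
#' @param c a [kd490_coefficients].
#' @param tol band-matching tolerance (nm).
#' @return List with `value` (m^-1), `gradient` and `active_blue`.
#' @export
kd490 <- function(s, c = kd490_coefficients(), tol = 3) {
  stopifnot(is_spectrum(s))
  ib <- vapply(c$blue_bands, function(b) nearest_band(s, b, tol), integer(1))
  ig <- nearest_band(s, c$green_band, tol)
  Rg <- s$values[ig]
  ratios <- s$values[ib] / Rg
  mx <- max(ratios)
  if (!is.finite(mx) || mx <= 0 || Rg <= 0)
    stop("non-positive band ratio; Kd490 undefined", call. = FALSE)
  k <- which(ratios == mx)[1]
  ia <- ib[k]
  chi <- log10(mx)
  p10 <- 10^poly_eval(c$poly, chi)
  value <- c$floor + p10
  dP <- poly_deriv(c$poly, chi)
  g <- numeric(length(s$wavelengths))
  g[ia] <- p10 * dP / s$values[ia]
  g[ig] <- g[ig] - p10 * dP / Rg
  list(value = value, gradient = g, active_blue = s$wavelengths[ia])
}

#' Particulate organic carbon (blue-green power law)
#'
#' `POC = a_poc * X^b_poc` with `X = Rrs(443)/Rrs(555)`. The gradient is
#' `(b POC / R443, -b POC / R555)` on the two bands, so under spectrally
#' flat uncorrelated relative uncertainty `r` the propagated relative
#' uncertainty is the constant `|b_poc| sqrt(2) r`.
#'
#' @param s [spectrum] of Rrs.
#' @param c a [poc_coefficients].
#' @param tol band-matching tolerance (nm).
#' @return List with `value` (mg m^-3), `gradient`, and the ratio `X`.
#' @export
poc <- function(s, c = poc_coefficients(), tol = 3) {
  stopifnot(is_spectrum(s))
  i1 <- nearest_band(s, c$blue, tol)
  i2 <- nearest_band(s, c$green, tol)
  R1 <- s$values[i1]; R2 <- s$values[i2]
  if (R1 <= 0 || R2 <= 0)
    stop("POC requires positive Rrs at both ratio bands", call. = FALSE)
  X <- R1 / R2
  value <- c$a_poc * X^c$b_poc
  g <- numeric(length(s$wavelengths))
  g[i1] <- c$b_poc * value / R1
  g[i2] <- -c$b_poc * value / R2
  list(value = value, gradient = g, X = X)
}

#' Normalized fluorescence line height
#'
#' Height of the chlorophyll fluorescence peak above a linear baseline
#' drawn between two flanking bands of normalized water-leaving radiance:
#' `nflh = nLw(peak) - [nLw(left) + (nLw(right) - nLw(left)) * w]` with
#' `w = (lambda_peak - lambda_left)/(lambda_right - lambda_left)`. The
#' model is linear, so its gradient is the constant coefficient vector and
#' first-order propagation is exact.
#'
#' @param nlw [spectrum] of normalized water-leaving radiance
#'   (mW cm^-2 um^-1 sr^-1).
#' @param b an [nflh_bands].
#' @param tol band-matching tolerance (nm).
#' @return List with `value` (mW cm^-2 um^-1 sr^-1) and `gradient`.
#' @export
nflh <- function(nlw, b = nflh_bands(), tol = 3) {
  stopifnot(is_spectrum(nlw))
  il <- nearest_band(nlw, b$left, tol)
  ip <- nearest_band(nlw, b$peak, tol)
  ir <- nearest_band(nlw, b$right, tol)
  lam <- nlw$wavelengths
  w <- (lam[ip] - lam[il]) / (lam[ir] - lam[il])
  value <- nlw$values[ip] -
    (nlw$values[il] + (nlw$values[ir] - nlw$values[il]) * w)
  g <- numeric(length(lam))
  g[ip] <- 1
  g[il] <- -(1 - w)
  g[ir] <- -w
  list(value = value, gradient = g)
}

#' Convert Rrs to normalized water-leaving radiance
#'
#' `nLw(lambda) = Rrs(lambda) * F0(lambda)` with `F0` the band-averaged mean
#' extraterrestrial solar irradiance (mW cm^-2 um^-1). The bundled default
#' table holds approximate literature-style values on the package's 16-band
#' grid; supply your own for other sensors. The transform is linear, so
#' uncertainties scale by the same factor.
#'
#' @param s [spectrum] of Rrs (sr^-1).
#' @param f0 [spectrum] of solar irradiance on (at least) the same bands.
#' @return [spectrum] of nLw, tag `"nLw"` (or `"u_nLw"` for uncertainty
#'   input).
#' @export
rrs_to_nlw <- function(s, f0 = default_solar_irradiance()) {
  stopifnot(is_spectrum(s), is_spectrum(f0))
  i <- vapply(s$wavelengths, function(w) nearest_band(f0, w, 3), integer(1))
  tag <- if (grepl("^u_", s$quantity_tag)) "u_nLw" else "nLw"
  spectrum(s$wavelengths, s$values * f0$values[i], tag)
}

#' @rdname rrs_to_nlw
#' @export
default_solar_irradiance <- function() {
  spectrum(default_band_centers(),
           c(172.9, 170.2, 187.6, 205.4, 202.4, 194.9, 192.9, 190.2,
             185.7, 180.0, 173.0, 166.0, 161.0, 155.0, 148.0, 139.0),
           "F0")
}
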