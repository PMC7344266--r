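#' Radiometric uncertainty models for remote-sensing reflectance
#'
#' Three regimes for assigning per-band uncertainty u(Rrs,i):
#' spectrally flat relative uncertainty ([flat_u()]), a chlorophyll-indexed
#' tabulated relative-uncertainty surface ([surface_u()]), or a full
#' user-supplied covariance matrix ([build_covariance()]).
#'
#' @name rrs-uncertainty
NULL

#' Spectrally flat relative uncertainty
#'
#' `u(Rrs,i) = rel * |Rrs,i|` on every band. Relative uncertainties of 1, 5
#' and 10% are the conventional mission accuracy scenarios.
#'
#' @param s [spectrum] of Rrs.
#' @param rel dimensionless relative fraction, >= 0 (e.g. 0.05).
#' @return [spectrum] of u(Rrs), tag `"u_<tag>"`.
#' @export
flat_u <- function(s, rel) {
  stopifnot(is_spectrum(s))
  if (!is.finite(rel) || rel < 0)
    stop("relative uncertainty must be a non-negative number", call. = FALSE)
  spectrum(s$wavelengths, rel * abs(s$values),
           paste0("u_", s$quantity_tag))
}

#' Chlorophyll-indexed relative-uncertainty surface
#'
#' A tabulated surface of relative Rrs uncertainty on a (chl, wavelength)
#' grid, of the kind published for on-orbit sensors. Rows are chlorophyll
#' levels (mg m^-3, ascending), columns wavelengths (nm, ascending), body
#' entries dimensionless fractions.
#'
#' @param chl_levels ascending chlorophyll grid (mg m^-3).
#' @param wavelengths ascending wavelength grid (nm).
#' @param rel_values matrix `length(chl_levels) x length(wavelengths)` of
#'   non-negative fractions.
#' @return Object of class `rel_uncertainty_surface`.
#' @export
rel_uncertainty_surface <- function(chl_levels, wavelengths, rel_values) {
  chl_levels <- as.numeric(chl_levels)
  wavelengths <- as.numeric(wavelengths)
  m <- as.matrix(rel_values)
  if (is.unsorted(chl_levels, strictly = TRUE) ||
      is.unsorted(wavelengths, strictly = TRUE))
    stop("chl levels and wavelengths must be strictly ascending",
         call. = FALSE)
  if (!all(dim(m) == c(length(chl_levels), length(wavelengths))))
    stop("rel_values must be chl x wavelength", call. = FALSE)
  if (any(!is.finite(m)) || any(m < 0))
    stop("relative uncertainties must be finite and non-negative",
         call. = FALSE)
  structure(list(chl_levels = chl_levels, wavelengths = wavelengths,
                 rel_values = m),
            class = "rel_uncertainty_surface")
}

#' Evaluate a relative-uncertainty surface for a spectrum
#'
#' Bilinear lookup: linear in wavelength inside the table's range (never
#' extrapolated in wavelength), linear in chlorophyll inside the chl grid,
#' linearly extrapolated from the last two levels for chl above the grid
#' top, and clamped to the lowest level below the grid bottom. Returns
#' `u(Rrs,i) = rel(lambda_i, chl) * |Rrs,i|`.
#'
#' @param surf a [rel_uncertainty_surface].
#' @param s [spectrum] of Rrs; wavelengths must lie within the table range.
#' @param chl chlorophyll concentration (mg m^-3) indexing the surface,
#'   typically from [chl_blend()].
#' @return [spectrum] of u(Rrs).
#' @export
surface_u <- function(surf, s, chl) {
  stopifnot(inherits(surf, "rel_uncertainty_surface"), is_spectrum(s))
  wl <- surf$wavelengths
  if (any(s$wavelengths < min(wl)) || any(s$wavelengths > max(wl)))
    stop("spectrum wavelengths outside tabulated range; wavelength is never extrapolated",
         call. = FALSE)
  cl <- surf$chl_levels
  # per-chl-level interpolation in wavelength, then linear in chl
  rel_at <- function(level_row) {
    stats::approx(wl, surf$rel_values[level_row, ], xout = s$wavelengths)$y
  }
  n <- length(cl)
  if (chl <= cl[1]) {
    rel <- rel_at(1)                      # clamp below grid
  } else if (chl >= cl[n]) {
    # linear extrapolation from the top two levels (also exact on cl[n])
    r1 <- rel_at(n - 1); r2 <- rel_at(n)
    w <- (chl - cl[n - 1]) / (cl[n] - cl[n - 1])
    rel <- r1 + w * (r2 - r1)
  } else {
    j <- findInterval(chl, cl)
    r1 <- rel_at(j); r2 <- rel_at(j + 1)
    w <- (chl - cl[j]) / (cl[j + 1] - cl[j])
    rel <- r1 + w * (r2 - r1)
  }
  rel <- pmax(rel, 0)
  spectrum(s$wavelengths, rel * abs(s$values), paste0("u_", s$quantity_tag))
}

#' Assemble a spectral covariance from uncertainties and a correlation
#'
#' `V_ij = corr_ij * u_i * u_j`. With `corr` omitted the result is the
#' diagonal matrix `diag(u_i^2)` (the uncorrelated case).
#'
#' @param u [spectrum] of per-band uncertainties (or numeric vector with
#'   `wavelengths` supplied).
#' @param corr optional correlation matrix: symmetric, unit diagonal,
#'   entries in \[-1, 1\].
#' @param wavelengths grid when `u` is a plain vector.
#' @return A [spectral_covariance].
#' @export
build_covariance <- function(u, corr = NULL, wavelengths = NULL) {
  if (is_spectrum(u)) {
    wavelengths <- u$wavelengths
    uv <- u$values
  } else {
    uv <- as.numeric(u)
    if (is.null(wavelengths))
      stop("wavelengths required when u is not a spectrum", call. = FALSE)
  }
  if (any(uv < 0)) stop("uncertainties must be non-negative", call. = FALSE)
  n <- length(uv)
  if (is.null(corr)) {
    V <- diag(uv^2, n)
  } else {
    corr <- as.matrix(corr)
    if (!all(dim(corr) == n))
      stop("correlation matrix dimension mismatch", call. = FALSE)
    if (max(abs(corr - t(corr))) > 1e-10)
      stop("correlation matrix must be symmetric", call. = FALSE)
    if (max(abs(diag(corr) - 1)) > 1e-10)
      stop("correlation matrix must have unit diagonal", call. = FALSE)
    if (any(corr < -1 - 1e-12) || any(corr > 1 + 1e-12))
      stop("correlation entries must lie in [-1, 1]", call. = FALSE)
    V <- corr * tcrossprod(uv)
  }
  spectral_covariance(wavelengths, V)
}

#' Read / write a relative-uncertainty surface as CSV
#'
#' Layout: first header row = wavelengths (nm); first column = chlorophyll
#' levels (mg m^-3); body = relative fractions.
#'
#' @param path file path.
#' @export
read_uncertainty_surface_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  rel_uncertainty_surface(as.numeric(rownames(tab)),
                          as.numeric(colnames(tab)),
                          as.matrix(tab))
}

#' @rdname read_uncertainty_surface_csv
#' @param surf a [rel_uncertainty_surface].
#' @export
write_uncertainty_surface_csv <- function(surf, path) {
  m <- surf$rel_values
  dimnames(m) <- list(surf$chl_levels, surf$wavelengths)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
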