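#' Spectral data types, band matching and multiband subsampling
#'
#' A `spectrum` is the basic container used throughout the package: a strictly
#' increasing wavelength grid (nm) paired with the values of one spectral
#' quantity and a tag naming that quantity's role. The conventional tags are:
#'
#' * `"Rrs"`, `"rrs"` -- above- and sub-surface remote-sensing reflectance
#'   (sr^-1);
#' * `"u_Rrs"` -- 1-sigma uncertainty of Rrs (sr^-1);
#' * `"nLw"`, `"u_nLw"` -- normalized water-leaving radiance and its
#'   uncertainty (mW cm^-2 um^-1 sr^-1);
#' * `"a"`, `"bb"` -- absorption / backscattering coefficients (m^-1).
#'
#' @param wavelengths numeric, strictly increasing, all > 0 (nm).
#' @param values numeric of the same length, all finite.
#' @param quantity_tag single string naming the quantity.
#' @return An object of class `spectrum`.
#' @export
#' @examples
#' s <- spectrum(c(443, 555), c(0.004, 0.002), "Rrs")
#' nearest_band(s, 547, tol = 10)
spectrum <- function(wavelengths, values, quantity_tag = "Rrs") {
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) < 1L)
    stop("spectrum needs at least one wavelength", call. = FALSE)
  if (any(!is.finite(wavelengths)) || any(wavelengths <= 0))
    stop("wavelengths must be finite and positive", call. = FALSE)
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (length(values) != length(wavelengths))
    stop("values and wavelengths differ in length", call. = FALSE)
  if (any(!is.finite(values)))
    stop("spectrum values must be finite", call. = FALSE)
  structure(
    list(wavelengths = wavelengths, values = values,
         quantity_tag = as.character(quantity_tag)[1]),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat("<spectrum>", x$quantity_tag, "on", length(x$wavelengths),
      "bands:", paste0(min(x$wavelengths), "-", max(x$wavelengths), " nm\n"))
  print(stats::setNames(x$values, x$wavelengths))
  invisible(x)
}

#' @export
length.spectrum <- function(x) length(x$wavelengths)

is_spectrum <- function(x) inherits(x, "spectrum")

#' Symmetric spectral covariance matrix over a wavelength grid
#'
#' Container for a covariance matrix of a spectral quantity (e.g. `V_Rrs`,
#' units sr^-2, or the residual error covariance `E_rrs` of the reflectance
#' inversion). Validates symmetry, non-negative diagonal and numerical
#' positive semi-definiteness (eigenvalues >= -1e-10 times the largest
#' diagonal element).
#'
#' @param wavelengths numeric, strictly increasing (nm).
#' @param matrix square numeric matrix conformable with `wavelengths`.
#' @param role string, e.g. `"V_Rrs"` or `"E_rrs"`.
#' @return An object of class `spectral_covariance`.
#' @export
spectral_covariance <- function(wavelengths, matrix, role = "V_Rrs") {
  wavelengths <- as.numeric(wavelengths)
  m <- as.matrix(matrix)
  n <- length(wavelengths)
  if (is.unsorted(wavelengths, strictly = TRUE) || any(wavelengths <= 0))
    stop("wavelengths must be strictly increasing and positive", call. = FALSE)
  if (!all(dim(m) == c(n, n)))
    stop("covariance matrix dimensions do not match wavelength grid",
         call. = FALSE)
  if (any(!is.finite(m)))
    stop("covariance entries must be finite", call. = FALSE)
  scale <- max(abs(m), 1e-300)
  if (max(abs(m - t(m))) > 1e-12 * scale)
    stop("covariance matrix is not symmetric", call. = FALSE)
  m <- (m + t(m)) / 2
  if (any(diag(m) < 0))
    stop("covariance diagonal must be non-negative", call. = FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(diag(m), 1e-300))
    stop("covariance matrix is not positive semi-definite", call. = FALSE)
  structure(list(wavelengths = wavelengths, matrix = m, role = role),
            class = "spectral_covariance")
}

is_spectral_covariance <- function(x) inherits(x, "spectral_covariance")

#' Multispectral band set
#'
#' Band centers plus a common boxcar width. The default is the sixteen
#' 10 nm-wide visible bands used throughout the package, centered on 412,
#' 425, 443, 460, 475, 490, 510, 532, 555, 583, 617, 640, 655, 665, 678
#' and 710 nm -- a set spanning bands of past and present NASA ocean-color
#' sensors.
#'
#' @param centers numeric, strictly increasing band centers (nm).
#' @param width common band width (nm), > 0.
#' @return An object of class `band_set`.
#' @export
band_set <- function(centers = default_band_centers(), width = 10) {
  centers <- as.numeric(centers)
  if (is.unsorted(centers, strictly = TRUE))
    stop("band centers must be strictly increasing", call. = FALSE)
  if (!is.finite(width) || width <= 0)
    stop("band width must be positive", call. = FALSE)
  structure(list(centers = centers, width = width), class = "band_set")
}

#' @rdname band_set
#' @export
default_band_centers <- function() {
  c(412, 425, 443, 460, 475, 490, 510, 532, 555,
    583, 617, 640, 655, 665, 678, 710)
}

#' Find the band nearest a nominal wavelength
#'
#' Algorithms address bands by nominal center (443, 555, ...); this resolves
#' a nominal wavelength to an index on the actual grid. Ties resolve to the
#' shorter wavelength.
#'
#' @param s a [spectrum], or a numeric wavelength vector.
#' @param target nominal wavelength (nm).
#' @param tol maximum allowed distance (nm); default 3.
#' @return Integer index into the wavelength grid.
#' @export
nearest_band <- function(s, target, tol = 3) {
  wl <- if (is_spectrum(s)) s$wavelengths else as.numeric(s)
  d <- abs(wl - target)
  i <- which.min(d)          # which.min takes the first (shortest) on ties
  if (d[i] > tol)
    stop(sprintf("no band within %g nm of %g nm (nearest: %g nm)",
                 tol, target, wl[i]), call. = FALSE)
  i
}

#' Subsample a hyperspectral spectrum onto a multiband grid
#'
#' Each output value is the unweighted (boxcar) mean of the input values
#' whose wavelengths fall in the closed interval
#' `[center - width/2, center + width/2]`. The output grid is the band
#' centers.
#'
#' @param hyper a [spectrum] covering every band interval.
#' @param bands a [band_set].
#' @return A [spectrum] on the band centers, same quantity tag.
#' @export
subsample_to_bands <- function(hyper, bands = band_set()) {
  stopifnot(is_spectrum(hyper), inherits(bands, "band_set"))
  half <- bands$width / 2
  vals <- vapply(bands$centers, function(c0) {
    sel <- hyper$wavelengths >= c0 - half & hyper$wavelengths <= c0 + half
    if (!any(sel))
      stop(sprintf("band %g +/- %g nm contains no source wavelengths",
                   c0, half), call. = FALSE)
    mean(hyper$values[sel])
  }, numeric(1))
  spectrum(bands$centers, vals, hyper$quantity_tag)
}

# ---- delimited-table I/O ----------------------------------------------------

#' Read and write spectra tables as delimited text
#'
#' Spectra tables are plain CSV: a header row of wavelengths (nm) and one row
#' per spectrum. `read_spectra_csv()` returns a list of [spectrum] objects;
#' `write_spectra_csv()` writes one. Covariance matrices use a square CSV with
#' the wavelength grid as both header and first column.
#'
#' @param path file path.
#' @param spectra list of [spectrum] objects sharing one grid.
#' @param quantity_tag tag assigned to spectra read from file.
#' @return `read_spectra_csv()`: list of [spectrum]; writers return the path,
#'   invisibly.
#' @export
read_spectra_csv <- function(path, quantity_tag = "Rrs") {
  tab <- utils::read.csv(path, check.names = FALSE)
  wl <- as.numeric(colnames(tab))
  if (any(is.na(wl)))
    stop("spectra CSV header must be numeric wavelengths", call. = FALSE)
  lapply(seq_len(nrow(tab)), function(i)
    spectrum(wl, as.numeric(tab[i, ]), quantity_tag))
}

#' @rdname read_spectra_csv
#' @export
write_spectra_csv <- function(spectra, path) {
  if (is_spectrum(spectra)) spectra <- list(spectra)
  wl <- spectra[[1]]$wavelengths
  m <- do.call(rbind, lapply(spectra, function(s) {
    if (!isTRUE(all.equal(s$wavelengths, wl)))
      stop("all spectra must share one wavelength grid", call. = FALSE)
    s$values
  }))
  colnames(m) <- wl
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_spectra_csv
#' @export
read_covariance_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  wl <- as.numeric(colnames(tab))
  spectral_covariance(wl, as.matrix(tab))
}

#' @rdname read_spectra_csv
#' @param V a [spectral_covariance].
#' @export
write_covariance_csv <- function(V, path) {
  stopifnot(is_spectral_covariance(V))
  m <- V$matrix
  dimnames(m) <- list(V$wavelengths, V$wavelengths)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
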