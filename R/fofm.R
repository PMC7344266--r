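#' The first-order first-moment (GUM) propagation law
#'
#' Given a scalar output `y = f(x)` and the gradient `g_i = df/dx_i`, the
#' law of propagation of uncertainty gives, for uncorrelated inputs,
#' \deqn{u^2(y) = \sum_i g_i^2 u^2(x_i)}
#' and, with input error covariance `V`,
#' \deqn{u^2(y) = g^T V g.}
#' These two operations are the propagation engine every product algorithm
#' in the package feeds.
#'
#' @param g numeric gradient vector (df/dx_i), or a [spectrum] whose values
#'   are the partials.
#' @param u numeric vector of 1-sigma input uncertainties (>= 0), or a
#'   [spectrum].
#' @return `propagate_uncorrelated()` and `propagate_covariance()` return the
#'   non-negative scalar `u(y)`. `propagate_covariance()` carries the
#'   attribute `clipped = TRUE` when a slightly negative quadratic form from
#'   roundoff was clipped to zero.
#' @export
#' @examples
#' propagate_uncorrelated(c(3, 4), c(1, 1))  # 5
propagate_uncorrelated <- function(g, u) {
  g <- spectral_values(g)
  u <- spectral_values(u)
  if (length(g) != length(u))
    stop("gradient and uncertainty vectors differ in length", call. = FALSE)
  if (any(!is.finite(g)) || any(!is.finite(u)))
    stop("non-finite entries in gradient or uncertainties", call. = FALSE)
  if (any(u < 0))
    stop("uncertainties must be non-negative", call. = FALSE)
  sqrt(sum((g * u)^2))
}

#' @rdname propagate_uncorrelated
#' @param V a [spectral_covariance] (or plain symmetric matrix) over the same
#'   grid as `g`.
#' @export
propagate_covariance <- function(g, V) {
  gv <- spectral_values(g)
  if (is_spectral_covariance(V)) {
    if (is_spectrum(g) &&
        !isTRUE(all.equal(g$wavelengths, V$wavelengths)))
      stop("gradient and covariance are on different wavelength grids",
           call. = FALSE)
    m <- V$matrix
  } else {
    m <- as.matrix(V)
    scale <- max(abs(m), 1e-300)
    if (!all(dim(m) == length(gv)) || max(abs(m - t(m))) > 1e-8 * scale)
      stop("V must be a symmetric matrix conformable with the gradient",
           call. = FALSE)
  }
  if (length(gv) != nrow(m))
    stop("gradient and covariance dimensions differ", call. = FALSE)
  v <- drop(crossprod(gv, m %*% gv))
  clipped <- FALSE
  if (v < 0) {
    if (v < -1e-8 * max(diag(m) * gv^2, 1e-300))
      warning("g'Vg substantially negative; check covariance validity")
    v <- 0
    clipped <- TRUE
  }
  structure(sqrt(v), clipped = clipped)
}

spectral_values <- function(x) {
  if (is_spectrum(x)) x$values else as.numeric(x)
}

#' Central-difference gradient of a scalar spectral model
#'
#' Numerical fallback used to verify every analytic gradient in the package:
#' central differences with per-band step
#' `h_i = max(eps_rel * |x_i|, eps_abs)`.
#'
#' @param f function taking a [spectrum] and returning a scalar (or a list
#'   with a `value` element).
#' @param s the [spectrum] at which to differentiate.
#' @param eps_rel,eps_abs relative and absolute step-size floors.
#' @return Numeric gradient vector, one partial per band of `s`.
#' @export
numeric_gradient <- function(f, s, eps_rel = 1e-5, eps_abs = 1e-9) {
  stopifnot(is_spectrum(s))
  eval_f <- function(sp) {
    y <- f(sp)
    if (is.list(y)) y <- y$value
    as.numeric(y)
  }
  x <- s$values
  vapply(seq_along(x), function(i) {
    h <- max(eps_rel * abs(x[i]), eps_abs)
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    yp <- eval_f(spectrum(s$wavelengths, xp, s$quantity_tag))
    ym <- eval_f(spectrum(s$wavelengths, xm, s$quantity_tag))
    if (!is.finite(yp) || !is.finite(ym))
      stop(sprintf("model non-finite when perturbing band %g nm",
                   s$wavelengths[i]), call. = FALSE)
    (yp - ym) / (2 * h)
  }, numeric(1))
}
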