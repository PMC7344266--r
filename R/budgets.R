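#' Measurement-uncertainty budgets for particulate organic carbon
#'
#' A product's measurement uncertainty combines two sources: data
#' uncertainty (propagated radiometry) and model uncertainty (imperfect
#' algorithm coefficients), combined in root-sum-square:
#' `u_measurement = sqrt(u_data^2 + u_model^2)`. Both POC algorithms
#' considered share the power-law form `POC = a X^b`, with `X` either the
#' blue-green reflectance ratio (standard algorithm, a = 203.2,
#' b = -1.034) or the particulate backscattering at 470 nm (IOP-based
#' algorithm, a = 141253, b = 1.18).
#'
#' @name budgets
NULL

#' Model-coefficient variance of a power-law POC algorithm
#'
#' First-order variance of `POC = a X^b` due to coefficient (and, for the
#' IOP-based model, input) model uncertainty, with zero coefficient
#' covariance:
#' \deqn{u^2 = (X^b)^2 u_a^2 + (a X^b \ln X)^2 u_b^2
#'   + (a b X^{b-1})^2 u_X^2.}
#' The logarithm is natural, the calculus-consistent derivative of `X^b`
#' with respect to `b`. Published defaults for the coefficient
#' uncertainties are (2.20, 0.015) for the blue-green ratio model and
#' (45534, 0.046) for the IOP-based model.
#'
#' @param X model input (ratio, dimensionless, or b_bp,470 in m^-1), > 0.
#' @param a,b power-law coefficients.
#' @param u_a,u_b,u_X model uncertainties of `a`, `b` and `X` (all >= 0;
#'   `u_X = 0` for the reflectance-ratio model).
#' @return `u_model(POC)` in mg m^-3.
#' @export
poc_model_variance <- function(X, a, b, u_a = 0, u_b = 0, u_X = 0) {
  if (!is.finite(X) || X <= 0)
    stop("power-law input X must be positive", call. = FALSE)
  if (any(c(u_a, u_b, u_X) < 0))
    stop("uncertainties must be non-negative", call. = FALSE)
  Xb <- X^b
  v <- Xb^2 * u_a^2 + (a * Xb * log(X))^2 * u_b^2 +
    (a * b * X^(b - 1))^2 * u_X^2
  sqrt(v)
}

#' Data variance of the IOP-based POC algorithm
#'
#' `u_data(POC) = |a b b470^(b-1)| u_data(b470)`, the first-order
#' propagation of the backscattering data uncertainty (itself obtained from
#' the inversion and [bbp_shift()]) through the power law.
#'
#' @param b470 particulate backscattering at 470 nm (m^-1), > 0.
#' @param u_b470 its 1-sigma data uncertainty (m^-1).
#' @param a,b power-law coefficients; published values 141253 and 1.18.
#' @return `u_data(POC)` in mg m^-3.
#' @export
poc_iop_data_variance <- function(b470, u_b470, a = 141253, b = 1.18) {
  if (!is.finite(b470) || b470 <= 0)
    stop("b_bp,470 must be positive", call. = FALSE)
  if (u_b470 < 0) stop("uncertainty must be non-negative", call. = FALSE)
  abs(a * b * b470^(b - 1)) * u_b470
}

#' Combine data and model uncertainty in root-sum-square
#'
#' @param u_data,u_model non-negative component uncertainties (product
#'   units).
#' @return `sqrt(u_data^2 + u_model^2)`.
#' @export
combine_measurement <- function(u_data, u_model) {
  if (any(u_data < 0) || any(u_model < 0))
    stop("component uncertainties must be non-negative", call. = FALSE)
  sqrt(u_data^2 + u_model^2)
}

#' Fractional contribution of variance components
#'
#' `fraction_k = u_k^2 / sum_j u_j^2`; the variance shares sum to 1 and are
#' the quantities shown in source-contribution pie charts.
#'
#' @param components named non-negative uncertainties (not variances).
#' @return Named numeric fractions summing to 1.
#' @export
budget_fractions <- function(components) {
  u <- as.numeric(components)
  if (any(u < 0)) stop("components must be non-negative", call. = FALSE)
  tot <- sum(u^2)
  if (tot == 0) stop("all components are zero", call. = FALSE)
  stats::setNames(u^2 / tot, names(components))
}

#' Full uncertainty budget for a POC estimate
#'
#' Assembles value, data and model uncertainty, combined measurement
#' uncertainty, and variance fractions into one object.
#'
#' @param value derived POC (mg m^-3).
#' @param u_data data (radiometric) uncertainty (mg m^-3).
#' @param u_model model uncertainty (mg m^-3).
#' @return Object of class `uncertainty_budget`: the inputs plus
#'   `u_measurement`, `rel_u_measurement` (percent) and `fractions`.
#' @export
uncertainty_budget <- function(value, u_data, u_model) {
  um <- combine_measurement(u_data, u_model)
  structure(list(value = value, u_data = u_data, u_model = u_model,
                 u_measurement = um,
                 rel_u_measurement = 100 * um / abs(value),
                 fractions = budget_fractions(c(data = u_data,
                                                model = u_model))),
            class = "uncertainty_budget")
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat(sprintf("value %.4g | u_data %.3g | u_model %.3g | u_measurement %.3g (%.1f%%)\n",
              x$value, x$u_data, x$u_model, x$u_measurement,
              x$rel_u_measurement))
  cat("variance fractions:",
      paste(sprintf("%s %.2f", names(x$fractions), x$fractions),
            collapse = ", "), "\n")
  invisible(x)
}
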