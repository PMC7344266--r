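#' Comparison statistics for appraising analytic against Monte-Carlo
#' uncertainties
#'
#' Both statistics work on log10-transformed values, appropriate for
#' bio-optical quantities whose uncertainties are log-normally distributed.
#'
#' @name appraisal
NULL

#' Multiplicative log-space bias
#'
#' `bias = 10^mean(log10(ref) - log10(test))`; with the Monte-Carlo
#' estimates as reference ("quasi-truth"), a bias of 1 means the analytic
#' method is unbiased in the multiplicative sense.
#'
#' @param ref,test positive numeric vectors of equal length.
#' @return Multiplicative bias (dimensionless, > 0).
#' @export
log_bias <- function(ref, test) {
  ref <- as.numeric(ref); test <- as.numeric(test)
  if (length(ref) != length(test))
    stop("ref and test differ in length", call. = FALSE)
  if (any(!is.finite(ref)) || any(!is.finite(test)) ||
      any(ref <= 0) || any(test <= 0))
    stop("log bias requires finite positive values", call. = FALSE)
  10^mean(log10(ref) - log10(test))
}

#' Type II (standardized major axis) regression slope in log space
#'
#' The SMA slope on `(log10 x, log10 y)`:
#' `sign(corr) * sd(log10 y)/sd(log10 x)`. Symmetric in the sense that
#' `slope(x, y) * slope(y, x) = 1`.
#'
#' @param x,y positive numeric vectors, length >= 3.
#' @return Dimensionless slope.
#' @export
type2_slope <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal-length x and y with n >= 3", call. = FALSE)
  if (any(x <= 0) || any(y <= 0))
    stop("type II slope computed on log-transformed positive values",
         call. = FALSE)
  lx <- log10(x); ly <- log10(y)
  sx <- stats::sd(lx); sy <- stats::sd(ly)
  if (sx == 0) stop("zero variance in x", call. = FALSE)
  r <- stats::cor(lx, ly)
  sign(ifelse(r == 0, 1, r)) * sy / sx
}

#' Paired comparison report
#'
#' Convenience wrapper producing per-product bias and slope from an
#' [mc_batch()] table (Monte-Carlo as reference).
#'
#' @param tab data.frame with columns `product`, `u_mc`, `u_fofm`.
#' @return data.frame with `product`, `bias`, `slope`, `n`.
#' @export
comparison_stats <- function(tab) {
  stopifnot(all(c("product", "u_mc", "u_fofm") %in% names(tab)))
  out <- lapply(split(tab, tab$product), function(d) {
    d <- d[is.finite(d$u_mc) & is.finite(d$u_fofm) &
             d$u_mc > 0 & d$u_fofm > 0, ]
    data.frame(product = d$product[1],
               bias = log_bias(d$u_mc, d$u_fofm),
               slope = if (nrow(d) >= 3)
                 type2_slope(d$u_fofm, d$u_mc) else NA_real_,
               n = nrow(d))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
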