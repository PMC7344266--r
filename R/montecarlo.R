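#' Monte-Carlo verification of first-order uncertainty estimates
#'
#' Perturbs an input spectrum with zero-mean Gaussian noise and builds the
#' empirical distribution of any scalar product, providing the benchmark
#' against which analytic propagation is appraised.
#'
#' @param model function mapping a [spectrum] to a scalar (or a list with a
#'   `value` element).
#' @param s the unperturbed input [spectrum].
#' @param u either a [spectrum] of per-band 1-sigma uncertainties
#'   (independent Gaussian perturbations, no spectral correlation) or a
#'   [spectral_covariance] (multivariate Gaussian draws).
#' @param n_iter number of draws; 5000 by default.
#' @param seed integer seed; mandatory so that identical seeds and inputs
#'   give identical results.
#' @return Object of class `mc_result`: `mean`, `sigma` (unbiased, n-1),
#'   `value0` (the unperturbed model value), `rel_sigma` (`sigma/|value0|`),
#'   `n_iter`, `n_failed`, `seed`. Draws on which the model raises an error
#'   are counted as failed and excluded; more than 50% failures is an
#'   error.
#' @export
mc_uncertainty <- function(model, s, u, n_iter = 5000, seed) {
  stopifnot(is_spectrum(s), n_iter >= 2)
  if (missing(seed)) stop("seed is mandatory for reproducibility",
                          call. = FALSE)
  nb <- length(s$wavelengths)
  eval_model <- function(sp) {
    y <- model(sp)
    if (is.list(y)) y <- y$value
    as.numeric(y)
  }
  value0 <- eval_model(s)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  if (is_spectral_covariance(u)) {
    if (!isTRUE(all.equal(u$wavelengths, s$wavelengths)))
      stop("covariance grid does not match spectrum", call. = FALSE)
    ev <- eigen(u$matrix, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nb)
    pert <- matrix(stats::rnorm(n_iter * nb), n_iter, nb) %*% t(L)
  } else {
    stopifnot(is_spectrum(u))
    if (!isTRUE(all.equal(u$wavelengths, s$wavelengths)))
      stop("uncertainty grid does not match spectrum", call. = FALSE)
    pert <- matrix(stats::rnorm(n_iter * nb), n_iter, nb) *
      rep(u$values, each = n_iter)
  }
  draws <- vapply(seq_len(n_iter), function(k) {
    vals <- s$values + pert[k, ]
    tryCatch(
      eval_model(structure(list(wavelengths = s$wavelengths, values = vals,
                                quantity_tag = s$quantity_tag),
                           class = "spectrum")),
      error = function(e) NA_real_)
  }, numeric(1))
  ok <- is.finite(draws)
  n_failed <- sum(!ok)
  if (n_failed > n_iter / 2)
    stop("more than 50% of Monte-Carlo draws failed; model undefined near input",
         call. = FALSE)
  structure(list(mean = mean(draws[ok]),
                 sigma = stats::sd(draws[ok]),
                 value0 = value0,
                 rel_sigma = stats::sd(draws[ok]) / abs(value0),
                 n_iter = n_iter, n_failed = n_failed,
                 seed = as.integer(seed)),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("<mc_result> mean %.6g  sigma %.6g  (%d draws, %d failed, seed %d)\n",
              x$mean, x$sigma, x$n_iter, x$n_failed, x$seed))
  invisible(x)
}

#' Batch Monte-Carlo vs analytic comparison table
#'
#' Runs each named model over a list of spectra, computing both the
#' analytic (first-order) and Monte-Carlo uncertainty per spectrum, the
#' shape of a dataset-wide comparison summary.
#'
#' @param models named list of functions; each must return
#'   `list(value, gradient)` so the analytic propagation can be formed.
#' @param spectra list of input [spectrum] objects.
#' @param u_fn function of a spectrum returning its uncertainty
#'   [spectrum] (e.g. `function(s) flat_u(s, 0.05)`).
#' @param n_iter Monte-Carlo draws per spectrum.
#' @param seed base seed; spectrum `i`, model `j` uses
#'   `seed + 1000 * j + i`.
#' @return A data.frame with columns `spectrum`, `product`, `value`,
#'   `u_fofm`, `u_mc`, `rel_u_fofm`, `rel_u_mc` (percent), `n_failed`,
#'   `failed` (model error on the unperturbed spectrum).
#' @export
mc_batch <- function(models, spectra, u_fn, n_iter = 5000, seed = 1) {
  stopifnot(length(models) > 0, !is.null(names(models)))
  rows <- list()
  for (j in seq_along(models)) {
    for (i in seq_along(spectra)) {
      s <- spectra[[i]]
      row <- tryCatch({
        res <- models[[j]](s)
        us <- u_fn(s)
        u_fofm <- propagate_uncorrelated(res$gradient, us$values)
        mc <- mc_uncertainty(models[[j]], s, us, n_iter = n_iter,
                             seed = seed + 1000 * j + i)
        data.frame(spectrum = i, product = names(models)[j],
                   value = res$value, u_fofm = u_fofm, u_mc = mc$sigma,
                   rel_u_fofm = 100 * u_fofm / abs(res$value),
                   rel_u_mc = 100 * mc$rel_sigma,
                   n_failed = mc$n_failed, failed = FALSE)
      }, error = function(e)
        data.frame(spectrum = i, product = names(models)[j],
                   value = NA_real_, u_fofm = NA_real_, u_mc = NA_real_,
                   rel_u_fofm = NA_real_, rel_u_mc = NA_real_,
                   n_failed = NA_integer_, failed = TRUE))
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}
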