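#' Batch drivers
#'
#' High-level entry points tying the modules together: compute products
#' with first-order uncertainties over a table of spectra
#' ([run_products()]), verify against Monte-Carlo ([run_mc_compare()]),
#' build POC measurement-uncertainty budgets ([run_budget()]), and write
#' synthetic datasets ([run_synth()]). A thin command-line wrapper over
#' these functions is installed at `system.file("scripts", "fofmoc",
#' package = "fofmoc")`.
#'
#' @name run
NULL

#' Uncertainty-model specification
#'
#' One of three regimes: `flat` (spectrally flat relative fraction),
#' `surface` (chlorophyll-indexed tabulated surface; the indexing
#' chlorophyll is the blended product computed from the spectrum itself),
#' or `cov` (full user-supplied covariance).
#'
#' @param type `"flat"`, `"surface"` or `"cov"`.
#' @param rel relative fraction (flat).
#' @param surf a [rel_uncertainty_surface] (surface).
#' @param V a [spectral_covariance] (cov).
#' @return Object of class `uncertainty_model`; calling
#'   `uncertainty_for(m, s)` yields the u-spectrum (flat/surface) or the
#'   covariance (cov) for spectrum `s`.
#' @export
uncertainty_model <- function(type = c("flat", "surface", "cov"),
                              rel = 0.05, surf = NULL, V = NULL) {
  type <- match.arg(type)
  if (type == "surface" && !inherits(surf, "rel_uncertainty_surface"))
    stop("surface model requires a rel_uncertainty_surface", call. = FALSE)
  if (type == "cov" && !is_spectral_covariance(V))
    stop("cov model requires a spectral_covariance", call. = FALSE)
  structure(list(type = type, rel = rel, surf = surf, V = V),
            class = "uncertainty_model")
}

#' @rdname uncertainty_model
#' @param m an `uncertainty_model`.
#' @param s the Rrs [spectrum] it applies to.
#' @export
uncertainty_for <- function(m, s) {
  stopifnot(inherits(m, "uncertainty_model"), is_spectrum(s))
  switch(m$type,
    flat = flat_u(s, m$rel),
    surface = {
      chl <- chl_blend(s)$value
      surface_u(m$surf, s, chl)
    },
    cov = {
      if (!isTRUE(all.equal(m$V$wavelengths, s$wavelengths)))
        stop("covariance grid does not match spectrum", call. = FALSE)
      m$V
    })
}

# product model registry: each returns list(value, gradient) w.r.t. the Rrs
# vector (nflh chains through the linear Rrs -> nLw conversion)
product_models <- function(products,
                           ocx = ocx_coefficients(),
                           lh = lh_chl_coefficients(),
                           bw = blend_window(),
                           kd = kd490_coefficients(),
                           pc = poc_coefficients(),
                           nb = nflh_bands(),
                           f0 = default_solar_irradiance()) {
  all <- list(
    chl = function(s) chl_blend(s, ocx, lh, bw),
    chl_br = function(s) chl_br(s, ocx),
    chl_lh = function(s) chl_lh(s, lh),
    kd490 = function(s) kd490(s, kd),
    poc = function(s) poc(s, pc),
    nflh = function(s) {
      nlw <- rrs_to_nlw(s, f0)
      r <- nflh(nlw, nb)
      i <- vapply(s$wavelengths, function(w) nearest_band(f0, w, 3),
                  integer(1))
      list(value = r$value, gradient = r$gradient * f0$values[i])
    })
  unknown <- setdiff(products, names(all))
  if (length(unknown))
    stop("unknown products: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  all[products]
}

#' Compute products and first-order uncertainties over a batch of spectra
#'
#' @param spectra list of Rrs [spectrum] objects.
#' @param unc an [uncertainty_model].
#' @param products character subset of `chl`, `chl_br`, `chl_lh`, `kd490`,
#'   `poc`, `nflh`.
#' @param use_covariance for a `cov` uncertainty model: `TRUE` uses the
#'   full matrix (off-diagonals included), `FALSE` zeroes the
#'   off-diagonals. Ignored for flat/surface models.
#' @param ... coefficient overrides passed to the product registry.
#' @return data.frame, one row per spectrum and product: `value`, `u`
#'   (1-sigma), `rel_u` (percent), `branch` (chl blend flag or `NA`),
#'   `failed`. Per-spectrum failures are flagged, never abort the batch.
#' @export
run_products <- function(spectra, unc = uncertainty_model("flat", 0.05),
                         products = c("chl", "kd490", "poc", "nflh"),
                         use_covariance = TRUE, ...) {
  if (length(products) == 0) stop("empty product list", call. = FALSE)
  if (is_spectrum(spectra)) spectra <- list(spectra)
  mods <- product_models(products, ...)
  rows <- list()
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    for (p in names(mods)) {
      rows[[length(rows) + 1]] <- tryCatch({
        res <- mods[[p]](s)
        um <- uncertainty_for(unc, s)
        u <- if (is_spectral_covariance(um)) {
          V <- if (use_covariance) um$matrix else diag(diag(um$matrix))
          as.numeric(propagate_covariance(res$gradient, V))
        } else {
          propagate_uncorrelated(res$gradient, um$values)
        }
        data.frame(spectrum = i, product = p, value = res$value, u = u,
                   rel_u = 100 * u / abs(res$value),
                   branch = if (!is.null(res$branch)) res$branch else NA,
                   failed = FALSE)
      }, error = function(e)
        data.frame(spectrum = i, product = p, value = NA_real_,
                   u = NA_real_, rel_u = NA_real_, branch = NA,
                   failed = TRUE))
    }
  }
  do.call(rbind, rows)
}

#' Summarize a product table into per-product median and range
#'
#' @param tab output of [run_products()].
#' @return data.frame per product: medians and ranges of value, absolute
#'   and relative uncertainty, and failure count.
#' @export
summarize_products <- function(tab) {
  out <- lapply(split(tab, tab$product), function(d) {
    ok <- d[!d$failed, ]
    data.frame(product = d$product[1],
               n = nrow(ok), n_failed = sum(d$failed),
               value_min = min(ok$value), value_median = stats::median(ok$value),
               value_max = max(ok$value),
               u_median = stats::median(ok$u),
               rel_u_median = stats::median(ok$rel_u))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Monte-Carlo vs first-order comparison over a batch
#'
#' Runs [mc_batch()] with the package's product models and appends the
#' per-product appraisal statistics (multiplicative log-space bias and
#' Type II slope, Monte-Carlo as reference).
#'
#' @inheritParams run_products
#' @param n_iter Monte-Carlo draws per spectrum.
#' @param seed integer seed.
#' @return List with `table` (per-spectrum comparison) and `stats`
#'   (per-product bias/slope).
#' @export
run_mc_compare <- function(spectra, unc = uncertainty_model("flat", 0.05),
                           products = c("kd490", "poc", "nflh"),
                           n_iter = 5000, seed = 1, ...) {
  if (unc$type == "cov")
    stop("MC comparison mode expects a per-band uncertainty model",
         call. = FALSE)
  mods <- product_models(products, ...)
  tab <- mc_batch(mods, spectra, function(s) uncertainty_for(unc, s),
                  n_iter = n_iter, seed = seed)
  list(table = tab, stats = comparison_stats(tab))
}

# covariance between the fitted backscattering amplitude and the slope,
# both driven by the same radiometric errors:
# cov = (G V_rrs g_gamma)[x_bp], G the Gauss-Markov map rrs-error -> x-error
bbp_gamma_covariance <- function(state, V_rrs) {
  cfg <- state$cfg
  g_gamma <- gamma_from_rrs(spectrum(cfg$fit_bands, state$rrs_obs, "rrs"),
                            cfg)$gradient
  G <- solve(crossprod(state$J), t(state$J))
  drop(G %*% V_rrs %*% g_gamma)[3]
}

#' POC measurement-uncertainty budgets over a batch of spectra
#'
#' For each spectrum, builds the data + model uncertainty budget of the
#' two POC algorithms:
#' * blue-green ratio model: data uncertainty by first-order propagation of
#'   the radiometric uncertainty; model uncertainty from the coefficient
#'   uncertainties (defaults 2.20 and 0.015);
#' * IOP-based model: the reflectance inversion supplies `b_bp` at the
#'   reference band with radiometric and misfit uncertainty; the amplitude
#'   is shifted to 470 nm including the slope variance and the
#'   amplitude-slope covariance (estimated from the same radiometric
#'   covariance); data and model components then propagate through the
#'   power law (coefficient uncertainty defaults 45534 and 0.046).
#'
#' @inheritParams run_products
#' @param giop a [giop_config] for the inversion.
#' @param br_coeffs [poc_coefficients] of the ratio model.
#' @param br_model_u `c(u_a, u_b)` coefficient uncertainties of the ratio
#'   model.
#' @param iop_coeffs `c(a, b)` of the IOP-based power law.
#' @param iop_model_u `c(u_a, u_b)` of the IOP-based model.
#' @param target_nm wavelength of the shifted backscattering input (nm).
#' @return data.frame, one row per spectrum and algorithm: `value`,
#'   `u_data`, `u_model`, `u_measurement`, `rel_u` (percent),
#'   `frac_data`, `frac_model`, `failed`.
#' @export
run_budget <- function(spectra, unc = uncertainty_model("flat", 0.05),
                       giop = giop_config(),
                       br_coeffs = poc_coefficients(),
                       br_model_u = c(2.20, 0.015),
                       iop_coeffs = c(141253, 1.18),
                       iop_model_u = c(45534, 0.046),
                       target_nm = 470) {
  if (is_spectrum(spectra)) spectra <- list(spectra)
  rows <- list()
  add <- function(i, algo, value, u_data, u_model) {
    b <- uncertainty_budget(value, u_data, u_model)
    rows[[length(rows) + 1]] <<- data.frame(
      spectrum = i, algorithm = algo, value = value,
      u_data = u_data, u_model = u_model,
      u_measurement = b$u_measurement, rel_u = b$rel_u_measurement,
      frac_data = b$fractions[["data"]], frac_model = b$fractions[["model"]],
      failed = FALSE)
  }
  fail <- function(i, algo) {
    rows[[length(rows) + 1]] <<- data.frame(
      spectrum = i, algorithm = algo, value = NA_real_, u_data = NA_real_,
      u_model = NA_real_, u_measurement = NA_real_, rel_u = NA_real_,
      frac_data = NA_real_, frac_model = NA_real_, failed = TRUE)
  }
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    # ratio model
    tryCatch({
      pr <- poc(s, br_coeffs)
      um <- uncertainty_for(unc, s)
      u_data <- if (is_spectral_covariance(um))
        as.numeric(propagate_covariance(pr$gradient, um$matrix))
      else propagate_uncorrelated(pr$gradient, um$values)
      u_model <- poc_model_variance(pr$X, br_coeffs$a_poc, br_coeffs$b_poc,
                                    u_a = br_model_u[1], u_b = br_model_u[2])
      add(i, "poc_ratio", pr$value, u_data, u_model)
    }, error = function(e) fail(i, "poc_ratio"))
    # IOP-based model
    tryCatch({
      state <- giop_invert(s, giop)
      if (!state$converged) stop("inversion did not converge")
      um <- uncertainty_for(unc, s)
      if (is_spectral_covariance(um)) {
        idx <- vapply(giop$fit_bands,
                      function(w) nearest_band(um$wavelengths, w, 3),
                      integer(1))
        VR <- um$matrix[idx, idx, drop = FALSE]
      } else {
        idx <- vapply(giop$fit_bands, function(w) nearest_band(um, w, 3),
                      integer(1))
        VR <- diag(um$values[idx]^2, length(idx))
      }
      iops <- derived_iops(state, VR)
      bbp_row <- iops[iops$product == "b_bp", ]
      d <- drrs_dRrs(state$Rrs_fit)
      V_rrs <- VR * tcrossprod(d)
      rrs_sp <- spectrum(giop$fit_bands, state$rrs_obs, "rrs")
      g_gamma_rrs <- gamma_from_rrs(rrs_sp, giop)$gradient
      u_gamma <- as.numeric(propagate_covariance(g_gamma_rrs, V_rrs))
      cov_bg <- bbp_gamma_covariance(state, V_rrs)
      sh_data <- bbp_shift(bbp_row$value, state$gamma, target_nm,
                           lambda_ref = giop$ref_band,
                           u_b = bbp_row$u_data, u_gamma = u_gamma,
                           cov_bg = cov_bg)
      sh_model <- bbp_shift(bbp_row$value, state$gamma, target_nm,
                            lambda_ref = giop$ref_band,
                            u_b = bbp_row$u_misfit)
      value <- iop_coeffs[1] * sh_data$value^iop_coeffs[2]
      u_data <- poc_iop_data_variance(sh_data$value, sh_data$u,
                                      a = iop_coeffs[1], b = iop_coeffs[2])
      u_model <- poc_model_variance(sh_data$value, iop_coeffs[1],
                                    iop_coeffs[2],
                                    u_a = iop_model_u[1],
                                    u_b = iop_model_u[2],
                                    u_X = sh_model$u)
      add(i, "poc_iop", value, u_data, u_model)
    }, error = function(e) fail(i, "poc_iop"))
  }
  do.call(rbind, rows)
}

#' Generate and write a synthetic dataset
#'
#' @param cfg a [synth_config].
#' @param spectra_path,truth_path output CSV paths.
#' @return The generated list, invisibly.
#' @export
run_synth <- function(cfg = synth_config(), spectra_path, truth_path) {
  gen <- generate_rrs(cfg)
  write_spectra_csv(gen$spectra, spectra_path)
  utils::write.csv(gen$truth, truth_path, row.names = FALSE)
  invisible(gen)
}
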