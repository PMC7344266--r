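# shared fixtures, all generated in code

# a fixed smooth positive 16-band Rrs spectrum (clear-water-like)
fixture_rrs <- function() {
  wl <- default_band_centers()
  spectrum(wl, 0.012 * exp(-(wl - 412) / 180) + 2e-4, "Rrs")
}

# batch of synthetic spectra from the generator (seed-deterministic)
fixture_batch <- function(n, seed = 42) {
  generate_rrs(synth_config(n = n, seed = seed))$spectra
}

# the four standard products as spectrum -> list(value, gradient) closures
product_models_for_tests <- function() {
  list(chl = function(s) chl_blend(s),
       kd490 = function(s) kd490(s),
       poc = function(s) poc(s),
       nflh = function(s) nflh(s))
}

# relative gradient discrepancy: max |analytic - numeric| scaled by the
# largest analytic entry
grad_relerr <- function(ga, gn) {
  scale <- max(abs(ga))
  if (scale == 0) return(max(abs(gn)))
  max(abs(ga - gn)) / scale
}
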