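---
title: "Propagating radiometric uncertainty through ocean-color algorithms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagating radiometric uncertainty through ocean-color algorithms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fofmoc)
```

## The problem

Every ocean-color data product — chlorophyll-a, diffuse attenuation,
particulate organic carbon (POC), fluorescence line height, inherent
optical properties (IOPs) — is derived from spectral remote-sensing
reflectance, $R_{rs}(\lambda)$ (sr$^{-1}$), which itself carries
radiometric uncertainty. `fofmoc` propagates that uncertainty through the
product algorithms analytically, using the first-order first-moment (FOFM)
law of propagation of uncertainty:

$$u^2(y) = \sum_i \left(\frac{\partial f}{\partial x_i}\right)^2 u^2(x_i)
  \;+\; 2 \sum_{i<j} \frac{\partial f}{\partial x_i}
  \frac{\partial f}{\partial x_j}\, u(x_i, x_j),$$

where the covariance terms are retained whenever a full spectral
covariance matrix $\mathbf{V}_{R_{rs}}$ is available
(`propagate_covariance()`), and dropped otherwise
(`propagate_uncorrelated()`). Because FOFM is a linearization, the package
also ships a Monte-Carlo engine (`mc_uncertainty()`) that perturbs each
band with zero-mean Gaussian noise and rebuilds the product distribution
empirically; agreement between the two routes is the standard check that
the algebraically complex analytic partials are correct.

## Product models and their gradients

Each product function returns `list(value, gradient)`, the gradient being
the analytic partial-derivative vector with respect to the input spectrum:

* `chl_br()` — maximum-band-ratio chlorophyll,
  $Chl = 10^{\sum_k a_k \chi^k}$ with
  $\chi = \log_{10}\max_b R_{rs}(b)/R_{rs}(555)$. Only the *active* blue
  band carries gradient; at an exact ratio tie the shortest wavelength is
  chosen and a discontinuity flag raised (the derivative does not exist at
  the tie, an inherent FOFM limitation).
* `chl_lh()` — color-index (line-height) chlorophyll, log-linear in a
  linear functional of three bands.
* `chl_blend()` — the standard blended product. Inside the blend window
  the weight $\alpha$ depends on $Chl_{LH}$ itself, so the full derivative
  includes $d\alpha/dR_{rs}$ cross terms. We implement the complete
  derivative; residual FOFM-vs-MC discrepancy near the window is inherent
  to linearizing a switching model. The blend is driven by $Chl_{LH}$
  (standard practice), with default window 0.15–0.2 mg m$^{-3}$.
* `kd490()` — diffuse attenuation with the 0.0166 m$^{-1}$ pure-water
  floor.
* `poc()` — blue-green power law $POC = a\,X^{b}$,
  $X = R_{rs}(443)/R_{rs}(555)$, published coefficients $a = 203.2$,
  $b = -1.034$. Under spectrally flat uncorrelated relative uncertainty
  $r$, the propagated relative uncertainty is the constant
  $|b|\sqrt{2}\,r$ — e.g. 7.31% at $r = 5\%$ — which makes POC a sharp
  analytic test case.
* `nflh()` — fluorescence line height on normalized water-leaving
  radiance, an exactly linear model for which FOFM and MC agree to
  sampling noise. On the package's 16-band grid the default triplet is
  665/678/710 nm; 667/678/748 is equally supported where those bands
  exist. `rrs_to_nlw()` converts $R_{rs}$ with a band-averaged solar
  irradiance table; gradients are expressed with respect to the quantity
  actually perturbed.

The polynomial coefficients of the band-ratio, line-height and Kd490
algorithms are not outputs of this package; the bundled defaults are the
standard NASA reprocessing values for a SeaWiFS-like band set and are
plain configuration — every structural test uses either degenerate
(coefficient-independent) forms or the published POC coefficients.

Every analytic gradient is verified against `numeric_gradient()` (central
differences, relative step $10^{-5}$, absolute floor $10^{-9}$ — a
compromise between truncation and roundoff for reflectances of order
$10^{-3}$) on batches of generated spectra, away from ratio ties and
window edges where the derivative is genuinely discontinuous.

## Radiometric uncertainty models

Three regimes are supported (`uncertainty_model()`):

* **flat** — $u(R_{rs,i}) = r\,|R_{rs,i}|$, the classical 1/5/10%
  mission-requirement scenarios. Uncertainty is applied to $|R_{rs}|$ so
  that rare negative red-band reflectances still receive a positive
  uncertainty.
* **surface** — a chlorophyll-indexed table of relative uncertainties of
  the kind published for on-orbit sensors: bilinear interpolation in
  wavelength (never extrapolated) and chlorophyll, linear extrapolation
  above the top chlorophyll level, clamped below the bottom one. The
  indexing chlorophyll is the blended product computed from the spectrum
  itself. The sensor-specific table is not shipped; a clearly synthetic
  illustrative surface is bundled for tests and examples.
* **cov** — a user-supplied $\mathbf{V}_{R_{rs}}$. `run_products()` can
  evaluate with the off-diagonals included or zeroed, the comparison that
  shows positively correlated radiometric errors partially cancel in
  ratio-based products.

## The reflectance inversion

`giop_invert()` implements a default-configuration semi-analytical
inversion: total absorption and backscattering are parameterized by three
amplitudes $(x_\phi, x_{dg}, x_{bp})$ at 443 nm with fixed spectral shapes
(chl-specific phytoplankton shape, exponential detrital/dissolved slope
$S_{dg} = 0.018$ nm$^{-1}$, power-law particulate backscattering), mapped
to sub-surface reflectance through the quadratic model
$r_{rs} = g_1 u + g_2 u^2$, $u = b_b/(a + b_b)$, $g_1 = 0.0949$,
$g_2 = 0.0794$ sr$^{-1}$. The backscattering slope $\gamma$ is fixed
before fitting from a QAA-style reflectance-ratio rule and is not a free
parameter; its uncertainty enters only where the amplitude is shifted in
wavelength (`bbp_shift()`). The unweighted least-squares fit runs over the
412–655 nm bands by Levenberg–Marquardt (`minpack.lm`), analytic Jacobian,
bounds $x \ge 0$, start $(0.1, 0.01, 10^{-3})$, `ftol = ptol = 1e-10`,
200 iterations; non-convergence returns a flagged state rather than an
error, mirroring per-pixel product masking. The fit residual is in
$r_{rs}$ space; the exact transform derivative
$dr_{rs}/dR_{rs} = 0.52/(0.52 + 1.7 R_{rs})^2$ chains above-surface
covariances into the fit.

Parameter uncertainty uses the Gauss–Markov sandwich
$$\mathbf{E}_x = (\mathbf{J}^T\mathbf{J})^{-1}\mathbf{J}^T \,\mathbf{V}\,
  \mathbf{J}(\mathbf{J}^T\mathbf{J})^{-1},$$
the generalization of $\mathbf{J}^{-1}\mathbf{V}(\mathbf{J}^T)^{-1}$ to a
non-square Jacobian (they coincide when $\mathbf{J}$ is square). Two
choices of $\mathbf{V}$ give the two uncertainty components:

* **data** — the radiometric covariance chained through $dr_{rs}/dR_{rs}$;
* **misfit** — $\mathbf{E}_{rrs} = \mathrm{diag}(\varepsilon_i^2)$ built
  from the optimum residuals, an estimate of model-imperfection
  uncertainty (`misfit_uncertainty()`). On noiseless synthetic spectra the
  residuals, and hence the misfit uncertainties, vanish to machine
  precision.

`derived_iops()` reports $a_\phi$, $a_{dg}$, $b_{bp}$ and their sum
$a_{nw} = a_\phi + a_{dg}$ at 443 nm, the $a_{nw}$ uncertainty including
the $x_\phi$–$x_{dg}$ covariance. Spectral-shape uncertainties
($u(a^*_\phi)$, $u(b^*_{bp})$) are deliberately not propagated; the
hooks exist but quantifying shape uncertainty is future work. The
reference wavelength is fixed at 443 nm throughout; the 440/443
distinction common in the literature is treated as the same band. The
bundled pure-water and phytoplankton-shape tables are approximate
literature-style values; no test depends on their exact numbers
(unit-shape configurations are used wherever arithmetic is asserted).

## Measurement-uncertainty budgets

`run_budget()` combines data and model uncertainty for two POC
algorithms sharing the power-law form $POC = a X^{b}$: the blue-green
ratio model ($a = 203.2$, $b = -1.034$, coefficient uncertainties
$\sim$2.20 and 0.015) and an IOP-based model with $X = b_{bp}(470)$
($a = 141253$, $b = 1.18$, coefficient uncertainties 45,534 and 0.046).
The coefficient variance is

$$u^2_{model} = (X^b)^2 u^2(a) + (a X^b \ln X)^2 u^2(b)
 + (a b X^{b-1})^2 u^2(X),$$

with the natural logarithm (the calculus-consistent derivative of $X^b$
with respect to $b$) and zero coefficient covariance. The combined
measurement uncertainty is the root-sum-square
$u_{meas} = \sqrt{u^2_{data} + u^2_{model}}$ — the form confirmed by
published budget arithmetic such as $\sqrt{4.40^2 + 0.94^2} = 4.50$. For
the IOP route, $b_{bp}(470)$ comes from the inversion amplitude shifted
with `bbp_shift()`, whose variance carries the slope term and the
amplitude–slope covariance; the package estimates that covariance from
the same radiometric covariance and the analytic $\gamma$ gradient rather
than assuming a fixed value. `budget_fractions()` returns the variance
shares behind source-contribution pie charts.

## What the synthetic generator emulates — and what it does not

The in-situ evaluation datasets this methodology is normally exercised on
are not redistributable, so `generate_rrs()` builds its own: chlorophyll
drawn log-uniformly over 0.03–1.3 mg m$^{-3}$ (bio-optical properties are
approximately log-normally distributed at sea), detrital/dissolved and
backscattering amplitudes tied to chlorophyll by power laws
($x_{dg} = 0.033\,Chl^{0.9}$, $x_{bp} = 0.004\,Chl^{0.6}$, lognormal
scatter with $\sigma_{\log} = 0.15$), and spectra produced by the
package's own forward model on the 16-band grid. The scalings were chosen
once so the derived products span realistic oligotrophic-to-mesotrophic
ranges (blended chlorophyll covering roughly 0.04–1.3 mg m$^{-3}$, Kd490
$\sim$0.02–0.13 m$^{-1}$, POC $\sim$15–200 mg m$^{-3}$). The slope
$\gamma$ is made self-consistent with the slope rule by fixed-point
iteration, so a noiseless inversion recovers the generating amplitudes
exactly — the round-trip test that anchors the inversion.

Two caveats follow. First, using the package's own forward model as the
generator makes inversion tests partly circular; that circularity is
broken by the independent Monte-Carlo oracle, closed-form checks, and
central-difference gradient verification, which do not share code with
the analytic path. Second, the generated spectra contain no fluorescence
peak, no Raman signal, no measurement artifacts and no optically complex
(Case-2) water types; passing tests demonstrate correctness of the
propagation calculus, not algorithm skill on real ocean data.

## Numerical choices

* Monte-Carlo: 5,000 draws by default, unbiased ($n-1$) standard
  deviation, relative uncertainty referenced to the unperturbed value
  (the mean is also reported). Draws on which a model raises a domain
  error (e.g. a perturbed reflectance ratio going non-positive) are
  excluded and counted; more than 50% failures aborts. Covariance draws
  use an eigenvalue factorization with negative roundoff eigenvalues
  clipped at zero.
* $g^T V g$ slightly negative from roundoff is clipped to zero with a
  flag (PSD inputs guarantee non-negativity analytically).
* Band matching: nominal centers resolved by nearest neighbour within
  3 nm; exact ratio ties take the shortest wavelength.
* Hyperspectral subsampling: unweighted boxcar mean over closed 10-nm
  intervals (no sensor response function is modeled).
* Type II regression: the standardized-major-axis estimator on
  log-transformed values; it is the conventional choice for
  uncertainty-validation scatter and is trivially swappable.
* Test problem sizes: 100-spectrum gradient sweeps, 200-spectrum
  Monte-Carlo appraisal at 500 draws per spectrum, 50-spectrum inversion
  round trips — sizes chosen to make the statistical bounds sharp while
  keeping the default suite quick.

## Worked example

```{r example, eval = FALSE}
gen <- generate_rrs(synth_config(n = 200, seed = 1))
tab <- run_products(gen$spectra, uncertainty_model("flat", 0.05))
summarize_products(tab)

cmp <- run_mc_compare(gen$spectra[1:50], products = c("kd490", "poc", "nflh"),
                      n_iter = 2000, seed = 1)
cmp$stats   # multiplicative bias and Type II slope, MC as reference
```

## Known limitations

FOFM is exact only for linear models; switching logic (maximum band
ratio, blend window) and strong nonlinearity produce genuine FOFM-vs-MC
disagreement that no implementation can remove. Spectral-shape
uncertainty in the inversion is not propagated. Covariance matrices are
consumed, not estimated, from satellite counts. No atmospheric
correction, BRDF/Raman handling, PIC, or satellite file ingestion is
included.
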