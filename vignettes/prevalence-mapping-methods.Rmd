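---
title: "Model-based geostatistics for district health atlases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based geostatistics for district health atlases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`prevatlas` implements a complete small-area prevalence-mapping pipeline of
the kind used to turn geolocated household-survey data (DHS-style cluster
surveys) into a subnational health-indicator atlas: gridded 5 km prevalence
surfaces with uncertainty, cross-validated model fits, and district-level
tables with confidence intervals. Because the survey microdata such
pipelines consume are access-restricted, the package ships a first-class
synthetic-data module that emulates the relevant features of the real
inputs, so every downstream stage is testable end to end without any
download.

This vignette records the model, the tunable parameters and their
defaults, the numerical choices, and the design decisions that were
genuinely open — the things a maintainer would want written down.

# The model

For clusters $i = 1, \dots, n$ at planar locations $s_i$ (km), with $m(s_i)$
sampled individuals and $Y(s_i)$ events of a binary indicator:

$$
Y(s_i) \mid m(s_i) \sim \mathrm{Binomial}\!\big(m(s_i),\, p(s_i)\big),
\qquad
\mathrm{logit}\, p(s_i) = x'(s_i)\beta + \omega(s_i) + \epsilon(s_i),
$$

where $\omega \sim N_n(0, \Sigma_\omega)$ is a Gaussian spatial random
effect with exponential covariance

$$
\Sigma_\omega = \sigma^2_\omega \exp(-\phi D),
$$

$D$ the Euclidean distance matrix between cluster locations, and
$\epsilon_i \sim N(0, \sigma^2_\epsilon)$ an independent (nugget) effect
per cluster. The spatial range is $3/\phi$: the distance at which
correlation decays to $e^{-3} \approx 0.05$.

Priors: independent $N(0, 1000)$ on each coefficient; penalized-complexity
(PC) priors on the spatial field — $P(\mathrm{range} < r_0) = 0.01$ with
$r_0$ defaulting to 5% of the east–west extent of the study domain, and
$P(\sigma_\omega > 3) = 0.01$; and a $\mathrm{Gamma}(2, 1)$ prior on the
precision of the nugget effect.

Two prior conventions deserve comment, and both are switchable in
`default_priors()`:

* **Sill prior direction.** The standard PC prior places a small tail
  probability on *large* standard deviations, $P(\sigma_\omega > u) =
  \alpha$. The reversed form $P(\sigma_\omega < 3) = 0.01$ would put 99%
  of its mass above 3 on the logit scale — implausibly diffuse (a logit SD
  of 3 swings prevalences from ~5% to ~95%). The standard direction is the
  default; `sigma_prior_direction = "as_printed"` selects the reversed
  one.
* **Nugget prior.** Hierarchical-model software conventionally parametrizes
  iid effects by their log precision. The default here is Gamma(2, 1) on
  the precision; `iid_prior = "as_printed"` instead places the Gamma(2, 1)
  density on the variance itself.

All coordinates are planar km throughout, with no geographic CRS. This
makes the Euclidean $D$ of the covariance function exact and removes any
projection ambiguity; real-survey users are expected to project their
coordinates to a suitable planar CRS (e.g. UTM) before import.

# Inference engine

The posterior is explored by Markov chain Monte Carlo with a dense,
exactly factorized covariance — no basis expansion, no mesh. At each
hyperparameter move an $n \times n$ Cholesky factorization is performed,
so the cost is $O(n^3)$ per iteration; this is deliberate. It is exact,
easy to verify against closed forms, and entirely adequate for surveys of
up to a few thousand clusters on one CPU. Sparse-approximation machinery
would buy scale at the price of a second approximation layer to validate.

The sampler has four kinds of move per iteration:

1. **Latent field — elliptical slice sampling.** The spatial effect and the
   nugget are sampled as one combined field $u = \omega + \epsilon$ with
   prior covariance $\Sigma_\omega + \sigma^2_\epsilon I$. The likelihood
   depends only on the sum, so sampling the two components separately forces
   the chain to random-walk along the variance-allocation direction —
   in experiments this mode mixed so slowly that the nugget absorbed
   spatial signal even after $10^4$ iterations. Sampling the sum removes
   that direction from the latent update entirely; the split is then
   governed by the hyperparameter moves and, at prediction time,
   marginalized exactly (below).
2. **Coefficients — adaptive random-walk Metropolis**, with the proposal
   covariance learned from the chain during burn-in (Haario-style) and a
   Robbins–Monro step-size adaptation targeting 25% acceptance.
3. **Coefficient–field interweaving.** A likelihood-invariant move proposes
   $\beta' = \beta + \delta$, $u' = u - X\delta$ and accepts on the prior
   ratio. The posterior strongly couples the intercept (and slopes) to the
   level of the field; without this move credible intervals for $\beta$
   were materially too narrow (67% empirical coverage of 95% intervals in
   a pilot run; with it, coverage is nominal).
4. **Hyperparameters — centred/whitened Metropolis pair**, alternated
   between iterations on $(\log \sigma^2_\omega, \log \phi, \log
   \sigma^2_\epsilon)$. The centred move holds $u$ fixed and accepts on the
   multivariate-normal prior density of $u$ (this is what identifies the
   spatial-vs-nugget split from the field's empirical structure); the
   whitened move holds the standard-normal innovations $z = U^{-T} u$ fixed,
   rescaling $u$, and accepts on the likelihood (this is what moves the
   overall scale). Each alternation costs one Cholesky factorization.

Adaptation runs during burn-in only, so the post-burn-in chain is a fixed
Markov kernel. All randomness flows from the single `seed` in
`inference_config()`; fits are bit-reproducible, and the generator state of
the calling session is saved and restored around every stochastic function
in the package.

Defaults (`inference_config()`): 3000 iterations, 800 burn-in, thinning 2
(1100 retained draws). These were chosen as the point where replicate
simulation studies at $n = 300$ clusters achieve nominal interval coverage
while a single fit stays near ten seconds; longer chains sharpen
Monte-Carlo error but did not change scientific conclusions in the
replicate studies. Diagnostics report acceptance rates and flag fits whose
hyperparameter acceptance collapses.

`fix = list(sigma2_omega = 0)` and `fix = list(sigma2_eps = 0)` switch
components off exactly (useful for reductions: with both fixed at zero the
model is Bayesian logistic regression, tested against the GLM MLE).

# Prediction surfaces

Covariate grids at their native 1 km resolution are block-averaged to the
5 km modelling resolution (`aggregate_grid`, missing-aware block means).
For each retained posterior draw, the spatial effect at the prediction
cell centres is simulated from its exact conditional distribution given
the combined latent field $u$ at the data sites:

$$
\omega_{\mathrm{new}} \mid u \sim N\!\big(\Sigma_{no} S^{-1} u,\;
\Sigma_{nn} - \Sigma_{no} S^{-1} \Sigma_{on}\big),
\qquad S = \Sigma_\omega + \sigma^2_\epsilon I .
$$

Conditioning on $u$ rather than on a sampled $\omega$ marginalizes the
spatial/nugget split analytically, draw by draw. Cells are simulated
jointly in row blocks (default 256 cells) to bound memory. The cell-level
prevalence is $\mathrm{logit}^{-1}(x'\beta + \omega_{\mathrm{new}})$; the
nugget is **excluded** by default, so the surface is the stable prevalence
field rather than cluster-level noise — `include_nugget = TRUE` adds it
for users who want total predictive spread. The posterior mean and the
standard deviation over draws form the prediction and uncertainty
surfaces. The SD uses the divisor $n_{\mathrm{draws}}$, so a single draw
yields an identically zero uncertainty surface rather than an undefined
one.

Cell ownership everywhere (extraction at points, zonal statistics) follows
a half-open rule — a point on a shared cell edge belongs to the cell to
its east, or south for horizontal edges — so extraction and zonal
aggregation are bit-reproducible and no cell is ever counted twice.

# Covariate selection

Selection is two-staged and deterministic given the data:

1. *Collinearity screen.* Pairs with $|r| > 0.8$ in the Pearson matrix are
   flagged (absolute value: strong negative collinearity is as harmful as
   positive); each flagged covariate is fitted alone (intercept plus
   covariate) in a binomial GLM and the lower-BIC member of each pair is
   retained. Remaining covariates with VIF > 4 are removed
   iteratively, worst first, with infinite VIFs (exact collinearity)
   removed before anything else.
2. *Backward stepwise BIC.* From the full screened model, the single
   removal with the lowest BIC is adopted if it improves the current BIC;
   the search stops when no removal improves, so the final model is
   locally optimal by construction. The intercept is never a removal
   candidate.

BIC is computed as $-2\log L + k \log n$ with $n$ the number of clusters —
the modelled observational units — not the number of Bernoulli trials.
Ties in the pairwise-BIC stage break deterministically toward the
lower-index covariate, with a warning.

# Cross-validation

`cross_validate()` refits the full spatial model on each of $k$ training
folds (default $k = 5$; the fold count is a free choice, five being the
common compromise between bias and cost) and predicts the posterior mean
prevalence at held-out cluster locations. Observed values are the held-out
empirical proportions $y_i / m_i$. Four metrics are reported per fold and
pooled: Pearson correlation, RMSE, MAE, and percentage bias
$100 \sum_i(\hat p_i - p_i) / \sum_j p_j$. A fold that fails to fit is
flagged and excluded from the pooled metrics with a warning. Random fold
assignment is seeded; spatially blocked CV is noted as better practice for
strongly autocorrelated data but is not implemented here.

Because predictions are posterior means while observations carry binomial
noise of scale $\sqrt{p(1-p)/m}$, the attainable correlation is bounded
below 1 even for a perfect model — at $m = 22$ and mid-range prevalences
the noise SD is about 0.1, which should be kept in mind when reading
$\rho$.

# District-level estimators

For indicators too rare (or too model-dependent) for cluster-level
mapping, the package provides district estimators with confidence
intervals:

* **Wilson score** intervals for proportions. Exact enumeration at
  $m = 22$ shows coverage 0.94–0.95 at moderate prevalences; at $p = 0.05$
  the discreteness of the binomial makes the interval conservative
  (coverage ≈ 0.978). That is a property of the interval itself, shared by
  its textbook presentations, not an implementation artefact.
* **Byar's approximation** for Poisson rates with counts above 5, and
  **exact (Garwood) limits** — computed from the gamma/chi-square
  relation rather than printed tables — for counts of 5 or fewer. The
  boundary count of exactly 5 is routed to the exact method, the
  conservative choice. Byar's endpoints agree with the exact limits to
  within 2% at counts ≥ 20 and 0.5% at counts ≥ 100.
* **Delta-method** intervals for modelled rates from saturated per-group
  GLMs (Poisson with log-exposure offset for fertility-style rates,
  binomial for mortality-style rates). Intervals are built symmetrically
  on the link scale and then transformed, which keeps rate intervals
  non-negative and probability intervals inside $[0, 1]$; the reported
  natural-scale standard error is the first-order delta value
  $|t'(\theta)|\,\mathrm{se}(\theta)$.
* **Synthetic-cohort child mortality**: the probabilities of dying in the
  age segments 12–23, 24–35, 36–47 and 48–59 months compose into the 1–4
  year probability as $1000\,(1 - \prod_j (1 - q_j))$.

Every district estimate carries the relative width of its 95% interval,
$(\mathrm{hi} - \mathrm{lo}) / \mathrm{estimate}$, the atlas's uncertainty
metric; it is undefined (returned as `NA` with a warning, never infinity)
for a zero estimate.

# The synthetic-data generator

The generator emulates the features of a geolocated cluster survey that
matter to the pipeline:

* **Clusters.** Locations uniform over the domain, with an urban/rural flag
  drawn at the requested urban fraction. The real two-stage
  probability-proportional-to-size design is deliberately simplified: the
  model conditions on cluster locations, so the fitting stages are
  unaffected by the location process.
* **Displacement.** Reported coordinates are the true ones perturbed by a
  uniform angle and a distance uniform on $[0, \mathrm{cap}]$ — 2 km for
  urban clusters, 5 km for rural, 10 km for a randomly chosen
  $\lfloor 1\% \rfloor$ subset of rural clusters, mirroring DHS
  confidentiality practice. A displaced point that leaves the domain is
  redrawn rather than clipped, preserving the distance distribution (the
  boundary behaviour of the real procedure is not public). Both true and
  reported locations are kept, so either convention can be used in
  fitting: the default fits on reported locations, as an analyst of the
  disclosure-protected data would; `use_locations = "true"` quantifies the
  displacement bias in simulations.
* **Covariates.** Smooth standardized Gaussian random fields at 1 km,
  produced by FFT convolution of white noise with a squared-exponential
  kernel (zero-padded: no periodic wrap-around), standing in for
  real gridded geospatial covariates.
* **Outcomes.** Binomial draws from the model above with known parameters,
  with the spatial covariance evaluated on the *true* locations
  (displacement happens after outcomes exist). Trials default to 22 per
  cluster, the households-per-cluster count of the emulated survey design.

What the generator does **not** emulate: survey weights, household
non-response, within-cluster correlation beyond the binomial, covariate
measurement error, and real administrative geographies (districts are
rectangular tilings). Passing tests therefore demonstrate the correctness
and calibration of the *methods* under the stated generative model, not
the accuracy of any real-world atlas.

# Numerical choices

* Covariance factorizations add a relative jitter of $10^{-8}
  \sigma^2_\omega$ to the diagonal before Cholesky; non-positive-definite
  failures after jitter raise errors naming the offending hyperparameters.
* Duplicated locations are permitted (warning) — the jitter keeps the
  factorization valid.
* Separation in screening GLMs (diverging coefficients or boundary fitted
  probabilities) marks the fit unconverged with a warning, and BIC refuses
  unconverged fits.
* Rasters are float on disk at 17 significant digits (lossless for
  doubles) in ESRI ASCII grid format with nodata −9999; polygons as
  GeoJSON in planar km. Plain-text formats keep every artefact diffable
  and round-trips exact at the written precision.
* Replicate-study sizes used in the package's own validation (chosen to
  keep each study minutes-scale on a single CPU): 50 simulate-and-fit
  replicates at $n = 300$ clusters for interval calibration; 100
  replicates at $n = 800$ for the selection-vs-exhaustive-search
  comparison; $10^5$ clusters for displacement-cap checks.

# Known limitations

* Dense $O(n^3)$ covariance algebra bounds practical problem sizes to a
  few thousand clusters.
* The spatial range is weakly identified at moderate $n$ (a classical
  property of this model class): posterior medians within a factor of two
  of the truth are the realistic expectation, and range and sill trade off
  against each other. Coefficient inference and the prevalence surfaces,
  the quantities the atlas reports, are robust to this.
* Percentage bias uses the sum of observed test values as denominator and
  is undefined when that sum is zero (flagged, not silently dropped).
* No reprojection: inputs must already be planar km.

# Worked example

```{r, eval = FALSE}
library(prevatlas)

res <- run_atlas(seed = 11, out = "atlas-out")
res$selection$final_names   # covariates surviving screening + backward BIC
res$fit                     # posterior summaries for beta and hypers
res$cv$pooled               # held-out rho / rmse / mae / pct_bias
head(res$district_table)    # Wilson intervals per district
```

The same pipeline is scriptable stage by stage (`generate_domain`,
`sample_clusters`, `displace_coordinates`, `generate_covariate_grids`,
`attach_covariates`, `simulate_outcomes`, `select_covariates`,
`fit_spatial_binomial`, `predict_surface`, `cross_validate`,
`zonal_mean`, `district_estimates`), and from the shell via
`inst/cli/atlas.R`.
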