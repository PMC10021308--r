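---
title: "Spatial targeting of house-based malaria interventions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial targeting of house-based malaria interventions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(setprior)
```

## The problem

Screening + Eave Tubes (SET) is a house modification for malaria control:
windows and eaves are screened and closed, and PVC tubes holding
insecticide-treated netting are fitted into the eave gap, where they kill
host-seeking mosquitoes. SET can only be installed in houses whose walls can
hold the tubes and whose roof line can be closed — in practice, houses with
finished walls (cement, bricks, cement blocks, stone set in lime or cement)
and finished roofs (metal, cement, ceramic tiles, roofing shingles). Before
a national programme can plan deployment it needs to know *where* enough
houses are suitable, how many people such a programme would cover, and what
it would cost.

`setprior` implements that targeting analysis as a reusable pipeline:

1. classify surveyed households as suitable or not from wall and roof
   material codes, and aggregate to survey-cluster counts;
2. correct the positional masking applied to rural survey clusters;
3. extract buffered covariate means at cluster locations;
4. fit a Bayesian beta-binomial logistic geostatistical model with a Matérn
   Gaussian process;
5. map, for every 5 km grid cell, the posterior mean suitability and the
   probability that true suitability exceeds 80% (the village-inclusion
   criterion of the SET cluster-randomised trial);
6. shortlist cells with three exclusion rules, estimate covered population
   and annual cost, and rank administrative departments by a signed z-score
   sum.

Because household surveys and national raster surfaces cannot be shipped, a
synthetic-data generator reproduces the statistical structure of all inputs,
and the whole pipeline is tested against it.

## The observation model

Let $Y_i$ be the number of SET-suitable households among the $n_i$ surveyed
in cluster $i$ at location $x_i$. The model is

$$Y_i \mid P(x_i) \sim \mathrm{Bin}(n_i, P(x_i)), \qquad
  P(x_i) \sim \mathrm{Beta}(\alpha_i, \beta_i),$$

with the Beta law tied to a logit-linear spatial predictor through the
mean–precision reparameterisation $\alpha_i = \mu_i\phi$,
$\beta_i = (1-\mu_i)\phi$:

$$\mathrm{logit}(\mu_i) = \beta_0 + x_i'\beta + S(x_i), \qquad
  S \sim \mathcal{GP}\!\left(0, C_\nu(\cdot;\sigma,\ell)\right).$$

The mean–precision link is a deliberate design choice: a Beta layer and a
logit-linear predictor only cohere if the linear predictor drives the Beta
*mean*, leaving a single precision $\phi$ to absorb within-cluster
overdispersion that the smooth spatial field cannot. Marginally the counts
are beta-binomial with variance
$n\mu(1-\mu)\left[1 + (n-1)/(1+\phi)\right]$; $\phi \to \infty$ recovers the
plain binomial. Cluster sizes vary (15–32 households in the motivating
survey), so $n_i$ is per-cluster throughout.

### Matérn covariance convention

The spatial field uses the Matérn family

$$C_\nu(d) = \sigma^2 \frac{2^{1-\nu}}{\Gamma(\nu)}
  \left(\sqrt{2\nu}\,\frac{d}{\ell}\right)^\nu
  K_\nu\!\left(\sqrt{2\nu}\,\frac{d}{\ell}\right),$$

i.e. the $\sqrt{2\nu}$ *scale* convention: at $\nu = 1/2$ this is exactly
$\sigma^2 e^{-d/\ell}$, and the practical range (correlation near 0.1) sits
at roughly $3\ell$. The smoothness default is $\nu = 1$, the value implied
in two dimensions by the common SPDE default $\alpha = 2$. Mesh-based SPDE
machinery is deliberately *not* reproduced: at desk scale (a few thousand
sites and cells) the exact GP the SPDE approximates is tractable directly,
so the package works with dense Matérn covariance matrices, a relative
diagonal jitter of $10^{-8}\sigma^2$, and blocked prediction beyond 2000
cells per block.

## Inference

The default backend follows the latent-Gaussian recipe:

* **Inner step.** For fixed hyperparameters $(\sigma, \ell, \phi)$, Newton
  ascent finds the joint mode of $z = (\beta, S_{\text{sites}})$ of the
  penalised log-posterior. The negative second derivative of the
  beta-binomial log-likelihood in $\eta$ can be locally negative for small
  $\phi$, so it is clamped below at a small positive value (a Fisher-like
  curvature), and a backtracking line search guarantees ascent.
* **Outer step.** The three log hyperparameters are optimised on the
  Laplace-approximate marginal posterior (Nelder–Mead; Brent when only one
  is free), with the latent mode warm-started between evaluations.
* **Skewness correction.** A Gaussian centred at the joint mode is biased
  when many clusters sit near saturation ($k_i = n_i$): the latent posterior
  is right-skewed and the mode underestimates the mean, which propagates
  into exceedance probabilities biased low. The package therefore shifts the
  Gaussian centre by $\Sigma A^\top \left(\tfrac12\, T \odot
  \mathrm{var}(\eta)\right)$, where $T$ is the third $\eta$-derivative of the
  log-likelihood at the mode — the mean correction of simplified-Laplace
  inference. Against the MCMC backend this removes most of the bias; it can
  be disabled with `skew_correction = FALSE`.
* **Uncertainty propagation.** Posterior functionals are computed from joint
  Gaussian draws of $(\beta, S_{\text{sites}})$ at the corrected centre,
  with hyperparameters held at their posterior mode. Hyperparameter
  uncertainty is thus not propagated — a known limitation shared with
  empirical-Bayes practice; the calibration check below bounds its practical
  effect.

Priors are explicit configuration because the motivating analysis does not
state its own: $N(0, 5^2)$ on fixed effects, half-normal (scale 2) on
$\sigma$, log-normal on $\ell$ centred at one third of the site-cloud
diameter (sdlog 1), log-normal on $\phi$ (meanlog $\log 10$, sdlog 1.5).
All are overridable in `set_model_spec()`.

A cross-check backend (`backend = "mcmc"`) runs elliptical slice sampling on
the latent Gaussian block with random-walk Metropolis on the log
hyperparameters. It is exact in the limit and used in the test suite to
validate the Laplace approximation; it is slower and not the default.

### Prediction and exceedance

For each posterior draw, the field at a cell centre is drawn from the GP
conditional $S_{\text{cell}} \mid S_{\text{sites}}$ (mean
$K_{cs}K_{ss}^{-1}S_{\text{sites}}$, variance
$\sigma^2 - K_{cs}K_{ss}^{-1}K_{sc}$). Draws are conditionally independent
*across cells* given the site values: per-cell means, standard deviations
and exceedance probabilities are unaffected, but joint statements about
several cells are not supported. Cell covariates use cell-centre values (the
radius-0 convention), transformed by the standardization recorded at fit
time. The exceedance probability of threshold $T$ (default 0.8) is the
fraction of draws with $\mathrm{logit}^{-1}(\eta) > T$, so it is by
construction non-increasing in $T$ on a fixed draw set.

## Decision layer

A grid cell is **excluded** when any of three rules fires — exceedance
probability below 0.70, parasite rate below 0.10 (little epidemiological
payoff), or travel time to the nearest major city above 180 minutes
(impractical logistics). All inequalities are strict, following the stated
rules literally; a cell exactly at a boundary is retained. Included cells
split into **high** transmission (parasite rate strictly above 0.35) versus
**moderate**. Each excluded cell records *every* violated rule.

Covered population is summed over the targeted strata and multiplied by the
trial's cost per person protected per year, \$21.47 (90% credible interval
\$6.08–\$49.99), giving point and interval costs for a high-only or a
moderate-plus-high strategy.

Departments are ranked by a signed z-score sum over four variables: mean
exceedance, mean parasite rate and mean travel time over the department's
included cells, plus the percentage of its area that is included. The
reference mean is the national mean over included cells (for the three cell
variables) or the national mean of per-department included area; the
denominator is the standard deviation across department means, because the
departments are the units being compared and a z-score needs a spread — the
source analysis does not state its denominator, so this choice is made
explicit here. Signs: exceedance, parasite rate and area count positively,
travel negatively. Ties break on department id; departments with no included
cells rank last and are flagged rather than scored.

## The synthetic world

`simulate_set_data()` generates the full input set with the statistical
structure the analysis assumes:

* a projected-plane grid of 5 km cells (the "5 km² grid square" of the
  motivating analysis is read as a 5 km × 5 km cell; the wording is
  ambiguous and the size is configurable);
* smooth standardized covariate fields (Matérn, $\nu = 1$, default scale
  30 km) standing in for aridity, travel time, urbanisation and crop value —
  right spatial statistics, no semantics;
* a latent Matérn field and the true suitability surface
  $p(x) = \mathrm{logit}^{-1}(\beta_0 + \sum_j \beta_j c_j(x) + S(x))$;
* clusters on distinct cells, sizes uniform on 15–32, suitable counts
  beta-binomial around the cell truth, and per-household wall/roof codes
  drawn from the appropriate/inappropriate catalogs so classification is
  exercised end to end;
* positional displacement as applied to real survey coordinates — uniform
  angle, distance uniform on [0, 2 km] for urban and [0, 10 km] for rural
  clusters (true coordinates are retained for test oracles). Real
  displacement respects administrative boundaries; the synthetic one does
  not, which is flagged here rather than imitated;
* context rasters: parasite rate squashed into [0, 0.65] (the approximate
  national range from near-elimination cities to the highest-burden
  districts), a population surface with exact zeros and clumped settlements,
  a travel-time surface anchored at the most populous cells, and a
  tessellation into contiguous toy departments via nearest-seed regions.

Default generator parameters state the world of the recovery experiments:
$\beta_0 = -0.5$, $\beta = (1.5, -0.8)$, $\sigma = 1$, $\ell = 25$ km,
$\phi = 15$, 150 clusters, 35% urban. The urban fraction and covariate
scale are package choices (a mostly rural survey frame; covariate fields
somewhat smoother than the GP) fixed once and documented here. The
calibration experiments use a world straddling the 80% threshold
($\beta_0 = 1.4$, $\beta = (0.8, -0.5)$, 80 clusters on a 20 × 20 grid) so
that exceedance probabilities populate all reliability bins.

What a green test establishes — and what it does not: the generator shares
the fitted model's functional form, so recovery and calibration checks
validate the *inference machinery*, not robustness to misspecified
covariates, non-stationary fields, or survey design effects. Real DHS data
also carry sampling weights, which the motivating analysis (and hence this
package) does not use.

## Geolocation correction

Rural cluster coordinates are masked by up to 10 km, so the analysis snaps
each rural cluster to the centre of the nearest cell with population above a
threshold (default: any positive population) within a search radius
(default 10 km). This is an automatic surrogate for the published manual
satellite-image re-georeferencing, which has no algorithmic description;
both the population threshold and the distance cap are configuration knobs.
Urban clusters are never adjusted. Ties break to the smaller distance, then
the smaller row-major cell index; unmatched clusters stay in place and are
flagged. On sparse synthetic settlements with true locations on populated
cells, snapping does not worsen — and typically improves — the median
distance to the withheld truth, which is the property motivating the
correction.

## Covariate extraction

Cluster covariates are means over a 2 km buffer: all cells whose centres
fall in the closed disk. Centre-in-disk was chosen over area-weighted
intersection for exact testability against an enumeration oracle; with 5 km
cells and a 2 km buffer the disk often contains no centre, in which case the
containing cell's value is used (and logged) — matching single-cell
extraction. Covariates are standardized by default (the source is silent;
GP-plus-fixed-effect models fit more stably standardized) and the
standardization record is replayed at prediction time, since an
unstandardised prediction grid would silently shift every coefficient.

## Housing-improvement scenario

The 20% improvement scenario models housing upgrades as *independent
per-component transitions*: each inappropriate wall upgrades with
probability 0.2, likewise each roof, so a house failing both has upgrade
probability $0.2^2 = 0.04$. This household-material reading is the default
because the rate is anchored in observed material transitions; the
alternative reading — adding 0.2 to each cluster proportion, capped at 1 —
ships as `mode = "additive"`. The `expected` mode propagates expected
(non-integer) suitable counts, which the beta-binomial likelihood accepts
through its gamma-function form; `stochastic` mode re-draws material codes
and re-classifies. Rate 0 reproduces the baseline bit for bit; rate 1
saturates every cluster.

## Numerical choices, degenerate inputs, limitations

* Linear predictors are clamped to $\pm 30$ inside the likelihood so
  saturated proportions cannot produce `NaN` gamma terms.
* Covariance matrices carry $10^{-8}\sigma^2$ diagonal jitter; a
  non-positive-definite matrix after jitter is a hard error with diagnostics,
  never a silent fallback.
* Inner-Newton non-convergence (gradient norm above tolerance) and optimiser
  failure are hard errors carrying diagnostics.
* All-equal cluster proportions (e.g. a rate-1 scenario) trigger a warning
  that the fit is prior-driven.
* Quantile summaries use the linear-interpolation convention (`type = 7`).
* Unknown material codes classify as unsuitable with a warning — the
  conservative choice for a feasibility screen.
* The empty-buffer fallback, the boundary conventions of the decision rules,
  and the ranking tie-breaks are all exact, documented behaviours with tests
  pinned to them.
* Known limitations: hyperparameter uncertainty is not propagated;
  cross-cell joint uncertainty is not represented; the synthetic world shares
  the model's form. The headline national coverage and cost figures of the
  motivating study depend on its proprietary survey and raster inputs and
  are out of reach of the synthetic world by design — the package reproduces
  the *method*, and its acceptance checks are property-based.

## A worked run

```{r pipeline, eval = FALSE}
sim <- simulate_set_data(grid_spec(30, 30, 5000), n_clusters = 150, seed = 1)
res <- run_set_pipeline(sim, seed = 1)
summary(res$fit)
res$cost_high
head(res$ranking)
plot(res$surface)
```

`run_set_pipeline()` chains every stage above; `run_scenario()` reruns it on
improved housing and reports newly included cells and the change in covered
population and cost.
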