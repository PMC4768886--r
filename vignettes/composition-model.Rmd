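---
title: "A Bayesian spatial multinomial probit model for tree composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian spatial multinomial probit model for tree composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spcomp)
```

## The problem

Settlement-era land-survey records give counts of trees by taxon, either
per cell of a regular grid (point surveys aggregated to, e.g., an 8 km
lattice) or summed over irregular administrative units ("townships")
whose within-unit tree locations are unknown. `spcomp` estimates the
latent composition — the vector of per-taxon proportions
$\theta_p(s_i)$ on the unit simplex at every grid cell $s_i$ — together
with full posterior uncertainty, smoothing over sampling noise,
interpolating across cells with no data, and reconciling the two
observation supports in a single model.

## Model

Counts in cell $i$ are multinomial,
$y_i \sim \mathrm{Multinomial}(n_i, \theta(s_i))$, without
overdispersion. Composition is linked to $P$ independent latent Gaussian
fields $\alpha_p$, one per taxon, through a multinomial probit: each
tree $j$ carries latent utilities
$W_{ijp} \sim \mathrm{N}(\alpha_p(s_i), 1)$, independent across taxa,
and the observed taxon is the argmax. Consequently
$\theta_p(s_i) = \Pr(W_{ijp} = \max_q W_{ijq})$, with an automatic
sum-to-one constraint. Only differences between the $\alpha_p$ at a
cell matter for $\theta$; the common level is not identified by the
data and is held down only by the priors.

Two spatial priors for each field are supported, on the cells of a
buffered lattice (the core grid plus `buffer_width` cells on every side;
buffer cells are ordinary cells with zero observations whose role is to
push boundary artifacts away from the cells that are reported):

* **CAR (intrinsic autoregression).** $\alpha_p \sim
  \mathrm{N}(0, \sigma_p^2 Q^{-})$ with $Q = D - C$, where $C$ is the
  four-cardinal-neighbor adjacency and $D$ its degree diagonal. $Q$ has
  rank $m - 1$; the improper flat level is left unconstrained during
  sampling (the probit link only uses contrasts), and a logged
  $10^{-8}$-scale ridge is a numerical fallback should a connected
  component ever carry no trees.
* **SPDE (Matérn $\nu = 1$ approximation).** A Gaussian Markov random
  field whose precision is the lattice stencil
  $Q(\rho) = (aI - C)^2$ with $a = 4 + 1/\rho^2$: interior diagonal
  $4 + a^2$, cardinal neighbors $-2a$, diagonal neighbors $2$,
  second-order cardinal neighbors $1$. The field is
  $\alpha_p \sim \mathrm{N}(\mu_p \mathbf{1},\,
  \sigma_p^2\, 4\pi\rho_p^2\, Q(\rho_p)^{-1})$; the $4\pi\rho^2$ factor
  makes $\sigma^2$ comparable between the two models. The range $\rho$
  is measured in grid-cell units — the construction is resolution-free
  and the prior bounds below only make sense on the lattice scale. Only
  $\nu = 1$ is implemented; no extra boundary correction is applied
  beyond building the stencil on the finite buffered lattice, which is
  why a buffer matters for this prior.

Hyperpriors are flat within bounds: $\sigma_p$ uniform on $(0, 1000]$,
$\mu_p$ uniform on $[-10, 10]$, and $\rho_p$ uniform on
$(0.1, e^5)$ (all configurable through `hyperprior_bounds()`).

### Township data (change of support)

A tree $j$ in township $t$ carries a latent cell membership $c_{tj}$
with prior mass $\psi_{ti}$ proportional to the areal overlap of the
township with cell $i$ (weights normalized to one per township). Its
utilities are $W_{tjp} \sim \mathrm{N}(\alpha_p(s_{c_{tj}}), 1)$, so
conditioning on the current memberships gives a soft, probabilistic
assignment of township trees to grid cells. Memberships are treated as
independent across trees, which ignores the regular spacing of real
boundary-marker trees; this is a recognized simplification of the
model, not of this implementation.

## Computation

The sampler alternates:

1. **Utilities.** For each tree, the observed taxon's utility is drawn
   from a normal truncated below at the largest competing utility, then
   each competing utility truncated above at that new value — so the
   observed taxon is always the strict argmax. Truncated-normal draws
   use rejection sampling (naive below a bound of 0.25, Robert's
   translated-exponential beyond), exact far beyond $\pm 8$ where naive
   inverse-CDF draws would saturate. The R-level `rtnorm()` uses the
   complementary log-scale inverse CDF for the same reason.
2. **Memberships.** Township trees are reassigned by the Gumbel-max
   trick on log weights $\log\psi_{ti} + \log L_{tji}$, which never
   underflows and never leaves the support.
3. **Sufficient statistics.** $A_{ii}$ = trees now in cell $i$;
   $\bar w_{ip}$ = mean utility per cell and taxon (zero for empty
   cells).
4. **Cross-level hyperparameter updates.** Per taxon, the blocks
   $\log\sigma_p$ (CAR) or $\mu_p$ then $(\log\sigma_p, \log\rho_p)$
   (SPDE; order configurable) are proposed by adaptive random walks and
   accepted with the field-marginalized ratio: because the field is
   proposed from its exact Gaussian full conditional
   $\mathrm{N}((A + Q_p)^{-1} b,\ (A + Q_p)^{-1})$,
   $b = A\bar w_p + Q_p \mu_p \mathbf{1}$, the joint
   Metropolis–Hastings ratio reduces to the marginal posterior ratio of
   the block given the utilities. Uniform priors sampled on the log
   scale contribute the log-scale Jacobian. After the blocks, the field
   is redrawn once more from its full conditional — an extra Gibbs
   refresh that is free (the factorization is in hand) and cannot harm
   invariance.

Adaptation is Robbins–Monro on the log proposal scale (targets 0.44 for
scalar blocks, 0.23 for the 2-D block) with a Haario-style running
covariance for $(\log\sigma, \log\rho)$, initialized at
`init_scale^2` times the identity, and frozen at the end of burn-in so
the post-burn-in chain is a fixed Markov kernel.

Linear algebra is sparse throughout: all per-taxon precisions share one
sparsity pattern per model kind, so each proposal only rewrites the
numeric entries; the symbolic Cholesky analysis of $A + Q_p$ is
computed once and numerically refactored per draw; and
$\log|Q(\rho)| = 2\sum_{ij}\log(a - \lambda_{ij})$ uses the closed-form
eigenvalues $\lambda_{ij} = 2\cos(\pi i/(n_x+1)) +
2\cos(\pi j/(n_y+1))$ of the lattice adjacency. Retained draws are
evenly spaced over the post-burn-in iterations; the run is bit-for-bit
reproducible from the seed.

### From fields to proportions

$\theta_p(s)$ has no closed form for $P > 2$, so `mc_theta()`
integrates by simulation: `n_mc` hypothetical trees per cell (10000 by
default), tabulating which taxon wins the argmax; floating-point ties
go to the lowest taxon index (deterministic, unbiased at achievable
precision). Each retained draw uses an RNG substream derived from the
master seed and the draw index, so draws are reproducible and could be
recomputed independently; a finer per-(draw, cell) substream scheme was
considered and dropped because block-vectorized generation is an order
of magnitude faster at identical statistical content. For $P = 2$ the
closed form $\Phi((\alpha_1 - \alpha_2)/\sqrt 2)$
(`probit_two_taxon_oracle()`) serves as the analytic cross-check.

## Holdout evaluation

`make_holdout()` implements the two designs used for model comparison:
holding out all trees from a random fraction of cells (interpolation
under sparse coverage) and holding out individual trees at random
(within-cell estimation). Metrics: multi-category Brier score per
held-out tree; log predictive density of held-out count vectors (with
predicted proportions that are exactly zero against positive counts
floored at $10^{-5}$ — the printed floor constant is read as
$1/100000$, and it is configurable); tree-weighted RMSPE and MAE
against held-out empirical proportions; and coverage/length of central
predictive intervals for held-out proportions, built per cell by
simulating a multinomial count from each retained composition draw and
taking proportion-scale quantiles (interval lengths are only
interpretable on the proportion scale). Cells need at least 50 held-out
trees to enter the interval summary. Every metric is computed both at
the posterior-mean composition and per retained draw;
`compare_models()` reports the fraction of draws where one model's
metric is lower, counting exact ties one half each. Coverage is pooled
over (cell, taxon) pairs by default.

## The synthetic-data generator

`scenario()` fixes the data-generating conditions and
`make_scenario()` provides presets that mirror the regimes the model
targets: a dense 25×25 grid; the same grid with 95% or 80% of core
cells masked; township-only data; and a mixed gridded + township
domain. Defaults are the study conditions: per-cell tree counts are
zero-truncated Poisson with mean 124 (the typical survey density —
the survey reports a mean, not a distribution, so Poisson is the
natural one-parameter choice), fields are SPDE with
$\rho = 3$, $\sigma = 1$, $\mu = 0$, and townships tile the core grid
in 4×4-cell blocks whose interior boundaries are jittered by ±1 cell so
units are irregular without any polygon machinery (cells have equal
area, so overlap weights are uniform over a township's member cells).
For the CAR kind, truth fields are drawn from the proper part of the
intrinsic prior with the level pinned at zero — the level is arbitrary,
and zero keeps $\theta$ truths unaffected. The generator emulates the
statistical structure the model assumes (smooth fields, multinomial
sampling, sparse coverage, areal aggregation); it does not emulate
surveyor bias, correction factors, taxonomic ambiguity, or
time-transgressive sampling, so passing recovery tests demonstrates
internal consistency of model and sampler, not robustness to those
real-data features.

A note on scale: with the $\sigma^2\,4\pi\rho^2$ parameterization, the
marginal standard deviation of an SPDE field is approximately
$\sigma\rho^2$, so the default conditions produce strong fields in
which many cells are dominated by one taxon. The probit link then
carries limited information about field magnitude (it saturates), which
is precisely why hyperparameter mixing is slow and why production runs
of this model family use chains of order $10^5$ iterations.

## Problem sizes used in the tests

The automated checks run at deliberately modest sizes chosen to
exercise the full pipeline: exact linear-algebra oracles on lattices up
to 7×7; a Geweke-style prior-invariance check of the full transition
kernel on a 3×3 lattice with narrowed (proper) hyperprior bounds; a
parameter-recovery study on the 25×25 default scenario with three
replicate fits of 6000 iterations (2500 burn-in); a change-of-support
equivalence check (1×1-block townships against the identical gridded
trees) on an 8×8 core; and an interval-calibration study holding out
half the trees of a 25×25 CAR-generated dataset. Production analyses
should scale the chain length up by one to two orders of magnitude, as
the slow-mixing note above explains; the sampler's per-iteration cost
is linear in trees and near-linear in cells.

## Numerical choices and edge cases

* Argmax ties in the probit integration resolve to the lowest index.
* Empty taxa (total count below `min_count`, default 1) are dropped
  with a warning; fewer than two remaining taxa is an error.
* Cells with no trees contribute nothing to the likelihood
  ($A_{ii} = 0$, $\bar w_{ip} = 0$); observed-but-empty and masked
  cells are therefore equivalent to the sampler, but the generator
  keeps the distinction in its truth tables.
* Initialization: fields at 0, $\sigma = \rho = 1$, $\mu = 0$;
  utilities drawn from the field prior predictive and rank-adjusted so
  the observed taxon starts as the argmax; memberships drawn from the
  overlap prior.
* Proposals outside the prior support are auto-rejected (not errors).
* The log-density floor, hyperprior bounds, thinning count, Monte Carlo
  sample count and adaptation targets are all exposed in
  `mcmc_config()` / `hyperprior_bounds()` with the defaults above.

## Known limitations

* Only the $\nu = 1$ SPDE stencil is available.
* Single chain per run; launch several processes with different seeds
  for between-chain diagnostics.
* The common-level direction of the fields (and $\mu_p$ under SPDE) is
  weakly identified by construction; monitor $\theta$, not raw fields,
  for convergence — composition is what mixes well.
* Townships are modeled through precomputed overlap areas; no polygon
  intersection is performed.
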