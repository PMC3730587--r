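---
title: "Models and methods behind sisterdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sisterdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

sisterdiv implements a sister-pair comparative analysis of whether sexual
selection, proxied by plumage dichromatism, accelerates phenotypic
divergence and diversification in birds. This vignette explains the
models, the parameters that matter, the numerical choices, and what the
synthetic-data experiments do and do not establish.

## Phenotype scoring

### Reflectance PCA

Spectra arrive as long tables (species, sex, specimen, body region,
wavelength in nm, percent reflectance) on a grid spanning 320–700 nm.
Spectra measured on different grids are linearly interpolated onto a
common 5-nm grid; spectrophotometers differ in step size and linear
interpolation is accurate at that resolution for smooth plumage spectra.

Each wavelength column is centred and scaled to unit variance before the
principal-component decomposition. This per-wavelength standardization is
what makes the scores brightness-independent: adding a constant to a
spectrum at any fixed wavelength across all records changes nothing, and
a uniformly brighter specimen moves along, not across, the retained axes.
PCA signs are arbitrary, so they are fixed by band anchors: PC1 is
oriented so its mean loading over 400–480 nm (short-wavelength chroma) is
positive, PC2 so its mean loading over 320–380 nm (ultraviolet) is
positive. Every specimen is scored individually and scores are then
averaged per species × sex × region — averaging scores of noisy specimens
rather than scoring an averaged spectrum keeps the specimen dispersion
visible and matches how species means are usually formed from museum
series.

### Dichromatism and divergence summaries

The dichromatism score of a species is the sum over regions and the two
axes of |male mean − female mean|. We read the per-region "Euclidean
distance" of the two PC axes as the per-axis absolute difference (the 1-D
Euclidean distance), summed over axes — not the joint 2-D norm per
region; the two conventions differ by at most √2 per region and the
per-axis form keeps the score an exact sum of interpretable terms.
Regions lacking one sex are skipped and reported. The pair-level
covariate S is the arithmetic mean of the two members' scores.

Traits (beak, tarsus, wing length plus the 12 region × axis colour
scores) are standardized to z-scores across species within sex; per-pair
divergence per trait is |z₁ − z₂|, summarized as the *total* (sum over
traits) and the *maximum* (largest single trait). Traits with zero
cross-species variance are dropped with a warning; traits missing in
either member shrink the summation set and the per-pair coverage fraction
is reported rather than invalidating the pair.

Ages come from a cytochrome-*b* clock of 1.05% per lineage per Myr
applied to the total pairwise distance: age = d / (2 × 0.0105) Myr.

## Divergence-rate models

For one trait and sex, the difference X between pair members after
per-lineage separation τ = T/2 is Gaussian with mean zero and variance

* Brownian motion: V = 2βτ,
* Ornstein–Uhlenbeck (shared optimum, constraint α): V = (β/α)(1 − e^(−2ατ)).

T is the *total* separating distance between the pair (genetic distance
or age; β's units follow). The observed divergence D = |X| then has the
half-normal density f(D) = 2(2πV)^(−1/2)·e^(−D²/2V), and the data
log-likelihood is the sum over pairs.

The covariate-dependent family sets β(S) = b_β·S + c_β and, for OU,
α(S) = b_α·S + c_α. The linear-in-S form *is* the model: we do not
re-parameterize to logs, because that would change the hypothesis being
fitted. Instead, parameter vectors implying β(Sᵢ) ≤ 0 or α(Sᵢ) < 0 at any
observed Sᵢ simply return −∞, which the derivative-free optimizer treats
as infeasible. The OU variance is evaluated through the BM limit when
ατ ≤ 1e−8 to avoid cancellation; the collapse to BM as α → 0 is exact in
the limit and tested at α = 1e−10.

Fitting uses Nelder–Mead with 20 jittered restarts (tolerance 1e−10 on
the negative log-likelihood; the surface can be ridge-like in (b_α, c_α)).
The one-parameter BM-constant model instead uses its closed form
β̂ = mean(D²/T), refined and cross-checked by a bracketed 1-D search.
Model comparison uses AICc = −2logL + 2k + 2k(k+1)/(n−k−1) and Akaike
weights; "best-supported" requires weight > 0.70 and a runner-up ΔAICc
> 2. Near-ties (ΔAICc < 0.01) are ordered toward fewer parameters so
output is deterministic. The sex contrast fits one shared parameter set
to pooled male + female data against sex-specific sets, comparing AICc at
pooled n with the doubled parameter count.

## Diversification from recognized sister ages

The likelihood of a set of sister-species ages under speciation rate λ,
extinction rate μ and mean recognition lag φ is built by simulation,
since the lag-pruned age density has no convenient closed form:

1. Trees are grown by Gillespie event simulation from the two daughters
   of an initial bifurcation over a horizon T_sim (implemented in C++;
   event simulation is the one hot loop in the package).
2. Replicates with fewer than two extant tips are discarded (a sister
   pair's ancestor is by construction a bifurcation that survived).
3. The extant-only tree is reconstructed; each internal node draws one
   lag from Exponential(mean φ) and nodes younger than their lag collapse,
   tipward to rootward, until stable — a node may only collapse once both
   daughters are single recognized species, which makes a single
   bottom-up pass the fixed point of the iteration.
4. Ages of surviving cherries (nodes whose daughters are both recognized
   species) are pooled into a histogram of 50 bins over [0, T_sim] with
   add-one smoothing, so every bin probability is at least
   ε = 1/(n_ages + n_bins) and any observation set has finite
   log-likelihood; ages beyond the support get log ε.

Defaults: T_sim = 1.5 × the oldest observed age (mass beyond the data
carries no likelihood but truncating too close biases the boundary
bins); 2000 trees per parameter evaluation. Under the linear model
λ(S) = b_λ·S + c_λ and μ(S) = b_μ·S + c_μ are evaluated on a 15-point S
grid spanning the observed range, one simulated distribution per grid
point, and each pair's log-probability is interpolated linearly in S; φ
is shared and does not vary with S. Every evaluation reuses identical
seed substreams (common random numbers), so the simulated likelihood is
a deterministic, replayable function of the parameters and smooth enough
for a simplex to climb. The C++ simulator caps each tree at 100,000
lineage records; parameter points that overflow (λ·T_sim too large) are
treated as infeasible rather than silently truncated. The constant model
has k = 3 (λ, μ, φ) and the linear model k = 5; they are compared by
AIC = 2k − 2logL, and the net-diversification slope is b_λ − b_μ.

## Regression layer

The mixed model of log-divergence on log-dichromatism, sex, their
interaction, age, sympatry and body mass — with random intercepts for
pair, each member species, and genus nested in family — is a standard
REML fit and is delegated to lme4, with Satterthwaite degrees of freedom
from lmerTest. Responses and the dichromatism predictor are
log-transformed with offset δ = half the smallest positive observed
value (recorded in the table's attributes), so exact zeros remain finite
without distorting ranks.

PGLS is implemented in-package. One representative tip per pair (its
`species_1`; the pair-level response is symmetric, so the choice is
arbitrary and fixed for determinism) gives a Brownian correlation matrix
whose off-diagonals are multiplied by Pagel's λ. The GLS profile
log-likelihood (σ² concentrated out) is maximized over λ ∈ [0, 1] by a
coarse grid (step 0.05) followed by golden-section refinement to 1e−4 —
the profile can be multimodal, and a pure line search can be trapped on
the wrong shoulder. λ = 0 reproduces ordinary least squares exactly,
which is a standing test. Coefficient standard errors use the residual
variance with n − p degrees of freedom at the profiled λ.

## Synthetic data: what it emulates, and what not

Generators produce complete studies from a `study_config()` with a
mandatory seed; every generator is a pure function of (config, seed).
Defaults mirror the empirical design the package targets: 84 pairs of
which 39 are true sisters, dichromatism covariate S ~ U(0, 2), pair
separations T ~ U(0.5, 5), a male divergence rate rising in S
(b_β = 0.5, c_β = 0.1) with a flat female rate, and a birth–death truth
of λ = 0.3/lineage/Myr, μ = 0, φ = 0.3 Myr with a 10-Myr generation
horizon — rates at the scale typical of recent passerine radiations.
Reflectance templates are a linear ramp plus two Gaussian bumps
(smooth, positive, band-controllable); males receive additional bumps in
the 400–480 and 320–380 nm bands whose per-species magnitude sets a known
dichromatism ordering; specimen noise is i.i.d. Gaussian, clipped at zero
reflectance with a warning.

What passing on such data shows: the estimators recover the parameters
of their own generating models, the model-selection machinery identifies
the generating structure, and the full pipeline is internally
consistent. What it does not show: robustness to real spectra (specimen
noise is neither Gaussian nor independent across wavelengths in museum
skins), to receptor-level colour perception (no visual-system model is
used, deliberately), to phylogenetic non-independence beyond the
modelled structures, or to misdated splits (the clock is treated as
exact).

## Numerical choices and known limitations

* Recovery experiments in the test suite run at sizes chosen to separate
  estimator error from sampling noise: n = 500 pairs for rate models,
  300 ages and 2000 trees per evaluation for birth–death fits, 52 tips
  and 20 replicates for Pagel's λ. Yule (pure-birth) trees are used for
  the λ simulations; coalescent topologies concentrate shared history at
  the root and leave λ weakly identified at these sizes.
* The half-normal MLE of the dichromatism-linear rate is unbiased but
  its intercept has sampling SD ≈ 0.028 at n = 500 under the default
  truth, so single-study intercept estimates should be read with that
  spread in mind; detection (via AICc) is far better powered than
  estimation.
* The simulated birth–death likelihood has Monte-Carlo granularity of
  order 1/√(n_trees); AIC differences smaller than ~1 should not be
  over-read at the 2000-tree default.
* Non-nested pair selection is greedy youngest-first: among pairs sharing
  a species the youngest is kept, deterministically (ties break on pair
  id).
* Multi-trait joint covariances, measurement-error models, non-linear
  rate functions, time-varying diversification rates and full-tree
  likelihoods are out of scope.
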