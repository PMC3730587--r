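# sisterdiv

Comparative-method toolkit for asking whether sexual selection — indexed by
plumage dichromatism — accelerates phenotypic divergence and diversification
across recently split bird lineage pairs.

The package is aimed at evolutionary biologists working with sister-species
(and "clade sister") comparisons: pairs of closely related lineages whose
phenotypic differences and divergence times carry information about the
tempo of recent evolution, without the confounds that accumulate across
deep nodes of a phylogeny.

## What it computes

**Phenotype scoring.** Spectrophotometric reflectance curves (320–700 nm,
six body regions, multiple specimens per species × sex) are collapsed by
PCA on per-wavelength standardized spectra into two brightness-independent
colour axes: short-wavelength chroma (PC1, anchored to 400–480 nm) and
ultraviolet reflectance (PC2, anchored to 320–380 nm). A species'
*dichromatism score* is the summed absolute male–female difference of the
two axes across regions; zero means monochromatism. Morphometric and
plumage traits are standardized across species (z-scores) and per-pair
divergence is summarized as the *total* (sum of |Δz| over traits) and
*maximum* (largest single-trait |Δz|). Divergence times come from a
cytochrome-*b* molecular clock of 1.05% per lineage per Myr:
age = d / (2 × 0.0105).

**Divergence-rate models (maximum likelihood).** For a pair separated by
distance T (per-lineage separation τ = T/2), the trait difference is
Gaussian with variance

- Brownian motion: V = 2βτ
- Ornstein–Uhlenbeck: V = (β/α)(1 − e^(−2ατ)), collapsing to BM as α → 0

and the observed 1-D divergence D = |Δz| follows the half-normal density
f(D) = 2(2πV)^(−1/2) exp(−D²/2V). The rate β (and OU constraint α) can be
constant or linear in the pair-mean dichromatism S:
β(S) = b_β S + c_β, α(S) = b_α S + c_α. Models are fitted by restarted
Nelder–Mead simplex and compared by AICc and Akaike weights; a
shared-versus-sex-specific rate contrast tests whether male and female
rates differ.

**Diversification from sister ages.** The likelihood of observed
recognized sister-species ages is built by simulation: birth–death trees
(speciation λ, extinction μ) are grown from an initial bifurcation,
pruned to their extant parts, and each surviving node draws an
exponential *lag to species recognition* with mean φ — splits younger
than their lag are not yet counted as species. The simulated
recognized-age histogram (Laplace-smoothed) gives each observed age its
probability. Constant rates are compared against rates linear in
dichromatism (AIC); the net-diversification slope is b_λ − b_μ.

**Regression layer.** Linear mixed models (lme4/lmerTest; random
intercepts for pair, member species, and genus nested in family) and
phylogenetic generalized least squares with maximum-likelihood Pagel's λ
profiled over [0, 1].

**Synthetic studies.** Every input — reflectance tables, morphometrics,
pair covariates, divergence observations, sister ages, a tree — can be
generated with known truth (`gen_study()`), so the full analysis chain is
testable end to end.

## Worked example

Fit the four divergence-rate models to the male observations of a
synthetic 84-pair study generated with a rate that rises with
dichromatism (b_β = 0.5, c_β = 0.1):

```r
library(sisterdiv)
cfg <- study_config(n_pairs = 84, seed = 2026)
obs <- subset(gen_pair_divergences(cfg)$observations, sex == "male")
fits <- list(
  BM_constant = fit_divergence_model(obs, "BM", "constant"),
  BM_linear   = fit_divergence_model(obs, "BM", "linear_in_S"),
  OU_constant = fit_divergence_model(obs, "OU", "constant"),
  OU_linear   = fit_divergence_model(obs, "OU", "linear_in_S"))
information_criteria(fits)
```

```
        model family   covariate k  logL AICc delta_AICc   weight best_supported
2   BM_linear     BM linear_in_S 2 -77.8  160       0.00 8.96e-01           TRUE
4   OU_linear     OU linear_in_S 4 -77.8  164       4.32 1.03e-01          FALSE
1 BM_constant     BM    constant 1 -88.9  180      20.12 3.83e-05          FALSE
3 OU_constant     OU    constant 2 -88.9  182      22.22 1.34e-05          FALSE
```

The generating structure (BM with a dichromatism-linear rate) is
best-supported: weight 0.90 and a ΔAICc gap of 4.3 to the runner-up. The
fitted slope itself is noisy at 84 pairs (`fits$BM_linear` prints
b_β = 0.83 against a truth of 0.5); rate *detection* is much easier than
rate *estimation* at study scale, which is why the package's recovery
experiments use larger simulated samples.

`run_pipeline()` chains the stages (phenotype scoring → mixed
models/PGLS → rate-model selection → birth–death fits) over a directory
of input files and writes CSV/JSON results plus a seeded run log.

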