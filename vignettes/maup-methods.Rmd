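---
title: "Methods: aggregation scale and Bayesian disease mapping with maupbym"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aggregation scale and Bayesian disease mapping with maupbym}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Disease mapping aggregates events to administrative areas before
modelling.  The modifiable areal unit problem (MAUP) is the fact that the
resulting inference — autocorrelation diagnostics, covariate effects,
smoothed risk surfaces — depends on which zoning is chosen.  `maupbym`
provides a complete, testable pipeline for studying the *scaling* facet of
the MAUP on sparse count data: the same simulated events are carried
across a five-level nested geography (a mesh-block through SA4 analogue of
the Australian Statistical Geography Standard) and the same Bayesian
spatial model is fitted at every level, with and without an area-level
deprivation covariate.

# Model

Counts are modelled per area $i$ as

$$Y_i \sim \mathrm{Poisson}(E_i e^{\mu_i}), \qquad
  \mu_i = \alpha + \mathbf{x}_i^\top\boldsymbol\beta + u_i + v_i,$$

where $E_i$ is the expected count from indirect age standardisation
($E_i = \sum_k y_k\,\mathrm{pop}_{ik}/\mathrm{pop}_k$ over $K$ age strata),
$\mathbf{x}_i$ holds dummy indicators for deprivation quintiles 2–5
(quintile 1, most disadvantaged, is the reference), $u_i$ is an intrinsic
conditional-autoregressive (CAR) structured effect,

$$u_i \mid u_{j\ne i} \sim N\!\Big(\tfrac{\sum_j w_{ij}u_j}{\sum_j w_{ij}},\,
  \tfrac{\sigma_u^2}{\sum_j w_{ij}}\Big),$$

with binary contiguity weights $w_{ij}$, and $v_i \sim N(0, \sigma_v^2)$ is
unstructured.  Priors are $\alpha, \beta_j \sim N(0, 10^6)$ and
$\sigma_u^2, \sigma_v^2 \sim \mathrm{InvGamma}(a{=}1,\ b{=}0.01)$ — the
vague defaults customary in this literature.

# The sampler

The model is fitted by a Metropolis-within-Gibbs sampler written for this
package (`src/bym_sampler.cpp`):

* random-walk Metropolis for $\alpha$ and each $\beta_j$ (an $O(1)$/
  $O(|\text{quintile}|)$ update using a cached vector of Poisson means);
* per-area random-walk Metropolis for $u_i$, with the CAR full
  conditional as prior times area $i$'s Poisson likelihood, and for $v_i$;
* conjugate Gibbs draws for $\sigma_u^2$ and $\sigma_v^2$.  The structured
  update uses shape $a + \tfrac12\big(\sum_{\text{multi-area comps}}
  (\text{size}-1) + n_{\text{isolated}}\big)$ — the rank of the intrinsic
  CAR precision plus one per isolated area — and scale
  $b + \tfrac12\sum_{i<j} w_{ij}(u_i-u_j)^2 + \tfrac12\sum_{\text{iso}}u_i^2$.
  On a fully connected graph this is the familiar $a + (n-c)/2$ with $c$
  components.

**Identifiability.** The intrinsic CAR prior is improper: each connected
component's level is confounded with $\alpha$.  We mean-centre $u$ within
every multi-area component after each iteration, the standard sum-to-zero
device.  Isolated areas (which arise after zero-population exclusions)
instead keep a *proper* $N(0, \sigma_u^2)$ prior and are not centred —
centring a singleton would pin it at zero and remove it from the model.

**Adaptation.** Every scalar update has its own proposal scale, multiplied
by 1.2 (or divided) whenever its acceptance rate over the last 50
burn-in iterations leaves the 40–50% band, clamped to
$[10^{-6}, 5]$, and frozen at the end of burn-in so the post-burn-in chain
is a fixed Markov kernel.

**Chain policy.** One chain per fit, as is common with long chains.  The
desk-scale default is 60,000 iterations with 10,000 burn-in and thinning 5
(10,000 retained draws); `bym_config(full_scale = TRUE)` selects the
production schedule of 1.5M iterations, 500k burn-in, thinning 100.  All
randomness flows through R's RNG, so a seed makes every fit and every
pipeline run byte-reproducible.

**Fractional counts.** Disaggregated counts are fractional (population
shares of integer counts).  The default policy rounds to the nearest
integer before the Poisson fit and records the total discrepancy;
`count_policy = "fractional"` instead evaluates the gamma-function form of
the likelihood on the fractional counts.  Rounding is the default because
the Poisson likelihood is only a genuine probability model on integers.

# Posterior summaries

Parameters are reported as posterior medians with equal-tailed 95%
credible intervals (empirical 2.5/50/97.5 percentiles).  The *fraction of
spatial variation* — the share of random-effect variability carried by the
structured component — is not uniquely defined in the literature; we
compute, per retained draw, the empirical variance across areas of $u$
over the sum of empirical variances of $u$ and $v$, and report the
posterior median of that ratio.  Exact numerical agreement with other
definitions (e.g. based on marginal variances) is not claimed.  Fitted
SIRs are per-area posterior medians of $e^{\mu_i}$.

# Diagnostics

**Moran's I** is computed from the contiguity structure with
row-standardised weights by default (binary selectable), and inference is
by a one-sided permutation test (999 relabellings by default), whose
smallest attainable p-value is $1/(B+1)$ — hence p-values like 0.001.  An
analytical normal approximation is deliberately not the default; the
permutation test makes no distributional assumption and is exact under
exchangeability.  Model residuals fed to Moran's I are Pearson residuals
$(y_i - E_i\widehat{\mathrm{SIR}}_i)/\sqrt{E_i\widehat{\mathrm{SIR}}_i}$
by default; raw response residuals are available.

**Geweke z-scores** compare the first 10% against the last 50% of the
retained draws, with segment variances estimated by the spectral density
at zero of an AIC-selected Yule–Walker autoregression, so within-segment
autocorrelation does not deflate the standard error.  $|z|>3$ is flagged
(not fatal) in pipeline logs.

# Geography and transfers

* **Contiguity**: queen by default (shared boundary point), matching common
  practice for lattice-like statistical geographies; rook available.
  Polygon-derived contiguity compares (snapped) boundary vertices, exact
  for lattice-aligned geometry such as the synthetic grids and typical
  administrative GeoJSON where shared borders repeat coordinates.
* **Counts** move by correspondence matrices whose rows sum to one:
  aggregation is exact summation; disaggregation uses population shares
  and yields fractional counts by default, with an opt-in multinomial
  integerisation.  Totals are conserved to $10^{-9}$ (exactly in
  integerised mode).
* **Index scores** are not mass: disaggregation copies the ancestor's
  score; aggregation takes the population-weighted mean.
* **Quintiles** are population-weighted (cut at cumulative-population
  fractions 0.2–0.8), not area-count quintiles, following statistical-
  agency practice for deprivation indices.  With fewer than five areas
  (the 4-area coarsest analogue) some quintiles are necessarily empty;
  their coefficients are then prior-dominated with very wide intervals —
  itself an instance of what coarse aggregation does to covariate
  inference.
* **Zero-population areas** are dropped before analysis at every level.
* Expected counts are computed once at the finest level and aggregated;
  because $E_i$ is linear in the stratum populations this equals direct
  computation at any level under exact nesting.

# The synthetic scenario

The generator emulates the study conditions end to end with no downloads:

* **Nesting** 4096 → 1024 → 64 → 16 → 4 (square-grid coarsenings),
  a desk-scale analogue of the 67,047 → 11,507 → 507 → 82 → 19 area counts
  of the Queensland five-level geography.
* **Populations**: log-normal totals with median ≈ 82 and sdlog 0.5
  (median matching the published mesh-block median; the sdlog gives
  mean/median ≈ 1.13 and a long right tail, similar to published mesh
  summaries), split over 18 five-year age strata around a fixed stylised
  age pyramid; 2% of cells get population zero to exercise exclusions.
* **Covariate**: at the SA2 analogue, a broad diagonal gradient plus a
  proper-CAR field, scaled to an index around 1000 — smooth, strongly
  autocorrelated, like a relative-disadvantage index.
* **Counts**: generated at the SA2 analogue — the level where such data
  realistically exist — from the BYM equations with
  $\alpha=0$, $\boldsymbol\beta = (-0.13, -0.23, -0.29, -0.46)$ (the
  magnitude of published SA2-level deprivation gradients),
  $\sigma_u^2 = 0.05$, $\sigma_v^2 = 0.005$, and an expected state total
  of 1229 cases so the finest level averages ≈ 0.3 cases per area, the
  sparse regime of interest.  The structured field is a *proper* CAR draw
  ($\rho = 0.95$, rescaled to the target empirical variance) because the
  intrinsic prior cannot be sampled; fitting still uses the intrinsic
  prior — a deliberate, realistic mismatch between data-generating process
  and model.
* The per-area counts are allocated to age strata in proportion to
  expected stratum risk, and the strata reference is rebuilt from the
  *simulated* counts exactly as an analyst would, which forces
  $\sum_i E_i = \sum_i y_i$ and a population-weighted mean SIR of one at
  every level.

What the generator does **not** emulate: real boundary irregularity
(areas here are squares, so contiguity degree is nearly constant),
coastline/remoteness population gradients, spatially varying age
structure, and registry artefacts.  Passing tests therefore demonstrate
correctness of the machinery and qualitative behaviour under the stated
statistical structure, not agreement with any particular real dataset.

# Design choices on genuinely open points

* **Which residuals feed Moran's I** after fitting is not standardised
  across the literature; we default to Pearson residuals and expose the
  choice.
* **CI-width comparison across levels**: the cross-level uncertainty
  claim is assessed by comparing the SA1-analogue against the SA4-analogue
  endpoint widths per replicate seed (fine vs coarse), the robust form of
  the "wider at coarser aggregation" statement.
* **Problem sizes**: recovery experiments use 200-area grids with 50
  replicates at the desk-scale chain; cross-level replicate runs skip
  fits at the 4096-cell finest level (its Moran diagnostics are still
  computed) — the finest-level fits are the heaviest and noisiest, and the
  cross-level contrasts are defined on the SA1–SA4 analogues.  The full
  five-level fit set (10 models) remains the pipeline default.
* **Empty-quintile coefficients** at very coarse levels are reported as
  sampled (prior-dominated) rather than dropped, keeping the model matrix
  schema identical across levels.

# Known limitations

* The intrinsic-CAR variance $\sigma_u^2$ is a *conditional* variance; it
  is not comparable in magnitude to the marginal variance of $u$, and the
  fraction-of-spatial-variation uses empirical variances rather than
  either parameterisation.
* Single-chain inference: convergence is monitored by Geweke scores only;
  no cross-chain statistics are computed.
* The permutation Moran test at a 4-area all-adjacent level is degenerate
  (the row-standardised statistic is constant at $-1/3$), so its p-value
  is 1 by construction — a faithful reflection of how little spatial
  information such a level carries.
* Queen contiguity from polygons relies on shared vertices; boundaries
  that touch without sharing a vertex (impossible on the synthetic grids)
  would be missed.

# A worked example

```{r example}
library(maupbym)

scen <- scenario_config(seed = 1)      # default five-level scenario
model <- bym_config(seed = 2)          # desk-scale chain: 60k/10k/5
res <- run_experiment(scen, model, out_dir = "maup_out")
res$table2                             # Moran's I per level and target
res$posterior_cov                      # covariate-model posterior summaries
```

The same run is scripted in `scripts/acceptance.R`, which recomputes the
package's headline quantities from scratch and writes them as JSON.
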