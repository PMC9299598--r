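---
title: "Recrediting forest carbon offsets against species-specific common practice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recrediting forest carbon offsets against species-specific common practice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recredit)
```

## The problem

Improved forest management (IFM) offset projects earn *upfront credits* for
the difference between their measured initial carbon stocks and the 100-year
average of carbon stocks in a modeled baseline harvest scenario. Protocol
rules floor that baseline average at *common practice* (CP): the average
standing-live aboveground carbon density (tCO2e/acre) of the project's
*assessment area* — a group of forest types pooled across an entire
*supersection* (a large geographic region built from smaller, ecologically
more homogeneous *ecosections*). In practice nearly all projects report
baselines sitting exactly at this floor, so the CP number itself largely
determines issuance.

Pooling ecologically distinct forests into one average creates a statistical
arbitrage: a developer holding land whose forest type (say, carbon-dense
tanoak) naturally exceeds the pooled average (tanoak averaged with arid
ponderosa pine) is immediately eligible for credits without changing
management — adverse selection against an unrepresentative regional mean,
a textbook instance of the ecological fallacy / modifiable areal unit
problem. `recredit` quantifies the resulting crediting error by re-estimating
CP at species/forest-type resolution and recomputing credits.

## The procedure

1. **Issuance replication.** Upfront credits are reconstructed from the
   digitized project components:
   `credits = [(IFM1+IFM3 + WP_proj) − (B̄·A + WP_base) + S]·(1 − d)`,
   floored at 0, where `B̄` is the 100-year baseline average onsite density,
   `A` the acreage, `WP` the wood-product pools for the project and baseline
   scenarios, `S` secondary effects (≤ 0), and `d` the confidence deduction.
   The protocol's issuance equation is not reprinted in public summaries at
   component level, so this reconstruction — in particular the multiplicative
   placement of the deduction — is isolated in `compute_upfront_credits()`
   for auditability. On synthetic records the replication is exact (R² = 1);
   `replicate_issuance()` reports the comparison.

2. **Design-based common practice.** Per stratum, carbon and acreage are
   summed separately over inventory conditions (each scaled by its expansion
   factor) before taking the ratio:
   `CP = Σ cᵢaᵢ / Σ aᵢ`. The variance is the delta-method ratio-estimator
   variance with conditions as sampling units and expansion acreage as size
   weights, `V = n Σ(yᵢ − R xᵢ)² / ((n−1)(Σxᵢ)²)` — the standard design-based
   inventory formula. Single-condition strata get variance 0 (no
   within-stratum variance is estimable) with a logged note. The
   regulator-style stratification pools forest types by assessment area
   (`carb_common_practice()`); the alternative stratifies by forest-type code
   within the supersection (`species_specific_common_practice()`).

3. **Forest-type classification.** Projects report species composition
   (fractional basal area, species > 5%), not forest-type codes. A
   radius-neighbors classifier per supersection maps compositions to a
   probability distribution over forest types: probability of type *t* is the
   share of training conditions labeled *t* among all conditions within the
   Euclidean radius of the query. The radius is chosen by grid search
   (21 values geometrically spaced in [0.05, 1.5]) with stratified 5-fold
   cross-validation maximizing the class-support-weighted F1, averaging
   per-fold scores; ties break toward the smallest radius (locality). A query
   with no neighbors inside the radius falls back to its single nearest
   neighbor with probability 1 — every project must receive a classification —
   and the fallback is logged. Euclidean distance on composition vectors is
   the conventional metric for this classifier family; compositions are
   bounded in [0, 1] so no rescaling is needed. When only project-wide
   species data exist, the same composition is applied uniformly to every
   assessment area of the project.

4. **Rescaled common practice and recrediting.** Rather than replacing the
   reported CP outright, each project's reported value is scaled by the
   assessment-area-acreage-weighted ratio of the alternative (species-specific)
   CP to our own recomputation of the assessment-area CP, so the change
   reflects only the change in aggregation, not reproduction error. The
   alternative CP of a project area is the classifier-probability-weighted
   mean of the per-type estimates (a configuration switch `alt_method =
   "argmax"` pools on the most probable type instead; the posterior-weighted
   default uses the full classification). New baselines assume projects
   re-optimize against the new floor: a baseline that sat at its CP snaps to
   the scaled value, while the minority that reported a margin above CP keep
   their absolute margin above the new floor (`baseline_mode =
   "preserve-margin"`; `"snap-to-cp"` is available) — conservative about
   developer behavior. A project whose scaled CP reaches its initial onsite
   density earns nothing (100% over-credited); credits never go negative, so
   per-project over-crediting is capped at 100% of issuance.

5. **Uncertainty propagation.** Forest-type mean densities are perturbed with
   Gaussian noise (sd = √variance of the ratio estimator), 1000 draws by
   default, reporting the 5th/50th/95th percentiles (the per-project table
   adds quartiles). Each forest type owns a keyed random-number substream, so
   a type's draw in iteration *j* is reused consistently in both the
   alternative CP and the rebuilt assessment-area reference (their
   correlation comes from sharing one inventory; perturbing them
   independently would inflate the variance — a `perturb_reference` switch
   exposes the fixed-reference variant). Draws are not truncated at zero,
   keeping the Gaussian assumption; a negative CP is floored at zero only
   when credits are computed, and the event is counted in the run log.
   Program-level percentiles are computed on per-draw program totals, never
   by summing per-project percentiles.

## The synthetic-data generator

Real inventories and project filings cannot be redistributed here, so a
generator emulates their statistical structure with known ground truth:

* **Landscape.** Supersections contain ecosections with area weights and
  additive carbon-density offsets (heterogeneous wetness), and forest types
  with Normal(mean, sd) carbon censored at zero and Dirichlet species
  mixtures around a per-type centroid. Assessment areas partition the types.
  `example_landscape()` mirrors published regional contrasts: a mixed-conifer
  assessment area pooling Douglas-fir (122.5 tCO2e/acre) and tanoak (192.4)
  with ponderosa pine (60.4) across three unequally wet ecosections, and a
  coastal supersection pooling Sitka spruce (121.1) and western hemlock
  (143.0) with cottonwood (41.4) and paper birch (38.3).
* **Ground truth.** Because carbon is censored at zero, the generator's true
  type-level CP uses the closed-form censored-Normal mean
  `μΦ(μ/σ) + σφ(μ/σ)`, area-weighted over ecosections; assessment-area truth
  pools member types equally (types are sampled uniformly and expansion
  acreage — lognormal, median ≈ 5000 acres — is independent of strata).
  Recovery of these values within 3 SE is a standing test.
* **Projects.** Each candidate enrolls one condition with probability
  proportional to `acres · exp(γ·z)`, `z` the standardized carbon density:
  γ = 0 is enrollment uniform over land area; γ large enrolls only
  carbon-dense parcels. Defaults follow observed portfolio behavior: 89% of
  baselines sit exactly at reported CP, the rest a half-Normal (sd 20
  tCO2e/acre) margin above it — chosen so the portfolio-mean baseline-to-CP
  gap is about 2 tCO2e/acre with median 0; acreage uniform on
  1,000–30,000 acres; confidence deduction uniform on [0, 0.05]; secondary
  effects uniform on [−20,000, 0] tCO2e; wood-product pools zero (the
  crediting formula's wood-product terms are exercised with hand-built
  records). Species compositions are thresholded at >5% fractional basal
  area and renormalized, as digitized filings are. Only candidates whose
  initial density exceeds their reported CP are emitted, matching the
  analysis scope of the credited population. The generator emits
  single-assessment-area projects; multi-area records are supported
  throughout the downstream analysis.

What the generator does *not* emulate: spatial autocorrelation and climate
gradients within ecosections, successional change in species composition,
site-class and inventory-period stratification (aggregated over, as the
published CP values effectively are), multi-supersection projects, and the
messiness of transcribed filings (typos, unit mix-ups, species-name
synonymy). Passing tests therefore demonstrate the correctness of the
estimators, classifier, crediting algebra, and uncertainty propagation under
the stated statistical model — not the empirical magnitude of over-crediting
in any real program.

## Properties the test suite enforces

* The ratio-of-sums estimator equals a brute-force accumulation to 1e-9,
  is invariant to rescaling all acreages, shifts by exactly *c* when all
  densities shift by *c*, and the supersection estimate equals the
  acreage-weighted combination of its assessment-area estimates.
* With γ = 0 on a landscape whose assessment areas pool types of *equal*
  expected carbon, program-wide crediting error has mean zero (within 3 SE
  over replicates). The neutral landscape matters: the protocol's own
  eligibility rule (initial stocks above CP) already tilts enrollment toward
  carbon-dense types whenever pooled types differ in mean carbon — which is
  precisely the adverse-selection mechanism under study, present even before
  any deliberate selection. Program-wide error in tCO2e is strictly positive
  and monotone at γ ∈ {1, 5} on a heterogeneous landscape. (Error as a
  *percentage* of issued credits is deliberately not the monotonicity
  metric: denser enrolled parcels also earn proportionally more credits,
  so the share can fall while the tonnage grows.)
* Classifier output always sums to 1, is permutation-invariant, reaches
  weighted F1 = 1 under cross-validation on separable landscapes, and
  degrades monotonically as Dirichlet concentration shrinks.
* Monte Carlo percentiles are ordered; interval widths are nondecreasing in
  every forest-type variance; program medians come from per-draw totals
  (asserted on a case where the total of medians differs); a linear
  project's tails match closed-form Gaussian quantiles within the sampling
  error of an empirical quantile (≈ 6.7% of σ at 1000 draws for the
  5th/95th percentile — wider than a casual reading might assume).

## Numerical choices and degenerate inputs

Ties in cross-validated F1 and in nearest-neighbor fallback resolve
deterministically (smallest radius; first index). Folds are stratified by
label under a caller-supplied seed. Empirical percentiles use the default
interpolating quantile (type 7). Strata with a single condition, empty
expected strata, classifier fallbacks, dropped unseen species and
negative-CP floors are all logged (`recredit_log` messages, collected into
`run_log.txt` by `run_pipeline()`). Zero recomputed assessment-area CP makes
the scaling ratio undefined and is an error, not a silent floor. A
supersection with a single forest type yields a degenerate classifier that
returns that type with probability 1 and score 1. Seeds everywhere are plain
integers; identical configuration and seeds reproduce every output file
byte-for-byte.

## Problem sizes

The bundled analyses use two supersections with 150–500 conditions each,
portfolios of 30–200 projects, and 250–1000 Monte Carlo draws; the full demo
pipeline (400 conditions per supersection, 80 projects, 1000 draws) completes
in a few seconds on one CPU. These sizes keep every distributional check well
inside its Monte Carlo tolerance while remaining conveniently fast.

## Known limitations

The crediting equation is a reconstruction from documented components; the
exact placement of the confidence deduction and the entry of wood products
into the 100-year average are not publicly specified at component level.
Site class and inventory period are not modeled as strata. The classifier's
metric, radius grid and zero-neighbor fallback are package choices (the
classifier family is standard; its hyperparameters were not published). The
buffer-pool figure is a ratio report, not an actuarial model. None of the
synthetic results estimate the over-crediting of any real portfolio.
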