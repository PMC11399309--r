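---
title: "Methods: community trait means, bioclimate and trait surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community trait means, bioclimate and trait surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitclim)
```

This vignette documents the statistical model behind each stage of the
pipeline, the design decisions taken where several defensible choices
existed, what the synthetic-data generator does and does not emulate,
and the numerical conventions that the tests pin down.

## Community-weighted means

A vegetation plot is a list of taxa with relative covers summing to
one. Taxa are assigned to the three plant groups (non-woody, woody
deciduous, woody evergreen) via a growth-form table that maps each form
to a probability triple; minority growth forms (ferns, palms, bamboos,
cacti, succulents and similar) receive zero probability everywhere and
are thereby excluded from all group computations, including the group
coverage denominator. Group coverage is relative abundance
`RA(g) = Σ RC(taxon) P_g(taxon)` renormalized over groups.

For a trait `t` and target group `g`, the CWM weight of a taxon is
`RC · P_g`, renormalized **over the taxa that have the trait measured**
— missingness in the trait table must not drag the mean toward zero.
Averaging is done on native-unit trait values and the natural log is
taken afterwards. The alternative convention (averaging logs, i.e. a
weighted geometric mean) is available as `log_first = TRUE`: species
trait distributions are roughly log-normal and either convention is
found in the literature, so the package exposes both and defaults to
the arithmetic-native one, consistent with plot databases that publish
native-unit CWMs. Log-transforming traits that can be non-positive
(e.g. a nitrogen isotope ratio) is refused unless a per-trait additive
`offset` is configured, because silently shifting data is worse than
an explicit error.

Unit conversions follow the standard definitions `LMA = 1/SLA`
(kg m^-2 from m^2 kg^-1) and area-based nutrient content
`X_area = X_mass / SLA` (g m^-2 from mg g^-1; the mg/kg factors cancel
exactly, which the tests assert as reciprocal consistency).

## Bioclimatic variables

Three site-level variables summarize the climatic controls on
vegetation:

* moisture index `MI = Σ pr_k / Σ PET_k` over the 12 months, used as
  `ln MI` to spread the dry end of the gradient;
* `MTCO`, the minimum of the 12 monthly mean temperatures (°C);
* `MGST = GDD0 / NGD0`, the mean temperature over days above 0 °C.

PET may be supplied directly (e.g. from a full soil-moisture and
radiation model). When it is not, a Priestley–Taylor form is used:
`PET = α s/(s+γ) · Rn/λ` with α = 1.26, `s` the Tetens slope of the
saturation vapour-pressure curve at the monthly temperature, γ = 0.0665
kPa °C^-1, λ = 2.45 MJ kg^-1 and net radiation approximated by absorbed
shortwave `Rn = (1 − 0.23) srad` with longwave exchange neglected.
That makes PET exactly linear in radiation at fixed temperature — a
deliberate, testable simplification, not a claim about radiation
physics; users with better PET inject it via the `pet` argument.

Where only monthly temperatures exist, daily series for the GDD sums
are linearly interpolated between month midpoints with periodic
wrap-around (December connects to January). Pixels with no above-zero
day have `MGST = NA`, never zero, and that missingness propagates into
every downstream model and map. The gridded computation applies the
scalar code path to every cell, so a one-pixel raster agrees with the
scalar functions bit for bit.

## Ordination

PCA is the eigen-decomposition of the covariance of the standardized
log-CWM matrix (equivalently the trait correlation matrix), with the
`n − 1` variance denominator throughout. RDA regresses the trait matrix
on the standardized bioclim triple by least squares and
eigen-decomposes the fitted values (constrained axes) and residuals
(unconstrained axes); the constrained fraction is `‖Ŷ‖²/‖Y‖²`. Because
reported axis shares can be read against total or constrained variance,
both normalizations are returned (`axis_fraction_total`,
`axis_fraction_constrained`).

Determinism across platforms is enforced by a sign convention (the
largest-magnitude loading on each axis is positive) applied before any
rotation. `rotate_to_reference()` aligns signs — and axis order within
blocks of numerically equal eigenvalues only — to a reference loading
matrix, leaving eigenvalues and the reconstruction `scores · loadingsᵀ`
unchanged; this is how panels for different plant groups are given a
common orientation. Rows with missing traits are dropped per analysis,
with the count reported: a plot incomplete for one group's trait set
still contributes to the others.

## Trait–climate surfaces

GAMs are Gaussian additive models with thin-plate penalized splines,
basis dimension `k = 10` per term by default (configurable and recorded
in the fit), and smoothness selected by REML. Cover-fraction
interactions are varying-coefficient terms — a smooth of the bioclim
variable multiplied by the cover fraction, plus a smooth main effect of
the fraction — and because the three group fractions sum to one, only
two of them should enter a model. A `sp` argument allows re-fitting at
fixed smoothing parameters; note that REML-selected smoothness is
sample-size dependent, so an exactly replicated data set reproduces the
original fit only when the penalty is scaled with the data (the test
suite demonstrates this with doubled data and doubled `sp`).

Per-predictor relative importance is the Shapley (LMG) decomposition:
the increment in deviance explained when a predictor enters, averaged
over all orderings of the predictors, requiring fits of all `2^p − 1`
predictor subsets. Shapley increments are exactly additive, so the
share of the full-model deviance explained and the share of the summed
contributions coincide; both are still reported (`share`, `share_raw`)
because the cheaper leave-one-out variant (`method = "loo"`), offered
for comparison, is not additive. In the linear special case
(`smooth = FALSE`) the decomposition reduces to the classical LMG
partition of R².

Concurvity — the smooth-model analogue of collinearity — is reported as
the "observed" measure: the proportion of each term's fitted-function
variance reproducible from the span of the other terms' bases.

Response surfaces are evaluated on a regular grid over the observed
range of (ln MI, MTCO, MGST) at increments of 0.05, 0.25 °C and
0.25 °C, and masked to the 3-D convex hull of the observed triples so
the surface is never shown where no data constrain it. The hull is
built by an incremental algorithm maintained in half-space form;
membership allows a tolerance of 100 times the hull's construction
epsilon (10^-10 of the data diameter), so boundary observations count
as inside. Degenerate (coplanar or collinear) observation clouds are
rejected with a message suggesting a lower-dimensional analysis. The
tests verify membership against an independent formulation: a point is
in the hull iff a simplex-constrained least-squares problem has zero
residual.

## Cover rasters, maps and evaluation

Plots on cropland, urban, bare, water or permanent snow/ice land-cover
pixels are removed before analysis. Fractional group-cover rasters are
built by giving each land-cover sub-class the componentwise **median**
group-cover triple of the all-vascular plots it contains, renormalized
to sum to one (componentwise medians need not), then block-averaging
fine pixels to the target resolution; unnatural sub-classes are missing
by construction. Means, not medians, are used at the aggregation step,
so block aggregation conserves the valid-pixel mean exactly.

Trait maps evaluate a fitted GAM per pixel, propagating missingness
from any predictor, with optional masking to the training climate
hull. Coarsening for map comparison uses valid-pixel block means with
a valid-fraction threshold (default 0.5 — a coarse pixel more than
half missing is itself missing; the threshold is a documented choice,
not an estimate), followed by bilinear alignment when the target grid
is not an integer multiple; a literal bilinear resampling is kept
behind `method = "bilinear"` for comparison, since pure interpolation
subsamples rather than averages at strong coarsenings.

Agreement metrics are computed on the natural-log trait scale over
jointly valid pixels: R² (squared Pearson correlation), RRMSE and bias
as proportions of the observed mean, and the slope of the regression of
*observed on predicted* — the direction matters and is fixed; swapping
the arguments is not equivalent. The screening flag requires R² ≥ 0.13
and slope strictly inside (0.5, 2).

All rasters are a minimal in-memory lon/lat grid (rows north to south,
cell-center values, half-open cells) with plain-text ESRI ASCII I/O.
Geographic sophistication (projections, datum handling,
latitude-weighted means) is out of scope; latitude weighting of block
means would matter for truly global grids and is noted as a limitation.

## The synthetic world

The generator exists so that every stage has recoverable ground truth.
Its defaults define the validation conditions and were chosen once, on
generative grounds:

* **Species pool** (400 species, group mix 0.4/0.3/0.3): species
  base log-traits are `intercept + L z + ε`, with `z` two independent
  standard-normal latent factors per species and `L` the planted
  loadings. The two loading columns are exactly orthogonal, and the
  planted dimensions live on disjoint trait blocks — size (H 1.2,
  DM 1.0, LA 0.9) and leaf economics (LMA 0.5, N_area 0.45, SSD 0.35)
  — with deliberately unequal strength. The strength gap makes the two
  dimensions identifiable in sample ordinations: with equal planted
  eigenvalues, any rotation within the plane is an equally good PCA
  solution and axis-by-axis recovery would be ill-posed. Residual noise
  is `noise_sd = 0.2` on the log scale.
* **Climate** is deterministic low-order structure: a latitudinal
  temperature gradient with a seasonal cycle whose amplitude grows with
  absolute latitude (phase flipping across the equator), longitudinal
  harmonics for continentality and moisture, non-negative
  precipitation, and radiation driving the PET stand-in. Units are
  °C and mm directly; no storage encodings of real climate products are
  emulated.
* **Communities**: each plot draws 5–20 taxa with Dirichlet(1) covers
  (typical unevenness); taxa are drawn by group according to a
  Dirichlet-perturbed version of the local land-cover sub-class
  mixture, which ties plot composition to the mosaic the cover-raster
  stage later estimates. About 5% of species carry minority growth
  forms and 5% a mixed-probability form, exercising the omission and
  probability-weighting rules.
* **Climate signal**: each species' realized trait value in a plot is
  its base value plus a group-specific additive shift — a sum of three
  univariate smooth functions of the plot's bioclim triple. The
  additive construction makes the generative per-predictor variance
  shares well defined; plant height carries the strongest signal.
  Stored truth has two levels: exact per-plot expected log-CWMs
  (matching the CWM module to rounding error when `noise_sd = 0`), and
  per-pixel surfaces equal to the climate shift at the pixel plus the
  mean plot-level composition constant — the surface is defined up to
  that additive constant, which is irrelevant to the correlation and
  slope criteria it serves.
* **Land cover**: a fine grid (4 × 4 per coarse cell) with 9 natural
  vegetation sub-classes whose sampling probabilities shift along the
  thermal gradient and 6 unnatural classes hitting a configurable
  overall fraction (default 0.1).

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: taxonomic name error and
resolution, imputation structure in trait databases, sampling bias and
resampling designs of plot databases, spatial autocorrelation of
residuals, soil and land-use covariates, and real-world deviations
from additive trait–climate effects. Recovery results here validate
the *machinery*, not ecological conclusions.

## Validation problem sizes and numerical tolerances

The validation suite uses: 50 random 30 × 4 / 30 × 3 problems for the
ordination oracle (agreement to 10^-8); a 1000-plot world with the
climate signal switched off for planted-dimension recovery (the
controlled ordination experiment isolates the latent covariance; the
analytic captured-variance target is computed from `L` and `noise_sd`
alone, so climate shifts must not add trait covariance); 2000
observations for surface and importance recovery against closed-form
planted values; and a 3000-plot, 40 × 40-pixel world for the
end-to-end map recovery run with coarse-scale evaluation at a 5 × 5
block aggregation. Axis-recovery cosines exceed 0.9 comfortably at the
fixed validation seeds; across arbitrary seeds the alignment can
degrade when the two sample eigenvalues happen to approach each other,
which is a property of PCA, not of the implementation.

Tolerances follow the quantity: exact identities (cover sums, metric
identities on self-comparison) are asserted at 10^-9 to 10^-12;
eigen-oracle agreement at 10^-8; stochastic recovery targets allow the
planted value ± 5 percentage points.

## Known limitations

* PET is a stand-in; no soil-moisture bucket, snow or topographic
  radiation corrections. Supply modeled PET where fidelity matters.
* One code path serves point and grid PET; no attempt is made to mimic
  products whose point and grid routines differ.
* Hull masking is optional for geographic maps (the masked fraction of
  climate space is reported for surfaces); predictions outside the
  training hull are extrapolations and should be treated as such.
* Block means are area-unweighted; at high latitudes on global grids
  this overweights small cells.
* The importance decomposition refits `2^p − 1` models; it is intended
  for the three-predictor bioclim setting, not for large predictor
  sets.
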