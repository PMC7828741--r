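---
title: "Methods: segregation indices, trajectory exposure, and survey harmonization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segregation indices, trajectory exposure, and survey harmonization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciclovia)
```

`ciclovia` quantifies whether open-streets programs let participants
traverse socioeconomic environments unlike their area of origin. This
vignette documents the statistical machinery, the choices made where the
problem is genuinely open, and what the synthetic validation does and does
not establish.

## Evenness indices

Urban segregation has several dimensions; this package implements only
*evenness* — how uniformly SES groups are distributed over geographic
units. For unit $i$ with population $t_i$ and within-unit group proportions
$\pi_{ri}$ over $r$ groups, the entropy score is
$E_i = \sum_r \pi_{ri} \log(1/\pi_{ri})$ (natural log, nats), with the
limit convention $0 \cdot \log(1/0) = 0$ enforced by an explicit guard. The
city-level Theil index is

$$H = \sum_i \frac{t_i\,(E - E_i)}{E\,T},$$

where $E$ is the entropy of the metropolitan composition and $T$ the total
population. $H$ is dimensionless in $[0, 1]$, zero when every unit mirrors
the metropolitan mix and one under complete separation. $H$ is invariant to
uniformly rescaling all populations and to merging units of identical
composition; the test suite asserts both numerically, and checks $H$
against an independent double-loop summation to $10^{-12}$ on random
tables.

Two deliberate reporting choices:

* **Both a city-level index and a local summary are emitted.** Applied
  reports often tabulate a per-city "entropy index (mean ± SD)" that
  cannot be the single Theil $H$; it is a summary of *local* diversity.
  We therefore report both, distinctly labelled: `H`, and the
  mean/SD of the normalized local entropies $e_i = E_i / \log r \in [0,1]$
  (normalization by $\log r$ makes the 0–1 scale exact). Because the
  population-weighting of such summaries is usually unstated, both
  unweighted (`mean_e`, `sd_e`) and population-weighted
  (`mean_e_weighted`, `sd_e_weighted`) versions are returned.
* **Quartile classes.** There is no theoretical basis for cut-points on
  $e_i$, so units are classified at the empirical quartiles (type-7 linear
  interpolation): below Q1 *highly segregated*, then *segregated*,
  *integrated*, and at or above Q3 *highly integrated*. If all $e_i$
  coincide the classification collapses to a single class with a warning.
  A metropolitan area inhabited by a single group has $E = 0$ and $H$
  undefined; this raises a specific error rather than returning NaN.

## Trajectories and exposure profiles

Participants are routed from their home (origin node) to their interview
point on the route (destination node) by shortest path through the street
network. Ties between equally short paths are broken toward the
lexicographically smallest node sequence, reconstructed by a greedy walk
over exact shortest-path distances, so routing is fully deterministic.
Whether real participants travel only to the route or also along it is
unknowable from intercept data; the implementation routes origin →
interview point and documents that choice.

Exposure is measured on the **SES percentile scale**: units are ranked by
SES score and each gets the midpoint percentile of its population block,
$100\,(\mathrm{cumpop}_{<} + 0.5\,t_i)/T$, ties sharing their block's
midpoint. This construction is invariant to monotone rescaling of the raw
score — only the ordering and the population weights matter — and its
population-weighted mean is 50 by construction, which the tests assert.

Each trajectory is cut into half-open 500-m bands $[500k, 500(k+1))$
measured along the path from the origin ($k$ 0-based). The band value is
the length-weighted mean percentile of the units the band's sub-polyline
crosses (a midpoint-join variant is available via `join = "midpoint"`). A
final partial band is kept only if it is at least 50 m long — shorter
tails carry almost no exposure information and add noise. Per
SES-of-origin group and band, the profile records the mean, the sample
variance (0 for a single participant) and the number of participants;
participants whose trips end before band $k$ simply drop out of it, with
no imputation.

The **maximum SES percentile difference** for a group is the signed
largest deviation of its band means from the group's origin baseline (the
mean origin-unit percentile), over bands with at least `min_n`
participants (default 10 — sparse tail bands otherwise dominate through
noise); ties go to the smallest band index, and the distance is reported
at the band midpoint $(k + 0.5) \cdot 0.5$ km, hence always an odd
multiple of 0.25 km. Because the field reports no test for this statistic,
the package supplies an explicitly labelled stand-in: a label-permutation
test that shuffles SES-of-origin labels (together with each participant's
origin percentile, which travels with the label) $B$ times and reports the
add-one p-value $(1 + \#\{|\Delta|_{perm} \ge |\Delta|_{obs}\})/(B+1)$.
Under label independence this p-value is uniform on its lattice; the
acceptance suite verifies a $0.05 \pm 0.01$ rejection rate at
$\alpha = 0.05$ over 500 replicates with $B = 199$.

### Spatial join on the tessellation

Units are disjoint axis-aligned rectangles. Lattice streets run along unit
boundaries, so boundary attribution cannot be left to chance: containment
uses half-open rectangles $[x_{\min}, x_{\max}) \times [y_{\min},
y_{\max})$, clamped on the tessellation's outer east/north edges. Every
point then belongs to exactly one unit, a polyline running along a shared
boundary is attributed to the unit east (or north) of it, and overlays are
exactly conservative: per-participant SES shares and route-overlay
fractions sum to 1 to $10^{-9}$, asserted in the tests.

## Survey harmonization

The harmonization layer is codebook-driven: a YAML file per survey dialect
maps raw columns and answer codes to harmonized variables, and variables a
survey lacks are explicit missing, never imputed. Derived classifications:

* **Age** in completed years (floor) at the observation date — the
  standard survey convention — banded 18–29 / 30–49 / ≥50; under-18 or
  future birthdates are validation errors.
* **BMI** $= \text{kg}/\text{m}^2$ with cut-points <18.5 / [18.5, 25) /
  [25, 30) / ≥30.
* **Self-rated health** 1→excellent, 2→good, 3–5→fair. The harmonized
  labels follow the reporting convention (*excellent/good/fair*) even
  though the underlying item's top anchor is "very good"; the 1→excellent
  mapping is a deliberate reconciliation of the two labelings.
* **Physical-activity guideline**: yes iff
  $\text{moderate} + 2 \cdot \text{vigorous} \ge 150$ min/week (each
  vigorous minute counts double, implementing the "equivalent
  combination"). Minutes of activity *during the program* are treated as
  moderate-intensity and compared to the same 150-min threshold for a
  single event; frequency-adjusted weekly variants are out of scope.
* **Safety** Likert 1–2 → unsafe, 3 → neither, 4–5 → safe; the three
  output classes are standard but the cut-points are not stated anywhere
  authoritative, so the symmetric split is a package choice.

Descriptive tables use per-variable complete-case denominators (a city
with no data on a variable contributes no cells and no column to its
test), with a Pearson χ² test of each variable-by-city table — computed
without continuity correction and warned when any expected count is below
5. Which specific contingency comparisons a given report intends by its
per-city p-value columns is ambiguous; the package computes
variable-by-city tables and says so. No multiplicity adjustment is
applied; p-values are reported raw. The two-level logistic model
(participants within survey city) is fit by maximum likelihood with a
Laplace approximation (`lme4::glmer`), reference levels male / low SES /
primary education, Wald 95% CIs on the log-odds scale exponentiated into
odds-ratio intervals. Constant covariates are dropped with a warning;
separation and non-convergence raise errors with diagnostics rather than
returning silently unstable estimates.

## The synthetic city: what it emulates, and what it does not

The generator provides the statistical structure the analysis assumes,
with every draw taken from a named RNG substream of `(seed, operation)` so
that, e.g., sampling participants never perturbs unit generation.

* **Units**: square cells (default 500 m, the same length scale as the
  exposure bands) on a `grid_rows x grid_cols` grid (default 12 × 20 —
  a few hundred units, elongated west–east so the gradient has room).
  Compositions are Dirichlet with mean following a multinomial-logit
  gradient in `x`: `gradient_strength` (default 4, a strongly sorted city,
  as the motivating settings are) controls sorting, `mixing_noise`
  (Dirichlet concentration, default 5) controls within-unit diversity.
  Populations are Poisson (default mean 1000) — the simplest count model
  with realistic variability — split multinomially by composition. The
  unit SES score is the population-weighted mean of group ranks (1, 2, 3),
  the minimal monotone score consistent with an ordinal low/middle/high
  reading; the unit SES category is the dominant group (ties to the lower
  rank).
* **Routes**: `"crossing"` runs west–east along the middle gridline,
  spanning the full gradient; `"confined"` runs north–south along the west
  edge of the high-SES-dominant district (the first column in which at
  least 75% of units are high-dominant; infeasible without such a column,
  which is an explicit error). Under the half-open join rule the confined
  route's length lies entirely in that district, so its exposure ceiling
  sits at the district's percentile — which is why confined routes
  attenuate the low-origin maximum difference relative to crossing routes,
  the contrast the acceptance suite asserts seed by seed.
* **Participants**: origin units sampled proportional to population
  (optionally within a restricted catchment, emulating an intercept
  survey's recruitment frame), origin node uniform among the unit's nodes,
  interview point uniform over route nodes. Uniform-over-route-nodes is a
  stand-in, not an inference about any study's sampling design.
* **Surveys**: raw tables are emitted in each city's dialect by inverting
  the same codebook used for harmonization — which both guarantees legal
  codes and makes the harmonization layer a genuinely exercised code path
  rather than a pass-through. The outcome (meeting the activity
  recommendation during the program) is drawn from a logistic model with a
  city random intercept and then *encoded as minutes* (≥150 iff yes), so
  the downstream classifier reconstructs the latent outcome exactly.
  Default fixed effects sit at the published odds ratios of the motivating
  analysis (sex 0.90, middle/high SES 0.94/1.21, education 0.92/1.43/1.88),
  city shares at the four surveys' sample-size proportions, covariate
  marginals at the pooled descriptive shares, and the city random-intercept
  SD at 0.5 — a moderate between-city heterogeneity consistent with
  program-level prevalences ranging from ~27% to ~87%.

What the synthetic city does **not** emulate: real road topology (it is a
lattice), geocoding error, route self-selection (origins are sampled
independently of the route unless a catchment is given), non-response, and
the idiosyncratic shapes of real cities. Passing tests therefore establish
that the *computations* are correct and well calibrated under the stated
data-generating process — not that any particular real city will show a
given exposure pattern.

### The planted-span scenario

`planted_span_scenario()` is the package's sharpest end-to-end check: a
one-row city with equal unit populations and strictly increasing scores,
so column $j$ of $C$ sits exactly at percentile $100(j - 0.5)/C$, with a
route ending at the east edge of a chosen column. Participants recruited
from the first column and interviewed uniformly along the route face a
known span of $100\,(j_{end} - 1)/C$ percentile points (40 by default)
between baseline and the far end of the route. The acceptance suite
requires the low-origin maximum difference to recover this span within 5
percentile points at $n = 500$ over 20 seeds; with the default geometry
the recovery is in fact exact, because band values in a one-row city are
noiseless and the last eligible band sits at the route's end.

## Numerical conventions and problem sizes

Proportions must sum to 1 within $10^{-9}$; entropy oracle agreement is
required to $10^{-12}$; overlay conservation to $10^{-9}$; shortest-path
tie-breaks are lexicographic and all other ties break to the smallest
index; coordinates are planar meters throughout (no geodesy — the 500-m
segmentation and route lengths need only metric geometry). Sub-seeds are
derived by hashing the operation name into $[0, 2^{31})$.

The validation sizes are chosen to make Monte-Carlo error small relative
to each tolerance while keeping a full run at desk scale: 100 random
tables for the entropy oracle, 100 random graphs (≤12 nodes) against
exhaustive path enumeration, 20 seeds × 500 participants for exposure
recovery and the scenario contrast, 500 replicates × 199 permutations for
null calibration, and 200 replicates of 4 cities × 800 participants for
model-recovery coverage. The whole suite runs in under ten minutes on one
core.

## Known limitations

* The rectangle tessellation and lattice network are structural
  assumptions of the generator and the join rule; applying the exposure
  machinery to arbitrary polygon tessellations would require replacing the
  locator in `R/overlay.R`.
* The permutation test conditions on the observed trajectories and tests
  label exchangeability — it is a stand-in where no test is specified, not
  a reconstruction of any published procedure.
* Wald intervals from a Laplace-approximated likelihood undercover
  slightly in small samples or with few groups; with 4 groups the
  acceptance suite requires ≥90% empirical coverage rather than the
  nominal 95%.
* A trajectory's maximum difference is a band-mean statistic: it compares
  group-average exposure at a distance, not individual excursions.
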