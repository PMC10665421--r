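---
title: "In silico fracture trials: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico fracture trials: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapmech)
```

## The problem

Mechanoinduction of fracture healing depends on the local strain state in
the fracture gap. Anthropometric parameters — body weight, body height,
BMI, tibia length — shape that strain state, yet fracture trials neither
stratify nor control for them. `gapmech` builds a virtual-trial chain to
ask two questions: how strongly does anthropometry determine gap
micromechanics, and how often do two randomly recruited trial cohorts
differ in anthropometric makeup enough to bias a trial?

The chain has five stages: a synthetic avatar population, body-weight
scaled stance-phase loads, a surrogate mechanical model of the
nail-stabilized fracture, strain-invariant statistics with a correlation
battery, and two cohort-resampling procedures.

## Avatar population

Avatars are men aged 20–60 in eight 5-year age groups, with body height
truncated to 1.60–1.95 m and BMI to 18–35 kg/m², sampled independently
per group from truncated normal laws (inverse-CDF sampling;
`sample_truncated()`). Body weight is derived as `bmi * height^2` and
tibia length from height via a forensic-type stature relation
`length_cm = (height_cm - 81.9) / 2.42` plus a group-specific residual
(default SD 1.2 cm), chosen to reproduce realistic tibia lengths
(1.79 m → ≈ 400 mm).

Per-age-group means and SDs of national survey data are not available at
this granularity, so the defaults are plausible stand-ins: height mean
1.78 m (SD 0.07 m) in every group and BMI mean rising linearly from 25.0
to 27.5 (SD 3.5) with age, with uniform group weights. All of these are
single config fields and are meant to be replaced when real
survey moments are at hand. Truncation is marginal (height and BMI
separately), the natural reading when the two are drawn independently.
Exact age within a group is never materialized because nothing downstream
consumes it.

All randomness flows from one master seed through named streams
(`stream_seed()`): population draws, tibia residuals and the two cohort
algorithms can each be reproduced in isolation.

```{r population}
av <- generate_population(n = 300, seed = 1)
summary(av[, c("height_m", "bmi", "weight_kg", "tibia_length_mm")])
```

## Stance-phase loads

Internal loads at the fracture level are represented by five landmarks
S1–S5 covering the stance phase, each a six-component load (three forces,
three moments) stored as percent of a 755 N reference body weight.
Published instrumented-implant recordings motivate the *shape* of this
table — an axial-force peak of about 2.6 × body weight at S4 and a
bending-moment peak at S5 — but the component values themselves are
configurable stand-ins, not measured data. Coordinates are right-handed
with x anterior, y medial, z superior; stance loads compress the gap
(Fz < 0), which fixes the sign of the hydrostatic strain downstream.

Per avatar the whole table is multiplied by
`lambda = weight * 9.81 / 755`; because the mechanics is linear, every
strain field inherits this factor exactly.

## Surrogate gap mechanics

The patient-specific CT/FE chain that would normally produce gap strains
is not distributable, so the package replaces it wholesale with a
documented surrogate: the nail (solid titanium circle, E = 110 GPa,
ν = 0.3, radius 5.5 mm) and the soft tissue annulus (connective tissue,
E = 3 MPa, ν = 0.3) act as parallel springs across a 3 mm gap. Axial,
bending, shear (correction factor 0.9) and torsional stiffnesses follow
from the section integrals; the six-component load maps linearly to an
interfragmentary motion (`gap_kinematics()`), and the motion maps to a
per-cell strain tensor over polar meshes of the gap annulus (10 × 48
cells) and callus annulus (6 × 48 cells):

* `ezz = (dz + phix*y - phiy*x) / h` — axial offset plus bending,
* `gxz = (dx - thetaz*y) / h`, `gyz = (dy + thetaz*x) / h` — transverse
  shear plus torsion,
* `exx = eyy = -nu_t * ezz` — unconfined Poisson response of the tissue.

The tibial outer radius scales linearly with tibia length
(0.028 × length), the cortical wall is 35% of the outer radius and the
callus extends to 1.3 × the outer radius. This is the channel through
which tibia length (and hence body height) reaches the mechanics: larger
bones place cells at larger radii where bending and torsional strains are
higher. Body weight enters through the load scale factor. Together these
two channels reproduce the qualitative structure of the full-model
analysis — body weight correlates most strongly at the axial-force peak
S4, the length-type parameters at the moment peak S5 — without claiming
any patient-specific fidelity.

The bone fragments themselves are treated as rigid by default; the
density–modulus law `E = 6570 * rho^1.37` (MPa, g/cm³) that assigns bone
material in a voxel-based model is exposed (`density_to_modulus()`)
because it defines the material scale of the modelled bone, but it does
not enter the default spring bundle. The titanium and tissue constants
are literature-magnitude stand-ins and configurable.

What passing tests on this surrogate do show: the analysis chain
(invariants → summaries → correlations → cohort algorithms) behaves
correctly on a linear, anthropometry-dependent strain field with
realistic spatial structure. What they do not show: agreement with any
individual patient's FE strains; published per-landmark correlation
coefficients depend on that unavailable geometry and are mirrored here
only in sign and magnitude class.

## Strain invariants

Per cell the package computes hydrostatic strain, octahedral shear
strain, maximum principal strain and J2. Two naming conventions exist for
the volume-change invariant; `gapmech` uses tr(ε)/3 (mean normal strain)
as "hydrostatic strain" and exposes tr(ε) as `volumetric_strain()`. The
two differ by the constant factor 3, so every correlation downstream is
unaffected by the choice. Tensors store tensor shear components
(ε_xy = γ_xy/2); the conversion from engineering shears happens once, at
the field boundary in `cell_strain_field()`.

The vectorized field path (`field_invariants()`) uses closed-form
component expressions plus the trigonometric eigenvalue solution; the
test suite cross-checks it cell by cell against an independent
eigendecomposition route, and verifies the identity
`oct_shear = 2*sqrt(2*J2/3)`, rotation invariance and homogeneity on
random tensors.

A mechanoregulation classifier over the (hydrostatic, octahedral shear)
plane is included but disabled by default: published threshold diagrams
do not print their boundary values, so the shipped example partition is
illustrative only and deliberately not presented as a validated tissue
model. Boundary points are assigned to the lower region (intervals closed
above), making the partition deterministic.

## Summaries and the correlation battery

Each of the 1500 avatar × landmark fields is reduced per region to mean,
median, IQR, MAD, and the 90th/95th percentiles. Quantiles use type-7
linear interpolation (pinned for testability); the MAD is unscaled
(`median(|x - median|)`, no 1.4826 factor) because it is reported
descriptively, not as a robust SD estimate. Summaries are unweighted per
mesh cell by default, with optional area weighting. The avatar-level
statistic entering the correlation battery is the median; the battery
(4 parameters × 5 landmarks × 2 regions × 4 invariants = 160 rows)
reports two-sided Pearson r and p with a 0.01 significance flag.

## Cohort algorithms

Both procedures use the pooled-SD Cohen's d and the pooled-variance
Student t-test, an internally consistent pair linked by
`t = d * sqrt(n1*n2/(n1+n2))`; a Welch variant exists behind a flag for
sensitivity analysis.

**Algorithm A** draws two disjoint simple-random cohorts of 30 from the
300-avatar population until the pair satisfies `p < 0.05` and
`|d| >= 0.9` on a chosen parameter (default BMI), then the correlation
battery is rerun inside each cohort. Hitting the iteration cap is an
explicit reported outcome (`converged = FALSE`), never an exception. For
validating the stopping rule against a known effect, an optional `strata`
argument draws cohort 1 from one planted subgroup and cohort 2 from the
other; with subgroups two pooled SDs apart the noncentral-t distribution
predicts success on the first draw with probability above 0.99, which the
tests verify empirically. Under the default (unstratified) semantics a
mixed population levels both cohorts toward the same mean, so planted
differences are *not* recovered in one draw — that contrast is the point
of the trial-recruitment simulation.

**Algorithm B** repeats the search over a metadata-only population
(10⁶ subjects by default) for trial sizes 10–60 and d thresholds 0.5–0.9
(grid step 0.1), recording the first qualifying iteration, and averages
over 100 runs per cell. Each iteration draws a fresh disjoint pair; one
run consumes a single RNG stream shared across the whole d grid, so the
recorded counts are pathwise non-decreasing in the threshold (common
random numbers) and one pass serves all thresholds. Runs hitting the
per-run cap are reported as censored, not extrapolated. Because the
stopping event has fixed probability per iteration, counts are geometric;
the tests check the empirical means against `1/P` with `P` from both
closed-form t-tail calculations (no-effect populations, where
`|d| >= tau` is exactly `|t| >= tau*sqrt(n/2)`) and an independent direct
Monte Carlo of the stopping event.

Published summaries of this kind of resampling report iteration counts
whose combination is not reproducible from any single stopping-rule
semantics under standard two-sample theory, so the package asserts only
the structural behaviour: the geometric law, monotonicity in the
threshold, and exponential growth of mean iterations with trial size once
the d condition binds.

## Problem sizes and numerical choices

The default experiment is 300 avatars × 5 landmarks (1500 strain fields,
768 cells each) and runs in seconds. Test-suite checks of Algorithm B use
a reduced metadata population of 10⁵ subjects and per-cell repeat counts
of 100, chosen to keep Monte-Carlo standard errors small relative to the
3-SE acceptance bands. The analysis scripts run the full 10⁶ population
with a per-run cap of 2 × 10⁴ iterations; cells whose expected counts
exceed the cap (large d with large cohorts) are reported with their
censored-run counts.

Degenerate inputs are handled explicitly: zero-SD truncated draws return
the mean (inside bounds) or error (outside); constant samples make
Cohen's d and the Pearson test error rather than return NaN; a constant
cohort parameter makes Algorithm A fail cleanly at its cap; zero-mass
truncation intervals and non-positive stiffnesses are rejected. Mesh
cells sit at sector area centroids so the bending neutral-axis identity
holds to quadrature accuracy, and region medians are converged to about
1% (measured on a degree-1 strain scale) at the default resolution.

## Known limitations

* The surrogate is linear and uncontacted: no fragment contact,
  nonlinear tissue behaviour, screw-level load transfer or nail bend
  geometry; absolute strain magnitudes are far below physiological gap
  strains because the solid-section titanium nail dominates the springs.
  Only relative, correlation-level statements are meaningful.
* Default load-table components and survey moments are stand-ins;
  conclusions about a specific population require replacing them.
* One fracture morphology and one implant configuration; variability of
  real fracture geometries would only widen cohort differences.
* Female, pediatric, geriatric, underweight and obese populations are out
  of scope by design.
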