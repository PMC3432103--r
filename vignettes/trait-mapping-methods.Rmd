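---
title: "Mapping community trait composition from stacked range maps: models and methods"
author: "traitscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping community trait composition from stacked range maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitscape)
```

## The problem

Ecologists increasingly summarise biological communities by the
functional traits of their members rather than by species identities
alone.  Three summaries dominate: the **community-weighted mean**
(CWM) — the mean trait value among individuals; **functional
richness** (FRICH) — the extent of trait space occupied; and
**functional divergence** (FDIV) — the degree to which individuals
spread out across that space.  Maps of these quantities over large
regions are usually built by stacking expert range maps, which forces
a strong assumption: that every species is equally abundant wherever
it occurs.  Whether that assumption matters depends on whether local
abundance covaries with the traits being mapped.

`traitscape` implements a complete, testable version of this mapping
workflow and of an evaluation framework that compares map-based
estimates against site-level survey observations.  Because the data
that motivated the workflow (continental range polygons, trait
databases, long-running volunteer counts) cannot be bundled, the
package includes a first-class synthetic-world generator that
reproduces the statistical structure the analysis assumes, so every
stage is exercised end to end with known truth.

## Abundance estimation methods

Given a presence stack (species × grid-cell occupancy after
elevational refinement), four schemes turn occupancy into per-cell
abundance:

* **(a) uniform** — every species has abundance 1 in every occupied
  cell.  `method_a_uniform()`.
* **(b) population / range area** — each species gets a constant
  abundance equal to its regional population total divided by its
  range size in cells.  The regional total is the mid-point of the
  global minimum and maximum population estimates, rescaled by the
  fraction of the species' occupied area inside the study region
  (`regional_population()`).  Row sums conserve the regional totals
  exactly.
* **(c) survey mean** — each species gets the mean of its per-site
  survey abundances across training sites, constant within its range.
* **(d) environmental model** — per-species additive models of
  survey abundance against three environmental covariates let
  abundance vary both among species and within ranges.

Species enter each method only when the required data exist for them
(population bounds for (b), survey records for (c), enough records
for (d)), so the methods generally operate on nested species subsets,
exactly as in real applications.

### Survey abundance and the correction rule

All survey-derived abundances use one rule
(`effort_corrected_abundance()`): counts are divided by the effort of
their count (observer-hours), averaged over the years in which the
species was recorded at the site (zero-count years are excluded), and
rounded **up** to the nearest integer.  The same rule feeds methods
(c) and (d) and the evaluation observations, so estimate and
observation live on the same scale; the round-up means every recorded
species has abundance at least 1.

### The environmental abundance model

Method (d) fits, per species, an additive model with one fixed
5-degrees-of-freedom regression-spline smooth per covariate
(`mgcv::gam` with `s(x, k = 6, fx = TRUE)`), by default with Gamma
errors and a log link on the positive, effort-corrected response.
The family is configurable (`"gamma"`, `"lognormal"`, `"gaussian"`);
if a Gamma fit fails numerically the species is refitted with the
log-normal variant, which in practice always converges.  Fixed
degrees of freedom (no automatic smoothness selection) are a
deliberate choice: the estimator is then identical for every species
regardless of sample size above the record threshold (default 30
records).

Two numerical guards matter for prediction
(`predict.ts_envmodel()`):

* covariates are **clamped** to each variable's training range before
  prediction, because unconstrained spline extrapolation on a log
  link produces absurd abundances in unsampled environments;
* predictions are **capped** at twice the species' maximum training
  abundance (configurable, `cap`), because a 15-df log-link surface
  fitted to a few dozen points can still spike inside sparsely
  sampled corners of the covariate box.  Without the cap a single
  species can dominate a cell's total abundance by several orders of
  magnitude.

## Trait space and metrics

Traits are two continuous variables — body mass (g) and generation
length (yr), both log-transformed everywhere because they are
strongly right-skewed — and two categorical ones: migratory class
(non-migrant, nomad, altitudinal, latitudinal) and diet class (fruit,
nectar, plant, invertebrate, vertebrate, mixed).

**Gower distances** (`gower_distance()`): continuous traits
contribute absolute differences divided by the trait's range over the
*global* species pool; categorical traits contribute a 0/1 mismatch;
the distance is the unweighted mean over the traits in scope.  Using
the global (not per-community) range keeps distances comparable
across cells, which is what makes maps of FDIV interpretable.  A
continuous trait with zero pool range contributes 0 (it carries no
discriminating information; this avoids 0/0).  Species with missing
trait values are rejected — the workflow excludes them upstream.

**PCoA** (`trait_pcoa()`): classical metric scaling of the all-traits
Gower matrix via `stats::cmdscale`; axes with non-positive
eigenvalues are dropped.  For the multivariate hull we keep the
smallest number of leading axes explaining ≥ 95% of the positive
eigenvalue mass, capped at 3 (`select_axes()`).  The cap keeps hull
volumes defined at species-poor cells (a hull in *k* dimensions needs
more than *k* affinely independent points) and bounds the cost of the
exact hull computation; it is configurable.

**CWM**: `sum(A_s x_s) / A` for continuous traits; for categorical
traits the proportion of individuals in each class.  Proportions over
the classes of a trait sum to 1 by construction.

**FRICH**: per trait, the range of values present (continuous) or the
number of classes present (categorical); over all traits together,
the convex-hull volume of the community's PCoA coordinates
(`convex_hull_volume()`, exact 2-D/3-D computation with degenerate
communities returning 0 plus a flag rather than an error).  FRICH
ignores abundance by its nature and is therefore only produced for
the presence-based method (a).

**FDIV**: Rao's quadratic entropy
`Q = sum_s sum_s' d(s,s') (A_s/A)(A_s'/A)` — the expected trait
distance between two randomly drawn individuals — converted to its
numbers equivalent `1/(1 - Q)`, the effective number of equally
abundant, maximally distinct species.  With distances in [0, 1], `Q`
for `S` equally abundant, mutually maximally distinct species is
`(S-1)/S` and the numbers equivalent is exactly `S`; the test suite
verifies this algebra for `S = 2..10` and checks `rao_q()` against a
brute-force double sum at tolerance 1e-12.

```{r metrics-example}
tr <- data.frame(
  species_id = c("wren", "thrush", "hawk"),
  log_mass = log(c(10, 80, 900)),
  log_genlength = log(c(2, 3.5, 8)),
  migratory_class = c("non-migrant", "latitudinal", "non-migrant"),
  diet_class = c("invertebrate", "mixed", "vertebrate"))
d <- gower_distance(tr)
q <- rao_q(c(wren = 10, thrush = 4, hawk = 1), d)
c(Q = q, FDIV = numbers_equivalent(q))
```

## Ranges and the presence stack

Range extents are refined by excluding cells whose (cell-mean)
elevation lies outside the species' reported elevational limits,
*inclusive* at both bounds (`refine_by_elevation()`); the limits
themselves are retained because only elevations outside them are
excluded.  Whether a species straddling its limit within one 20-km
cell should be kept is genuinely ambiguous at this resolution;
cell-mean elevation is this package's choice, flagged as such.
Species whose refined range is empty stay in the stack as all-zero
rows (with a message) so species indexing is stable across modules.
Grid cells are addressed 1-based in native (column-major) matrix
order, the natural convention in R.

## The synthetic world

`generate_landscape()` builds smooth layers (low-order trends plus
Gaussian-filtered noise): an elevation ridge and three environmental
covariates patterned loosely on temperature, precipitation and
minimum temperature.  `generate_species_pool()` draws log-normal mass
(median 50 g) and generation length (median 4 yr), class frequencies
mirroring a hemispheric avifauna (invertebrate-feeders commonest,
nectarivores rarest; most species non-migratory), wide elevational
tolerances, log-normal range sizes, and per-species log-linear
abundance responses to the standardised covariates.  Global
population bounds are generated consistently with each species' own
abundance scale and range size, with log-normal error and a
configurable fraction of species lacking estimates (default 30%,
mirroring the incompleteness of real population data).

The switch that matters scientifically is `trait_coupling`: at 0
(default) abundance intercepts are independent of traits — the regime
in which presence-only mapping is unbiased, and the regime real
survey data appear to occupy (mean abundance–mass correlations near
zero).  Positive values add that multiple of centred log-mass to each
species' log-abundance intercept, creating the bias regime in which
abundance-ignoring maps must fail.

`simulate_surveys()` draws `count ~ Poisson(lambda × effort × p)` per
site, species and year, with log-normal or fixed effort and an
optional logistic detection probability in centred log mass,
migratory class and centred log range size.  Detection acts only on
the records, never on the truth surfaces, because detectability is a
nuisance of observation, not a property of the community.

What the generator does **not** emulate: phylogenetic trait
correlation, temporal population trends, spatial aggregation of sites
(sites are uniform random cells), within-cell habitat heterogeneity,
vagrancy (species recorded outside their range), and range-map
commission error beyond what elevational refinement introduces.
Passing tests therefore demonstrate the correctness of the machinery
and the logic of the comparisons, not that real range maps achieve
any particular accuracy.

## Evaluation

Estimates at a site are read from the single grid cell containing the
site centroid (a 3×3-neighbourhood mean is available by
configuration).  Observed site communities go through *exactly the
same* metric code path as map cells (`community_metrics()`), which a
test enforces by feeding one community through both.

For every (metric, trait scope, method) pair,
`regress_estimate_on_observed()` regresses estimate on observation:
precision is the OLS R² with the correlation test's p-value; accuracy
is the fitted slope with a t-test of departure from the 1:1 line,
two-sided by default (one-sided `slope < 1` available, since
under-estimation at high observed values is the typical failure
mode).  Numerically perfect fits report `t = 0`, `p = 1` at slope 1
instead of dividing by a ~0 standard error.  Zero variance in the
observations refuses the fit.

Spatial robustness uses a simultaneous autoregressive error model
(`sar_error_model()`): `y = Xb + u`, `u = lambda W u + e`, with
row-standardised weights from a Delaunay triangulation of site
coordinates, profile maximum likelihood over `lambda` (log-determinant
from the eigenvalues of `W`), GLS slope standard errors at the
estimated `lambda`, and a likelihood-ratio test of `lambda = 0`.  The
Delaunay triangulation is computed exactly by the empty-circumcircle
property, which is entirely adequate for site networks of a few
hundred points; duplicate coordinates are jittered with a message.

Composition accuracy is the Jaccard similarity between the species
predicted by the stack at a site's cell and the species observed
there.  `trait_abundance_screen()` tests, per site, whether log
abundance covaries with the continuous traits (Pearson) or differs
among classes (one-way ANOVA), summarised as mean r ± SE and counts
of significant sites.  `detectability_glm()` relates the number of
sites at which each species was recorded to log range size, log mass
and migratory class with a quasi-Poisson GLM and reports a sequential
partition of explained deviance.

## Pipeline, configuration and reproducibility

`run_pipeline()` chains the stages under a single validated
configuration (`default_config()` / `validate_config()`, YAML
round-trip via `write_config()`/`read_config()`).  One master seed is
fanned out to per-stage streams through a documented hash
(`derive_seed`), so each stage is individually reproducible and two
runs of the same configuration are numerically identical; a manifest
(config hash, package and R versions) accompanies written artifacts.
`inst/scripts/traitscape.R` wraps the pipeline for shell use.

Default problem sizes — a 20×20 equal-area grid (nominal 20-km
cells), 40 species, 80 sites of which 20 are held out for evaluation,
five survey years — were chosen so that a full run takes seconds
while every eligibility filter (population data, recorded species,
record thresholds) still bites, mirroring the nested species counts
a real application produces.  The bias-contrast experiment in the
test suite uses a denser design (180 sites, 8 years, ranges covering
most of the grid, wide elevational tolerances) because the regime it
probes requires the environmental method's species set to be
effectively complete: species excluded by the record threshold are
missing from the estimate but present in the observation, which
otherwise confounds the comparison.

## Numerical choices, in one place

* Jost correction implemented as `1/(1 - Q)` — the standard numbers
  equivalent of Rao's Q for distances in [0, 1].
* Slope-departure test two-sided by default; sidedness configurable.
* Elevational limits inclusive; cell-mean elevation decides a cell.
* Gower normalisation by global pool range; zero-range traits
  contribute 0.
* PCoA axes: positive eigenvalues only; hull axes ≥ 95% eigenvalue
  mass capped at 3.
* Degenerate hulls (too few species, affine dependence) give volume 0
  with a `degenerate` flag, never an error.
* GAM smooths: fixed 5 df per covariate; covariate clamping and a
  2× response cap at prediction; log-normal fallback on numerical
  failure.
* Effort correction: zero-count years excluded; round-up to integer.
* Perfect regression fits report `t_unity = 0` rather than 0/0.
* SAR: Delaunay neighbours, row-standardised weights, profile ML,
  LR test for the error-autocorrelation parameter.

## Known limitations

The hull computation is exact but combinatorial, so it is capped at 3
axes; site placement ignores the strong spatial clustering of real
survey networks; the SAR implementation covers the spatial-error
specification only (no lag or mixed models); and the synthetic
abundance model is log-linear in the covariates — adequacy of that
stand-in for any real system is a configuration matter, not a claim.
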