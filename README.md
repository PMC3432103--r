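# traitscape

Mapping the functional-trait composition of ecological communities
from stacked species range maps — and testing how good such maps are.

## The problem

Large-scale maps of community trait composition are usually built by
overlaying expert range maps, which implicitly assumes every species
is equally abundant everywhere it occurs.  `traitscape` implements
that workflow together with three alternatives that inject increasing
amounts of abundance information, and an evaluation layer that
compares all of them against site-level survey observations:

* **method (a)** — range overlay: abundance 1 inside every range;
* **method (b)** — regional population size (mid-point of global
  bounds × area fraction) divided by range area;
* **method (c)** — mean effort-corrected survey abundance, constant
  within each range;
* **method (d)** — per-species additive models (5-df smooths, log
  link) of abundance against three environmental covariates.

From each abundance field the package computes, per grid cell and per
survey site: community-weighted means (CWM; `Σ A_s x_s / A`
for continuous traits on the log scale, class proportions for
categorical ones), functional richness (FRICH; trait ranges/class
counts, plus the convex-hull volume in Gower/PCoA trait space), and
functional divergence (FDIV) as Rao's quadratic entropy

    Q = Σ_s Σ_s' d(s,s') (A_s / A)(A_s' / A)

converted to its Jost numbers equivalent `1 / (1 − Q)`.  Estimates
are evaluated against observations by OLS (R², correlation p, slope,
t-test of slope = 1), spatial-error (SAR) refits, Jaccard composition
similarity, per-site trait–abundance screens, and a quasi-Poisson
detectability model.

Because the motivating data (range polygons, trait databases,
volunteer count schemes) cannot be bundled, the package ships a
first-class synthetic-world generator — landscapes, species pools,
contiguous ranges grown by neighbour accretion, elevational
refinement, abundance surfaces, and effort-dependent,
detectability-biased Poisson survey counts — so the whole pipeline
runs end to end with known truth.

## Worked example

```r
library(traitscape)
res <- run_pipeline(default_config(seed = 42), quiet = TRUE)
print(res)
#> traitscape pipeline run: 40 species, 20 x 20 grid, 80 sites
#>   methods: a, b, c, d; evaluation sites: 20; report rows: 77
#>   mean Jaccard similarity at evaluation sites: 1.00

df <- as.data.frame(res$report)
df[df$trait_scope == "mass", c("metric", "method", "r2", "slope", "p_unity")]
#>  metric         method   r2 slope p_unity
#>     CWM        uniform 0.32  0.40 0.00048
#>    FDIV        uniform 0.58  0.65 0.01553
#>   FRICH        uniform 1.00  1.00 1.00000
#>     CWM pop_over_range 0.30  0.51 0.01575
#>    FDIV pop_over_range 0.33  0.60 0.06215
#>     CWM    survey_mean 0.78  0.82 0.08446
#>    FDIV    survey_mean 0.69  0.62 0.00108
#>     CWM      env_model 0.60  1.15 0.51540
#>    FDIV      env_model 0.55  0.67 0.03827
```

Read: for CWM body mass the range-overlay estimate correlates with
the observed site values (R² = 0.32) but its slope of 0.40 is far
from the 1:1 line (p = 5e-4) — the estimate compresses the real
between-site variation.  The environmental method's slope (1.15) is
statistically indistinguishable from 1 (p = 0.52).  FRICH, which
ignores abundance, is recovered exactly here because the simulated
surveys detect every present species; species richness behaves the
same (R² = 1, slope = 1).  In this default world abundance is
independent of traits, and the per-site screens reflect it (mean
abundance–mass correlation 0.155 across 80 sites); the detectability
model attributes its explained deviance almost entirely to range
size, as it should when detection is perfect.

Maps are available as matrices via `metric_map_matrix()`, raw long
tables in `res$metric_maps`, and a shell entry point lives at
`inst/scripts/traitscape.R` (`init` / `validate` / `run-all`
subcommands over a YAML configuration).

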