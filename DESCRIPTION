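Package: traitscape
Title: Mapping and Evaluating the Functional-Trait Composition of
    Communities from Stacked Range Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping the functional-trait composition of
    ecological communities from stacked species range maps under four
    abundance-estimation schemes (uniform presence, population size over
    range area, mean survey abundance, and environmental abundance
    models), and for evaluating the resulting maps against site-level
    survey observations.  Computes community-weighted mean traits, Gower
    trait distances, principal-coordinates trait spaces, convex-hull
    functional richness, and Rao quadratic entropy with its Jost numbers
    equivalent.  Includes a synthetic-world generator (landscapes,
    species pools, contiguous ranges, abundance surfaces,
    effort-dependent and detectability-biased survey counts) so the
    whole pipeline can be exercised and tested without external data,
    plus an evaluation layer with ordinary and spatial-error
    regressions, Jaccard composition similarity, per-site
    trait-abundance screens and a detectability model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    stats,
    grDevices,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite
Config/testthat/edition: 3
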