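Package: leafatlas
Title: Quantitative Cellular and Subcellular Atlas of a Reference Leaf
Version: 0.1.0
Authors@R:
    person("Atlas", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A unit-aware pipeline for building a quantitative atlas of an
    Arabidopsis thaliana reference rosette leaf (leaf 6). From primary
    measured parameters (cell densities, vein metrics, organelle counts and
    volumes, shape parameters) it computes cell censuses, subcellular volume
    budgets with free-variable closure, membrane surface areas from
    closed-form shape models (sphere, ellipsoid, capsule, cylinder,
    semi-torus, pavement prism), cell-wall volumes, basis conversions (per
    leaf, per gram fresh weight, per mg chlorophyll) and harmonised
    metabolite concentrations in micromolar. Includes a provenance-tracked
    parameter compendium format, a bundled reference-leaf fixture and
    synthetic-data generators with ground-truth ledgers for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
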