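Package: paoscope
Title: Soil Polyphosphate-Accumulating Organism Community Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying soil polyphosphate-accumulating organism (PAO)
    communities under climate manipulation experiments. Implements PAO
    identification filters for FACS-sorted amplicon OTU tables, Shannon
    diversity and functional redundancy, linear mixed-model treatment effect
    sizes with renormalization, single-cell Raman spectral preprocessing and
    operational phenotypic unit (OPU) clustering, random matrix theory based
    co-occurrence network construction with a full complexity and stability
    metric suite (cohesion, modularity and nestedness against null models,
    robustness, vulnerability, node roles), and correlation screens linking
    community metrics to ecosystem functioning. A design-structured synthetic
    data generator with planted treatment effects provides a ground-truth test
    bed for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    vegan,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
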