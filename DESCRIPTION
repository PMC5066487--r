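Package: flophase
Title: Segmentation of Longitudinal Flowering Series into Stationary Phases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the longitudinal analysis of weekly organ-emergence
    counts in perennial plants, motivated by perpetual flowering in cultivated
    strawberry. Weekly inflorescence counts from all plants of a genotype are
    modelled as a multivariate series that switches between a small number of
    stationary flowering phases. The package fits synchronous multiple
    change-point models with categorical emission distributions by dynamic
    programming, selects the number of phases with the integrated completed
    likelihood (ICL) criterion via exact forward-backward computations of the
    segmentation likelihood and entropy, and reports posterior probabilities
    of models, segmentations, and change-point positions. Downstream helpers
    build consensus segmentations over pooled genotypes, extract per-phase
    trait tables, and compute marker-association and flowering-runnering
    correlation statistics. A seeded synthetic-data generator emulates the
    panel structure the model assumes, so the whole pipeline is testable
    without access to raw field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
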