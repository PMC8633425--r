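Package: netatrophy
Title: Connectome-Constrained Analysis of Longitudinal Brain Atrophy Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating longitudinal brain atrophy progression to
    network architecture and regional biology at the parcel level. Implements
    W-score normative modelling of deformation values against healthy-control
    age and sex effects, atrophy-progression maps with repeated-measures
    permutation inference, spatial-autocorrelation-preserving spin
    permutation nulls on spherical parcellations, connectome
    neighbourhood-atrophy statistics with comparison of dependent
    correlations, virtual-histology cell-class decoding, and a gene-wise
    screen feeding hypergeometric/Fisher overrepresentation analysis. A
    synthetic-data module generates atlases, connectomes, longitudinal
    cohorts and spatially autocorrelated expression data with planted
    effects for parameter-recovery and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
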