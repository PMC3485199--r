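Package: cyclehubs
Title: Temporal Interaction Networks and Competitive Regulation of
    Cell-Cycle Hub Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Overlays smoothed cell-cycle expression time courses on
    hub-seeded protein-interaction networks for budding yeast. Calls each
    gene periodic or aperiodic with a cosinor fit and a permutation test,
    classifies one- and two-interface ("singlish") hubs as dynamic
    (competitive) or static (non-competitive), renders threshold-gated
    network frames headlessly, and quantifies interface competition among
    interaction partners over time. Ships a synthetic-data generator that
    emulates synchronized-culture experiments with ground-truth labels so
    the full pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    igraph,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'competition_metrics.R'
    'data_io.R'
    'hub_classification.R'
    'periodicity.R'
    'pipeline.R'
    'smoothing.R'
    'synthetic_data.R'
    'temporal_network.R'
    'utils.R'
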