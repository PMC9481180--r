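Package: icephys
Title: Current-Clamp Intrinsic-Property Extraction and Electrophysiological Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extraction of intrinsic electrophysiological features from
    whole-cell current-clamp recordings (resting membrane potential, input
    resistance, membrane time constant, capacitance, action-potential and
    spike-train features), classification of immature spikelet responses,
    quantification of tetrodotoxin blockade, and unsupervised phenotyping of
    cells by Ward hierarchical clustering with silhouette-based model
    selection and Barnard unconditional exact composition testing. Includes
    a synthetic-membrane simulator (passive RC, adaptive exponential
    integrate-and-fire, and spikelet generators) providing ground truth for
    every pipeline stage, and readers/writers for a simple CSV/HDF5 sweep
    dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    jsonlite,
    yaml,
    minpack.lm,
    rhdf5,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
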