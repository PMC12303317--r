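Package: hrvnet
Title: Correlation Networks and Graph-Convolutional Importance for Early-ICU Physiological Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts heart-rate-variability, vital-sign and clinical features
    from early intensive-care monitoring data of traumatic brain injury
    patients, builds a thresholded Pearson correlation network over the
    resulting 51-feature table, and ranks features by the L2 norms of node
    embeddings from an unsupervised two-layer graph-convolutional
    autoencoder. Includes a seeded synthetic-cohort generator (240 Hz ECG,
    gappy minute-level vitals, pathology, Glasgow Coma Scale and
    demographics) with planted latent-factor correlations so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
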