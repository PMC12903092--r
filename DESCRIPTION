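Package: meaburst
Title: Burst Detection, Network Fingerprinting and Simulation for
    Micro-Electrode Array Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of multiwell micro-electrode array (MEA) recordings of
    cultured neuronal networks. Detects electrode bursts with the maximum
    inter-spike-interval algorithm, detects well-level network bursts by Otsu
    thresholding of the smoothed, standardized population signal, classifies
    fragmented network bursts, extracts a 39-parameter network activity
    fingerprint per well, selects stable and variable parameters from PCA
    loadings with a UMAP overview embedding, and compares network burst
    duration distributions with an empirical-quantile exceedance procedure.
    Includes a synthetic spike-train generator with ground-truth burst
    annotations so every stage of the pipeline is verifiable without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    uwot
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
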