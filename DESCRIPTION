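Package: spotMSI
Title: Spatial Segmentation and Differential Statistics for MALDI Imaging of
    Printed Membrane Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for MALDI mass-spectrometry imaging of printed
    membrane microarrays, as used to profile the lipidome of extracellular
    vesicle preparations spotted on glass slides. Provides a synthetic-data
    generator that emulates the array geometry (450-micron spots rastered on a
    150-micron grid, nine pixels per spot) and negative-ion lipid spectra with
    known ground truth; spectral preprocessing (total-ion-current
    normalization, peak alignment and picking, 0.5-percent base-peak
    filtering); divisive hierarchical segmentation using a competing
    random-walker split function on a pixel-similarity Markov chain, with
    correlation-based segment colouring and PCA; and spot-level differential
    statistics (dual-replicate Student t filtering of lipid forms, and
    fold-change/significance classification of protein quantitation tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    mclust,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
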