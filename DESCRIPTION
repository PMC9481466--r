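Package: ldscreen
Title: Analysis of Genome-Scale Imaging Screens for Lipid-Droplet Protein Targeting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of high-content RNAi imaging screens that
    quantify endoplasmic-reticulum-to-lipid-droplet protein targeting. Provides
    a synthetic-data generator for 384-well screening plates and multi-channel
    fluorescence fields with ground-truth masks; random-forest pixel
    classification and nucleus-seeded watershed segmentation of nuclei, cells
    and lipid droplets; per-cell lipid-droplet targeting ratios with
    autofluorescence correction and per-well median aggregation; robust
    Z-score (median/MAD) hit calling with cell-death and small-droplet
    filters and replicate concordance; confocal Otsu/Huang-threshold targeting
    metrics; and object-based 3D colocalization by closest boundary distance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ranger,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
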