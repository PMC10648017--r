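Package: forestseg
Title: Automatic Forest Labeling and Downscaled U-Net Segmentation for
    Multi-Band Aerial Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates forest/no-forest pixel labels for 4-band (RGBN)
    aerial imagery without manual annotation: a Gaussian mixture model is
    fitted to pixel spectra, the number of clusters is selected by an
    AIC/BIC elbow rule, clusters are merged into a binary forest mask,
    masks are cleaned with median and morphological closing filters, and
    labeled images are ranked by the Davies-Bouldin cluster-validity
    index. The best images are tiled into fixed-size patches and used to
    train a family of downscaled U-Net segmentation models whose kernel
    and trainable-parameter counts are derived analytically from an
    architecture ledger. A synthetic 4-band scene generator with known
    ground truth supports end-to-end testing of the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
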