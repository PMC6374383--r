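Package: iftomo
Title: Immunofluorescence Tomography: 3-D Reconstruction and Quantification of Serial-Section Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs high-resolution 3-D volumes from 2-D images of
    immuno-stained plastic serial sections and quantifies cell sub-populations.
    Provides mosaic tile stitching with correlation-based offset refinement,
    rigid slice-to-slice registration on the nuclear (DAPI) channel, re-probe
    channel fusion, anisotropic-voxel volume assembly, 3-D nucleus segmentation
    by thresholding and 26-connectivity connected components, and classification
    of label-retaining cells by fluorescence-intensity binning. Includes a
    synthetic serial-section phantom generator with full ground truth
    (ellipsoidal nuclei, 50%-per-division label dilution, physical sectioning,
    per-section rigid misplacement, overlapping mosaic tiles, noise) so every
    pipeline stage can be validated without real data.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
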