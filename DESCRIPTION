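Package: OrganelleEM
Title: Instance Segmentation and 3D Reconstruction of Mitochondria and
    Endoplasmic Reticulum from Serial Electron Microscopy
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An automated pipeline for reconstructing mitochondria and
    endoplasmic reticulum (ER) from anisotropic serial-section electron
    microscopy volumes. Mitochondria are detected per slice by a feature
    pyramid detection subnetwork and delineated by a recursive segmentation
    subnetwork whose field of view moves in eight directions beyond the
    detection box; ER and nuclear membrane are segmented jointly by a fully
    convolutional residual encoder-decoder and separated by a connected
    component relabeling rule. Per-slice instances are linked into 3D
    objects, rectified morphologically, and filtered by z-length.
    Morphometric measurements (skeletons, cross sections, volume and
    surface area, mitochondria-ER minimum distances and contact bands) are
    reported in physical units. A seeded phantom generator provides paired
    ground truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    png,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Segmentation, CellBiology, Visualization
RoxygenNote: 7.3.3
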