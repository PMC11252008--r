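Package: SynaptoSeg
Title: Synaptic Cleft Detection and Single-Bouton Morphometry in 3D
    Super-Resolution Volumes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and instance segmentation of putative synaptic cleft
    regions (pSCRs) in extracellularly labeled 3D super-resolution light
    microscopy volumes. High-intensity features of the structural
    (extracellular label) channel are isolated by percentile-formula global
    thresholding or a refined local (multi-Otsu) procedure, guided by
    pre-/post-synaptic marker channels, classified by marker co-localization,
    and assigned to mossy fiber boutons. Mesh-based morphometry (marching
    cubes, ball-pivoting contact surfaces) quantifies bouton volume, surface
    area and cleft contact area; spine extraction and bouton-spine interaction
    graphs quantify connectivity; object-level IOU/Dice precision-recall-F1
    metrics validate segmentations. A seeded synthetic phantom generator
    produces multi-channel test volumes with full ground truth so the whole
    pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    rhdf5,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, Segmentation, ImageImport
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'connectivity.R'
    'marching-table.R'
    'marker-masks.R'
    'metrics.R'
    'morphology.R'
    'morphometry.R'
    'phantom.R'
    'pipeline.R'
    'preprocess.R'
    'segmentation.R'
    'tiff-codec.R'
    'volume-io.R'
    'zzz.R'
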