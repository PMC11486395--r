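Package: smregister
Title: Scripted Registration of Spatio-Molecular Data to Microscopy Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A headless registration engine for aligning spatio-molecular
    point data (e.g. MERFISH cell centroids or Slide-seq bead coordinates
    with cluster annotations and gene counts) to related microscopy images
    such as H&E stains. Provides rigid manipulations (scaling to a common
    display scale, rotation, translocation, rotation-compensated flips)
    with a replayable undo/redo log, an elastic point-drag deformation with
    threshold-bounded linear falloff, annotation-preserving display
    downsampling with exact full-data replay on export, registration
    quality metrics (binned per-gene Spearman correlation between serial
    sections and tissue-mask overlap), and a fully seeded synthetic fixture
    generator. Reads CSV, XLSX and AnnData h5ad coordinate containers and
    PNG/JPEG images; writes self-sufficient registration bundles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    readxl,
    rhdf5,
    EBImage,
    Matrix,
    digest,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: Spatial, Transcriptomics, Alignment, Visualization
Config/testthat/edition: 3
RoxygenNote: 7.3.3
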