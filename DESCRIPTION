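Package: enteroquant
Title: Quantification of Enteroid Imaging, Electrophysiology and Rescue
    Transcriptomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of patient-derived intestinal enteroid
    assays as used in studies of microvillus inclusion disease (MVID):
    prominence-based cell counting and skeleton Feret-caliper brush-border
    continuity scoring on multiplex immunofluorescence images, pairwise
    channel correlation with hierarchical clustering, short-circuit-current
    trace analysis with four-parameter logistic dose-response fitting,
    ratiometric intracellular-pH calibration and Na+/H+ exchanger activity
    kinetics, forskolin-induced enteroid swelling quantification, an
    opposite-direction differential-expression "rescue gene" filter, and
    2^-ddCt qPCR quantification. A seeded synthetic-data generator emulates
    every input modality with known ground truth so the whole pipeline is
    testable without raw microscopy, electrophysiology or sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    minpack.lm,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
biocViews: Software, CellBiology, Transcriptomics, Visualization
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'electrophys.R'
    'enteroquant-package.R'
    'find-maxima.R'
    'io.R'
    'mxif.R'
    'ph.R'
    'pipeline.R'
    'rescue.R'
    'utils.R'
    'skeleton.R'
    'swelling.R'
    'synthetic-assay.R'
    'synthetic-de.R'
    'synthetic-image.R'
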