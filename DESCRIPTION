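Package: microquant
Title: Quantification Pipelines for Amyloid, Microglial and Tau
    Immunofluorescence with Single-Cell QC and Behavioral Indices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable implementations of the image-quantification readouts
    used in microglia depletion/repopulation studies of Alzheimer's disease
    mouse models: calibrated-stack projections, Otsu and Kapur
    maximum-entropy histogram thresholding, particle analysis with physical
    size cut-offs, micrometre-calibrated morphological dilation and mask
    algebra, plaque burden and plaque-associated neuritic damage (LAMP1),
    microglial coverage, recruitment and activation metrics, and
    phospho-Tau epitope ratios. Also provides the rule-based single-cell
    RNA-seq quality-control filter, Wilcoxon rank-sum marker detection with
    log-fold-change gating, cluster proportion accounting, hypergeometric
    overrepresentation tests, the novel-object-recognition discrimination
    index, and seeded synthetic-data generators (fluorescence scenes with
    ground truth and count matrices with planted failures) so every stage
    is testable without microscope or sequencer output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    Matrix,
    jsonlite,
    yaml,
    tiff,
    methods,
    stats,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
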