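Package: isletAge
Title: Isotope Birth-Dating, Consensus Regulatory Networks and Metabolic
    Phenotyping for Islet Cell Longevity Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying cell longevity and metabolic phenotype in
    stable-isotope labelling (SILAM) studies of the endocrine pancreas.
    Implements per-nucleus 15N/14N ratiometry on multi-isotope imaging mass
    spectrometry (MIMS) count rasters with fiducial-based affine registration;
    the label-dilution birth-dating model in which nuclear 15N excess halves
    at each cell division, with neuron-referenced long-lived-cell
    classification, division-count estimation and a finite mixture
    deconvolution of division numbers; a consensus filter for gene-regulatory
    networks inferred across repeated stochastic runs, with regulon-activity
    binarization, transcription-factor co-activity modules and betweenness
    influence ranking; a rank-based ROC enrichment screen for imaging
    mass-spectrometry ions with accurate-mass metabolite matching; and
    glucose-homeostasis phenotyping statistics (baseline-normalised meal
    tolerance AUC, Kitt glucose disappearance rate, HOMA-IR,
    calorie-restriction ration schedules and digested-energy accounting). A
    synthetic-data module generates every input with known ground truth so the
    full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    mclust,
    pracma,
    tiff,
    jsonlite,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
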