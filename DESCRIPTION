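Package: msDrugLib
Title: Drug MS/MS Spectral Libraries, Analog Propagation and Exposure Readout
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to assemble tandem mass spectrometry (MS/MS) drug spectral
    libraries with controlled-vocabulary pharmacologic metadata, to propagate
    candidate drug analogs from an MS/MS corpus by modified-cosine spectral
    alignment with a five-filter curation cascade (exposure source, curated
    delta-mass list, known-library match, structural similarity of shared
    parents, background-cohort prevalence), and to produce empirical
    drug-exposure readouts from untargeted metabolomics feature tables:
    annotation, ontology summaries, co-occurrence stratification and
    exposure-metabolite statistics. Includes a monoisotopic mass engine,
    MGF/MSP readers, and synthetic-fixture generators with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    cluster,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
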