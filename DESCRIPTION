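Package: synscreen
Title: Equimolar Drug-Combination Synergy Screening and High-Content
    Dominance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for image-based drug-combination screens in
    cancer cell lines. Converts well-level cell counts to normalized growth
    rates, fits four-parameter logistic dose-response curves with a
    closed-form area under the curve, and scores pairwise synergy by excess
    over Bliss independence, the Loewe combination index, and the drug
    sensitivity score. A high-content branch segments nuclei from
    three-channel fluorescence fields, extracts per-cell features, summarizes
    treatments as signed Kolmogorov-Smirnov profiles, and classifies
    combination responses as dominant, recessive, codominant, or interactive
    via shrinkage linear discriminant analysis, nearest-neighbor assignment,
    and a Bayesian confidence score. Includes synthetic-data generators with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    minpack.lm,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    MASS,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
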