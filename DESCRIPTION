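Package: psmaburden
Title: Whole-Body PSMA-PET Tumour Burden Quantification and Response
    Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative response assessment for whole-body PSMA-PET in
    metastatic castration-resistant prostate cancer. Segments tumour
    lesions by SUV thresholding (fixed SUV 3.0 threshold with a relative
    1.5 x liver-SUVmean rule for liver disease and mask-based exclusion
    of physiological uptake), computes per-lesion and whole-body
    molecular tumour volume (MTV, mL) and total lesion PSMA
    (TLP, mL x SUV), classifies per-patient response by modified PERCIST
    bands on delta-TLP/delta-MTV with a new-lesion override and by PCWG3
    PSA criteria, and provides the accompanying statistics: method
    concordance, Spearman correlation screens, cohort summaries, and
    Kaplan-Meier / log-rank survival stratification. A synthetic phantom
    and cohort generator with known ground truth makes every stage
    testable without image downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    igraph,
    jsonlite,
    survival,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
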