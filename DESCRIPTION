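Package: glycoPRM
Title: Targeted PRM Quantitation of Site-Specific Isomeric N-Glycopeptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A desk-scale pipeline for targeted LC-PRM-MS analysis of serum
    haptoglobin site-specific isomeric N-glycopeptides in cirrhosis versus
    hepatocellular carcinoma. Provides glycopeptide and fragment-ion mass
    construction from four-digit glycan composition codes, a transition-list
    builder for the three haptoglobin glycosylation sites (Asn184, Asn207,
    Asn241), a synthetic-cohort generator that renders PRM-style fragment
    chromatograms with known ground truth, extracted-ion-chromatogram peak
    detection and trapezoidal integration, per-site relative-abundance
    normalization, and marker statistics (gender-balanced differential
    testing with Bonferroni correction, PCA, and single- and combined-marker
    ROC/AUC with DeLong confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    cluster,
    withr
Config/testthat/edition: 3
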