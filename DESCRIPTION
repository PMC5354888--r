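Package: clonotrace
Title: Clonality and Tissue-of-Origin Inference for Multifocal Tumors from
    Somatic Mutations and Copy-Number Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to decide whether synchronous multifocal tumor lesions are
    clonally related from their shared somatic mutations and copy-number
    variants (CNVs), and to assign a tissue of origin to new lesions. Somatic
    calls are filtered by coverage, supporting-read, dbSNP and germline rules;
    shared events between lesions are counted with exact gene/coordinate and
    identical-interval matching, summarized as Venn decompositions, and used
    to order lesions along a putative metastatic route. Segmented copy-number
    profiles from a labelled multi-cancer cohort are aligned into disjoint
    regions to form a region-by-sample matrix; cancer-type-specific signature
    regions are selected by per-region one-vs-rest logistic regression with
    likelihood-ratio p-values (Firth-penalized under separation); and lesions
    are classified with a diagonal-covariance Gaussian discriminant model with
    stratified cross-validated accuracy reporting. A synthetic-cohort module
    generates labelled CNV cohorts and clonally structured multi-lesion
    patients with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
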