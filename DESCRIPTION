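Package: bulkdecon
Title: Cell-Type Deconvolution of Heterogeneous-Tissue Bulk Transcriptomes
Version: 0.1.0
Authors@R:
    person("bulkdecon", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for reference-based deconvolution of bulk
    expression profiles from heterogeneous tissue. Builds a signature gene
    matrix from a labeled single-cell reference (logFC / logCPM / SecondFC
    marker selection with a correlation-inflection rule for the SecondFC
    threshold), estimates cell-type proportions with several solvers
    (OLS, NNLS, robust regression, linear nu-SVR, dampened weighted least
    squares), and evaluates them against known mixtures (PCC_P, PCC_T1/T2,
    marker-fraction scans, average-rank stability). Downstream stages impute
    per-sample cell-type-level expression, score rank-based pathway activity
    (area under the gene-set recovery curve), train a linear SVM classifier,
    discover sample subtypes by NMF consensus clustering with cophenetic
    rank selection, and test cluster-clinical associations. A synthetic-data
    module generates single-cell references, pseudo-bulk mixtures with known
    proportions, and full case/control cohorts with planted subtype and
    clinical structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
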