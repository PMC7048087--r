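Package: ctdnalite
Title: Multi-Assay Circulating Tumor DNA Detection at Desk Scale
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tested implementations of the untargeted and targeted assays
    used to detect circulating tumor DNA (ctDNA) in low-burden cancers such
    as renal cell carcinoma: trimmed median absolute deviation (tMAD)
    copy-number deviation scoring from shallow whole-genome sequencing with
    GC/mappability correction and in-silico fragment size selection,
    chromosome-arm aneuploidy z-scores against a healthy control cohort, a
    grid-search tumor-fraction estimator with a frequent-SCNA rescue rule,
    patient-specific targeted mutation detection with UMI consensus error
    suppression and aggregate-likelihood calling, variant post-filters
    (population allele frequency, normal-adjacent tissue, FFPE sequence
    context, replicate concordance), fragmentomics features with a random
    forest triage model, and multi-region tumor heterogeneity representation
    analysis. A seeded synthetic cell-free DNA fragment generator provides
    the statistical structure these assays assume, so the whole pipeline is
    testable without access to patient sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    jsonlite,
    methods,
    rtracklayer,
    randomForest,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
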