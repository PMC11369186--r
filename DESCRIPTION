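Package: readmeld
Title: Read-Level DNA Methylation Deconvolution for Tumor Fraction
    Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers tumor-specific differentially methylated regions at
    single-read resolution (pDMRs) from bisulfite sequencing data, trains a
    per-read classifier on joint DNA-sequence and methylation-state
    encodings of reads within those regions, and scores samples by the
    estimated fraction of tumor-derived reads. Includes Youden-index cutoff
    selection, ROC evaluation, depth-downsampling robustness analysis, and
    a built-in synthetic bisulfite-read simulator so the whole pipeline is
    exercisable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    Rsamtools,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
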