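Package: ahltools
Title: Screening and Genome Mining of Acyl-Homoserine Lactone Quorum-Sensing Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting N-acyl-homoserine lactone (AHL) autoinducers in
    triple-quadrupole LC-MS/MS product-ion data and for post-processing
    genome-mining searches for their synthase (LuxI) and receptor (LuxR)
    protein families. Implements the characteristic daughter-ion screen at
    m/z 102 with confirmation at m/z 56, 74 and 84, extracted-ion-chromatogram
    peak detection, medium-control comparison, a theoretical AHL mass
    library for structural annotation, and k-means feature clustering.
    The genome-mining track filters HMMER3 tblout and BLAST tabular hit
    tables, resolves multi-model hits, counts per-assembly homolog copies,
    deduplicates species by the largest synthase-by-receptor copy product,
    and summarises copy-number distributions. A synthetic-data module
    generates MS runs (mzML and MGF) and hit tables with planted ground
    truth so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    mzR,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
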