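Package: ksgtome
Title: Translatome Analysis of Kasugamycin Action in Escherichia coli
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes per-gene translational efficiencies and Kasugamycin
    effect values (KEVs) from polysome-fractionation expression data,
    classifies transcripts as Kasugamycin-sensitive or -resistant, analyses
    start-codon regions (relative-entropy structure logos, Shine-Dalgarno
    motif detection, leaderless transcript calls), and summarises annotation
    features (operon position, intergenic distance, 5'-UTR length) across
    sensitivity groups. A synthetic-data module generates measurement
    matrices, start-region sequences and annotation tables with known ground
    truth so the whole pipeline can be exercised and validated without
    external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    readr,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
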