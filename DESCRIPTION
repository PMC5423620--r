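Package: h4map
Title: Mapping Viral Histone H4 Joining Sites on a Host Insect Genome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-alignment analysis chain for locating the chromosomal
    joining sites of a bracoviral histone H4 on the genome of its
    lepidopteran host and for quantifying the viral gene's contribution to
    parasitism-induced transcriptional change. Provides differential
    ChIP-target screening (E-value filtering, nearest-gene annotation with
    signed distances, control subtraction, two-screen intersection into core
    targets), joining-site sequence characterization (AT content, short
    tandem repeat detection with rotation-canonical motif classes),
    upstream/gene-body/downstream locality analysis with neighborhood read
    profiles, physical mapping of targets onto linkage groups, signed
    fold-change DEG calling from FPKM tables with set overlap and
    contingency chi-square tests, and a fully seeded synthetic-data
    generator with ground-truth records for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    withr
Config/testthat/edition: 3
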