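Package: phosmine
Title: Genome Mining of Phosphonate Biosynthetic Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mining prokaryotic genomes for phosphonate
    biosynthetic gene clusters anchored on phosphoenolpyruvate mutase (Ppm).
    Parses HMMER per-domain hit tables and applies gathering-threshold and
    model-coverage filters, scans protein sequences for the Ppm catalytic
    motif (EDKXXXXXNS), deduplicates sequences and inventories Pfam domain
    fusion architectures, computes gene-index distances between ppm and the
    nearest nucleotidyltransferase gene, and dereplicates genome sets by
    trinucleotide DNA signatures. Also fits Michaelis-Menten and
    substrate-inhibition models to initial-rate enzyme kinetic data and
    derives specificity constants and substrate-preference ratios. A
    synthetic-genome generator with known ground truth makes every stage
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
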