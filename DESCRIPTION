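Package: panledger
Title: Pangenome Graph Accounting, Variant Classification, and Assembly Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for accounting sequence in path-covered pangenome graphs
    and their companion outputs. Parses GFA v1.1 graphs with P/W sample
    paths, computes node/edge/length summaries, and attributes graph
    sequence to assemblies by a reference-first, largest-remaining-
    contributor-next greedy procedure. Classifies sample-carried VCF
    alleles into insertion/deletion/indel/SNV classes by allele-length
    rules with configurable structural-variant thresholds, censuses
    non-reference MAF alignment blocks per assembly and by assembly
    multiplicity, and computes assembly summary statistics (N50/L50, GC,
    percent-of-assembly). A seeded synthetic-pangenome generator emits
    ground-truthed FASTA/GFA/VCF/MAF bundles for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
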