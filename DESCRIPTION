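Package: nahrmeth
Title: Germline Hypomethylation, Low-Copy Repeats, and Structural Mutability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links germline DNA hypomethylation to structural mutability of the
    genome. Builds fixed-width window methylomes from per-CpG bisulfite
    observations and calls methylation deserts; computes a CpG-transition-based
    germline methylation index from SNPs with ancestral alleles; detects
    low-copy repeats (segmental duplications) by gapped k-mer genome
    self-comparison and extracts directly-oriented paralogous LCR (DP-LCR)
    regions susceptible to non-allelic homologous recombination (NAHR);
    classifies copy-number variants by their relationship to LCR architecture;
    estimates per-locus structural heterozygosity (2pq) with pedigree-aware
    counting; and provides the Kolmogorov-Smirnov, size-matched permutation,
    enrichment, and relative/attributable risk machinery tying these layers
    together. Includes a synthetic-data generator that plants duplications,
    deserts, methylation-coupled SNPs, element sets, and CNV cohorts with known
    truth so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    tibble,
    readr,
    rlang,
    withr,
    ggplot2,
    generics,
    data.table,
    Biostrings,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
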