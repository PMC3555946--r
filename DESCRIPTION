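Package: isletmir
Title: Small RNA-Seq miRNA Profiling, Tissue Specificity and GWAS Target
    Enrichment for Pancreatic Islets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale re-implementation of a small RNA sequencing
    analysis chain for profiling microRNA expression in human pancreatic
    islets and FACS-enriched beta-cells: 3' adaptor clipping and read
    filtering, prioritised three-tier alignment (contaminants, miRNA
    hairpins with mature/star windows, other ncRNA, genome) with
    fractional 1/k multi-mapping counts, median-of-ratios count
    normalization, tissue-specificity scoring across a merged tissue
    panel with a permutation false-discovery rate, LD-proxy expansion
    and variant/interval overlap, and a percentile-cutoff permutation
    test for GWAS association enrichment in predicted miRNA target-gene
    sets with Storey robust q-values. A synthetic-data module generates
    every input the pipeline consumes so that all stages are testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    DESeq2,
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
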