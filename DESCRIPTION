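Package: geneweldr
Title: Short-Homology Knock-In Donor Design and Junction Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Design and in-silico validation of short-homology
    (homology-mediated end joining, HMEJ) knock-in experiments at CRISPR/Cas9
    and TALEN cut sites. Locates nuclease target sites and computes blunt
    double-strand-break coordinates, extracts 5'/3' homology arms directly
    flanking a cut, renders them as annealing-oligo pairs with Type IIS
    (BfuAI/BspQI) sticky ends, simulates one-pot Golden Gate assembly into
    pGTag-style donor vectors and in-vivo liberation of the cargo at
    universal-guide (UgRNA) sites, predicts the precisely integrated allele
    (including deletion tagging across two cut sites), classifies sequenced
    junction reads as precise or imprecise by pairwise alignment, and
    generates seeded synthetic fixtures. Emits oligo order sheets (TSV),
    annotated GenBank plasmid maps, and JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    BiocGenerics,
    GenomicRanges,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Collate:
    'seq-utils.R'
    'intervals.R'
    'guides.R'
    'coding.R'
    'enzymes.R'
    'vector.R'
    'arms.R'
    'assemble.R'
    'offtarget.R'
    'genbank.R'
    'alleles.R'
    'classify.R'
    'simulate.R'
    'cli.R'
    'geneweldr-package.R'
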