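Package: nlrcnv
Title: Copy Number Variation Analysis of Plant NLR Resistance Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing copy number variation (CNV) of
    nucleotide-binding leucine-rich repeat (NLR) resistance genes across
    multiple genome assemblies of a single species. Implements NLR
    identification and architecture classification (TNL/RNL/CNL/NL) from
    protein-domain evidence tables, duplicate-gene classification
    (singleton/dispersed/proximal/tandem/WGD-segmental) with
    dynamic-programming collinear block chaining, megabase-window NLR
    cluster detection, pseudogene identification by pseudoexon filtering
    and intron-length-quantile linking, and group-level CNV summary
    statistics. A synthetic multi-genotype generator with planted ground
    truth makes every pipeline stage testable without external genome
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
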