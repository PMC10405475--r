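Package: viropop
Title: Viral Community and Population Genetics from Metagenomic Read Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream viromics inference from assembled contigs and read
    alignments: combining viral-detector scores into viral calls, greedy
    species-level vOTU clustering by average nucleotide identity, per-base
    coverage and per-gigabase abundance profiling, hypervariable-region
    (genomic island) detection, metatranscriptomic activity calling,
    community macrodiversity (Shannon, shared and unique vOTUs, rank
    abundance, rarefaction), and intra-population microdiversity (SNP
    calling, nucleotide diversity, SNP density, Nei-Gojobori pN/pS with
    positive-selection calls). Includes a synthetic-community generator
    with full ground truth so every stage is verifiable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    IRanges,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    seqinr
Config/testthat/edition: 3
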