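Package: plastmarker
Title: Comparative Plastome Analysis and PCR-Based Species Authentication Markers
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of complete chloroplast genomes for species
    authentication. Detects the quadripartite plastome structure (LSC/IRb/SSC/IRa)
    and summarizes structural statistics; extracts SNP and InDel events from a
    whole-genome multiple alignment with per-taxon alleles and projected genome
    coordinates; computes pairwise and species-specific variant tallies and
    sliding-window variability profiles; classifies SNP effects against annotated
    genes (including premature-stop pseudogene calls) and scans microsatellites
    (SSRs); designs co-dominant InDel markers and dominant allele-specific (ARMS)
    SNP markers with nearest-neighbor melting temperatures; validates markers by
    in-silico PCR banding and species calling; and builds Kimura two-parameter
    neighbor-joining trees with bootstrap support. A truth-tracked synthetic
    plastome generator makes the whole pipeline testable without any external
    data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    IRanges,
    ape,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
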