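Package: inilcurate
Title: Transposon Mining, Repeat Cataloguing and Map-Guided Curation for
    Plant Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale genome-curation toolkit modelled on the assembly
    finishing of the Japanese morning glory (Ipomoea nil) genome. Mines
    CACTA/Tpn1-family transposons from terminal inverted repeats (TIRs),
    target-site duplications (TSDs) and sub-terminal repetitive regions
    (SRRs); catalogues telomeric, centromeric and rDNA tandem arrays;
    detects and splits chimeric scaffolds against a genetic linkage map;
    builds pseudo-chromosomes with AGP output; computes assembly QC
    statistics (N50 family, BAC-end pairing, EST coverage); and forges
    seeded synthetic genomes with machine-readable truth tables so every
    stage is testable without the deposited data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
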