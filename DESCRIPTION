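Package: ribopause
Title: Codon-Level Ribosome Pausing and Transcriptional Attenuation from
    Ribosome Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Codon-resolution analysis of bacterial ribosome profiling and
    RNA-seq data. Assigns ribosome positions from footprint 3' ends, builds
    strand-aware per-nucleotide density tracks (raw or reads-per-million),
    computes A-site pause scores for the 61 sense codons with gene-level
    filtering and edge trimming, produces codon-aligned metagene occupancy
    profiles with peak calling, quantifies gene expression (RPKM) and
    ribosome occupancy, measures leader-to-downstream transcriptional
    attenuation ratios, and compares expression shifts between gene sets.
    Includes a seeded generative model of footprint and RNA-seq data with
    per-codon dwell-time enrichment, run-on blurring, ribosome-collision
    stacking, and attenuation read-through, with presets emulating
    tRNA-methyltransferase depletion strains.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
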