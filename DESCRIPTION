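Package: circLigate
Title: Joint Quantification of Linear and Circular RNA Splice Junctions
    from Ligation-Probe Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for targeted, ligation-probe based profiling of linear
    splicing and backsplicing. Probes hybridised at exon boundaries are
    ligated across splice junctions, tagged with unique molecular
    identifiers (UMIs) and sequenced; the probe order distinguishes linear
    (mRNA) from circular (circRNA) junctions. The package defines and
    validates probe-panel designs, simulates assay reads with ground
    truth, demultiplexes and matches reads to probe pairs, collapses PCR
    duplicates by UMI, classifies junctions, computes circRNA/mRNA ratios
    and relative proportions, flags allelic imbalance and genomic DNA
    contamination, renders schematic splicing profiles as SVG, and
    compares ratios between sample groups.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
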