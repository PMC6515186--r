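Package: aptastruct
Title: Secondary Structure Element Analysis of Single-Stranded DNA Aptamer Pools
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing predicted self-hybridized secondary structures
    across pools of single-stranded DNA aptamer candidates and random-sequence
    backgrounds. Folded structures are decomposed into seven secondary structure
    elements (single-stranded segment, hairpin stem, hairpin loop, internal
    loop, bulge, duplex, multi-branched loop), grouped into secondary structure
    families by element counts, scored per base position against a smoothed
    random background with a position-specific score matrix, globally aligned
    over the seven-letter structural alphabet with a progressive aligner, and
    segmented into consensus domains whose positional statistics are computed
    after gap removal. Includes a seedable library simulator for the
    fixed-flank screening design, a maximum-pairing baseline folder, an adapter
    for external thermodynamic folding engines, and parsers for connectivity
    table, dot-bracket and Clustal formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
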