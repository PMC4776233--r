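Package: bbcscreen
Title: Bead-Based Cleavage Screening for Protease Substrates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for bead-based cleavage (BBC) degradomics screens, in
    which a proteome is immobilized on beads, incubated with a protease
    (the reference application is caspase-3), and the released fragments
    are trypsin-digested and quantified by heavy/light isotope ratios.
    Provides an end-to-end simulator of the experiment with planted
    substrates and ground truth, readers and writers for the quantified
    peptide table and reference accession lists, dual-threshold substrate
    calling (log2 ratio and supporting-peptide count) with hot/warm
    tiering, cleavage-site extraction from semi-tryptic peptide termini
    with enzyme classification and DXXD caspase-motif analysis, position
    frequency matrices for sequence logos, and set-overlap statistics
    against known-substrate and in vivo degradome reference lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
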