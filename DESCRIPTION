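Package: activeTE
Title: Detection and Dating of Active, Horizontally Transferred DNA Transposons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An inference pipeline for identifying currently active DNA
    transposons and testing whether they arrived by horizontal transfer.
    Provides germline-expression triage of transposable-element (TE)
    transcripts against a single-copy reference gene set, consensus
    reconstruction and element anatomy (ORFs, terminal inverted repeats,
    mariner DD34D/YSPDLAP motifs), copy-number and nucleotide-diversity
    statistics, Nei-Gojobori (NG86) synonymous-divergence estimation with a
    codon-based Z-test, Games-Howell contrasts of TE versus nuclear-gene Ks,
    neighbor-joining phylogenies with Robinson-Foulds incongruence testing,
    neutral-rate calibration and insertion-time dating (T = k/2r) with burst
    profiling, and identity-by-descent aware calling of non-reference TE
    insertions from junction reads.  A forward simulator of TE life cycles
    (host species tree, horizontal entry, master-element proliferation,
    brother-pair genomes with IBD blocks) generates every input the pipeline
    consumes, with ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
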