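Package: selpep
Title: Selective Peptide Ranking for Phage Display Deep Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-part analysis of phage display biopanning screens sequenced
    on short-read amplicon platforms. Part one extracts the randomized peptide
    insert from demultiplexed FASTQ reads using the display library's flanking
    signatures, applies the library's degenerate-codon constraint (e.g. NNK
    with amber read-through), translates, and tabulates per-screen peptide
    frequencies with full read accounting. Part two normalizes each screen to
    its read depth and to an amplified unselected reference library, imputes
    absent values by the screen's non-zero mode, and ranks peptides by the
    ratio of mean normalized frequency across positive screens to negative
    screens, so that target-selective clones distil to the top of a comparison
    matrix while parasitic fast-amplifiers cancel out. A synthetic-screen
    simulator with skewed naive pools, selective spikes, parasitic clones and
    sequencing error supports end-to-end testing without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pheatmap,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
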