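Package: kmerphylo
Title: Alignment-Free Phylogenetics from 8-mer Spectrum Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds phylogenetic trees from whole-genome k-mer spectra
    without sequence alignment. Genomes are summarised by their 8-mer
    occurrence counts; the 65,536 8-mers are partitioned into motif-defined
    subsets (zero / one / two-or-more overlapping occurrences of a
    dinucleotide or trinucleotide), from which two complementary feature
    sets are extracted: 186 class-level features (93 separability and 93
    conservatism log-ratios over CpG-anchored subsets) and 65,536
    order-level features (the frequency rank of every 8-mer). Two
    evolutionary distances over these features feed a native
    neighbor-joining tree builder with Newick output. A Markov-chain genome
    simulator with tunable dinucleotide (notably CpG) transition biases
    supports testing and method exploration without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
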