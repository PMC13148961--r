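Package: peptax
Title: Peptide-to-Protein and Taxon Assignment with Interleaved Bloom Filter Indexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Indexes protein reference databases as partitioned interleaved
    Bloom filters over amino-acid k-mers and classifies de novo peptide
    sequences by approximate membership counting. Supports error-tolerant
    matching through BLOSUM62-guided k-mer variant expansion at index build
    time, optional forward-strand minimizer sketching, multi-index
    partitioning of large databases with reference blacklisting, and a
    thresholded per-bin assignment score for taxonomic or protein-level
    classification of peptide lists. Includes a seeded synthetic fixture
    generator (reference proteomes, tryptic digestion, noisy query peptides)
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
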