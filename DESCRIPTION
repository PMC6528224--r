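Package: sigmotif
Title: Translating Mutational Signatures into Transcription Factor
    Motif Alteration Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the probability that single-nucleotide mutations
    create or disrupt transcription factor binding motifs, and projects
    trinucleotide mutational signatures (COSMIC 96-class convention)
    through these probabilities into per-signature and per-patient motif
    alteration signatures.  Includes exact position-weight-matrix score
    p-values by dynamic programming, k-mer space enumeration with
    reverse-complement canonicalization, a per-SNV motif creation and
    disruption caller with a local second-order Markov background, summary
    statistics (absolute relative difference, motif entropy,
    creation-disruption correlation), and a synthetic-data generator for
    genomes, motifs, signatures, exposures and signature-driven SNVs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
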