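Package: starpick
Title: Two-Step Thermodynamic Prediction of Bacterial Small RNA Targets
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-wide and single-pair prediction of bacterial small
    regulatory RNA (sRNA) targets with a two-step hybridization model.
    Candidate seed helices between an sRNA and the region around an mRNA
    start codon are screened by length/composition rules and by an
    accessibility-corrected interaction energy (hybridization energy plus
    the cost of opening intra-molecular structure in both molecules).
    Surviving seeds are extended into full binding sites by constrained
    co-folding, each site is described by 22 structural and energetic
    features, and an ensemble of 1000 decision-tree classifiers trained by
    forward feature selection with stability analysis votes to produce an
    interaction probability per sRNA-mRNA pair. Folding energetics are
    computed through a pluggable engine contract with an adapter to the
    ViennaRNA command-line suite and a self-contained deterministic toy
    nearest-neighbour engine for fully offline computation and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse,
    withr
Config/testthat/edition: 3
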