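Package: fmhdnds
Title: Alignment-Free dN/dS Estimation from FracMinHash Containment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the ratio of non-synonymous to synonymous substitution
    rates (dN/dS) between protein-coding sequences without alignment, using
    debiased FracMinHash containment indices of DNA and protein k-mer
    sketches. Provides scaled MurmurHash3-based sketching, containment and
    multisearch comparisons, the closed-form containment-to-dN/dS estimator,
    a Nei-Gojobori (1986) counting implementation with Jukes-Cantor
    correction for ground-truth comparison, and a codon-position-targeted
    mutation simulator for benchmarking selection inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr
Config/testthat/edition: 3
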