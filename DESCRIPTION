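Package: splitscape
Title: Tree-Space Comparison of Alignment Strategies via Bipartition
    Support Analysis
Version: 1.0.0
Authors@R:
    person("Splitscape", "Developers", email = "splitscape@example.org",
           role = c("aut", "cre"))
Description: Compares sets of phylogenetic trees produced under different
    multiple-sequence-alignment and masking strategies. Trees with
    branch-support labels (ultrafast-bootstrap percentages or Bayesian
    posterior probabilities) are represented as vectors of bipartition
    supports, optionally reduced to backbone splits expressing only the
    interrelationships of predefined taxon groups, and compared by
    principal component analysis with per-variable contributions and a
    per-strategy dispersion (stability) score. The package also provides
    the alignment-thinning generators that produce such tree series
    (gap/block masking, confidence-score threshold series, stepwise
    removal of fastest-rate sites), an RNA helix analyzer (dot-bracket
    loop classification, bulge signatures, Fitch parsimony transition
    counts), a synthetic-data module that makes the whole pipeline
    exercisable without external data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
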