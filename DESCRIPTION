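Package: quartetHMM
Title: Crossover Detection in Family Quartets with a Transmission-State
    Hidden Markov Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects meiotic crossovers from SNP genotypes of nuclear-family
    quartets (father, mother, two children). A four-state hidden Markov model
    over parental transmission modes is decoded with the Viterbi algorithm,
    and each state change is delimited by a deterministic scan yielding a
    crossover prediction interval; a two-state maternal model handles the X
    chromosome. Includes PLINK text-format input with marker quality-control
    filters, a haplotype-panel simulator with known crossover truth for
    validation, quintet/triple cross-quartet consistency reconciliation,
    sex-specific genetic-map construction, historical-hotspot concordance
    analysis with a chance-overlap discount, and maternal-age regression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    IRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
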