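Package: paleoshift
Title: Diversification-Rate Shifts, Origination and Extinction in Fossil Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects diversification-rate shifts in time-calibrated fossil
    phylogenies from tree imbalance under an equal-rates Markov null, and
    relates them to origination and extinction rates estimated from the same
    trees. Provides stratigraphic time-calibration with minimum branch
    durations, per-node Delta1/Delta2 shift statistics with Monte-Carlo
    p-values, substage time slicing, phylogenetic diversity estimates with
    ghost-lineage sampling corrections, two-state Markov ancestral-state
    reconstruction for ecological traits, generalised-least-squares and
    random-forest model comparison of the shift series against rate series,
    and a fossil birth-death scenario generator with incomplete sampling for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    nlme,
    randomForest,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    phytools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
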