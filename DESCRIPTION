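Package: discordtime
Title: Divergence-Time Estimation Under Gene-Tree Discordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and inference tools for studying how topological
    incongruence between gene trees and the species tree biases estimates of
    branch-wise substitution counts, divergence times, and substitution rates.
    Provides fixed-topology and multispecies-coalescent gene-tree simulators,
    Jukes-Cantor sequence simulation, a fast pruning likelihood with
    maximum-likelihood strict-clock dating, unrooted branch-length and
    fixed-time rate estimation, per-branch congruence and equivalent-branch
    identification, locus filtering, and replicated experiment drivers that
    summarise percentage errors by branch class.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
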