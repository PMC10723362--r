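Package: wolclock
Title: Calibrated Chronograms, Tree Distances and Structure-Mapped
    Selection Analyses for Wolbachia Comparative Genomics
Version: 0.1.0
Authors@R:
    person("Wolclock", "Developers", email = "wolclock@example.org",
           role = c("aut", "cre"))
Description: Tools for time-calibrating endosymbiont phylogenies from
    examples of host-symbiont co-divergence: Jukes-Cantor third-position
    and Nei-Gojobori synonymous divergence from codon alignments,
    cladogenic substitution-rate estimation with credible intervals,
    mixture rate priors, and scaling of relative chronogram posteriors to
    absolute time.  Also provides split-based tree distances
    (Robinson-Foulds, Jaccard-Robinson-Foulds, clustering information)
    with random-tree normalization and permutation tests, spherical
    sliding-window dN/dS mapped onto protein structures with BCa
    bootstrap and rank-based group statistics, Kabsch superposition with
    TM-scores, hatch-rate incompatibility tests, and seeded simulators
    for every input format so all analyses run offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
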