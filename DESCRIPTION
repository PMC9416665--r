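Package: memprop
Title: Residue-Specific Membrane-Association Propensities of Disordered
    Protein Regions
Version: 1.0.0
Authors@R:
    person("memprop", "maintainers", email = "memprop@example.org",
           role = c("aut", "cre"))
Description: Predicts per-residue propensities of intrinsically disordered
    protein regions (IDRs) to associate with acidic membranes, from sequence
    alone. The score is a sequence-based partition function: every residue
    contributes a multiplicative, distance-attenuated Boltzmann factor whose
    amplitude depends on its charge class (K/R positive, D/E negative, all
    else neutral, with terminal pseudo-charges). Includes a sigmoid map from
    side-chain tip heights to contact probabilities, a moving-average-charge
    baseline with a linear-regression comparator, nonlinear fitting of the
    three amplitude parameters with per-protein scale factors and grouped
    leave-one-out analysis, a synthetic IDR/profile generator, FASTA/TSV
    input-output, an amide chemical-shift-perturbation utility, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
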