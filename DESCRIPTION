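Package: ampsynergy
Title: Pharmacodynamics and Loewe Synergy Analysis of Antimicrobial
    Peptide Combinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing time-kill experiments of antimicrobial
    peptides (AMPs) applied singly and in fixed-ratio two- and three-way
    mixtures. Net bacterial growth rates are estimated from log-transformed
    CFU time series, a four-parameter Hill pharmacodynamic model
    (psi_max, psi_min, kappa, zMIC) is fitted by weighted least squares and
    by an adaptive Markov chain Monte Carlo sampler, and drug interactions
    are quantified with Loewe combination indices profiled across the
    5-95% effect range, with posterior uncertainty propagation and
    synergy/additivity/antagonism calls. A synthetic-data generator with
    known ground-truth pharmacodynamics and a tunable interaction factor
    reproduces the serial-dilution kill-curve design (2-fold series from
    100x MIC, 20-min sampling, plating detection limit) so the full
    pipeline can be validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ampsynergy-package.R'
    'pdmodel.R'
    'mcmc.R'
    'combination.R'
    'killrates.R'
    'synthdata.R'
    'utils.R'
    'workflow.R'
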