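Package: aurokin
Title: Proteoform Mass Reconciliation and Enzyme Kinetics for Plant
    Polyphenol Oxidases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the intact-mass characterization and enzymology of
    latent and active plant polyphenol oxidases such as aurone synthase.
    Provides exact peptide and protein mass arithmetic on monoisotopic and
    average scales with disulfide/thioether crosslink and modification
    bookkeeping, charge deconvolution of multiply protonated electrospray
    envelopes, enumeration and tolerance matching of proteoform hypotheses
    (ragged C-termini, attached C-terminal peptides, phosphorylation or
    sulfation, oxidations), in-silico tryptic digestion with sequence-coverage
    arithmetic, kinetic model fitting (Michaelis-Menten, pseudo-first-order
    efficiency, suicide-inactivation progress curves, threshold-triggered
    allosteric activation of the latent pro-enzyme), and seeded synthetic-data
    generators emulating the corresponding instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
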