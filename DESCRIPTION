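Package: orgtill
Title: In Silico EcoTILLING of Organelle Genes
Version: 0.1.0
Authors@R: person("orgtill", "developers", role = c("aut", "cre"),
    email = "orgtill@example.org")
Description: Tools for mismatch-cleavage (CEL I / EcoTILLING) mutation
    scanning of chloroplast and mitochondrial genes in silico: enumeration
    of polymorphisms between haplotypes, virtual heteroduplex cleavage into
    dual-channel (IRD700/IRD800) gel band patterns under an explicit
    detection model, recovery of mutation positions from observed band
    sizes by the fragment-additivity constraint, detection-rate and
    mutation-frequency statistics, Kimura two-parameter distances with
    neighbour-joining trees and bootstrap supports, and a seeded synthetic
    cohort generator so the whole pipeline is testable without wet-lab
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
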