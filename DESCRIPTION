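Package: plastidkit
Title: Comparative Plastome Analysis and Phylogenetic Marker Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated chloroplast genomes
    and for ranking candidate phylogenetic markers against whole-plastome
    trees. Reads and writes GenBank flat files and FASTA, detects the
    quadripartite LSC/IRb/SSC/IRa structure from the raw circular sequence,
    reports inverted-repeat junction shifts across accessions, computes
    sliding-window nucleotide diversity and identity profiles, profiles
    Townsend phylogenetic informativeness from per-site substitution rates,
    infers maximum-likelihood trees under GTR+Gamma with bootstrap
    consensus, and scores per-locus trees against a reference tree with
    plain and generalized (clustering-information) Robinson-Foulds
    distances. A plastome simulator with known species tree, per-locus
    rates, indels, and IR junction events makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape (>= 5.0),
    phangorn,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
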