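Package: nifphylo
Title: Minimal Nif Gene-Set Screening and Nitrogenase Phylogenetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens prokaryotic genome annotations for the minimal
    six-gene nitrogenase complement (NifHDKENB) with genomic-neighborhood
    resolution of paralogs and length-based detection of NifEN/NifNB gene
    fusions; builds per-gene and concatenated protein phylogenies with a
    built-in progressive aligner, Kimura-corrected distances and
    neighbor joining; combines gene trees by majority-rule consensus and
    quartet-score supertree search; and flags horizontal gene transfer
    candidates from gene-tree/species-tree discordance by greedy
    Robinson-Foulds leaf pruning. Includes a fully seeded synthetic-data
    generator (Yule species trees, SPR transfer events, Poisson protein
    evolution, planted operon fixtures) so every stage can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    Rcpp,
    tibble,
    dplyr,
    rlang,
    readr,
    jsonlite,
    withr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
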