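Package: mmphylo
Title: Curation, Phylogeny and Clade-Based Reannotation of Matrix
    Metalloproteinase Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for large protein-family phylogenetics,
    built around the mammalian matrix metalloproteinases (MMPs). Provides a
    three-step sequence curation cascade (length window, conserved-domain
    architecture, exact-duplicate removal) with per-stage statistics, a
    neighbor-joining baseline tree with outgroup rooting (externally computed
    trees are accepted wherever a tree is consumed), an automatic clade-vote
    rule that formalizes phylogeny-guided class (re)annotation, and a
    patristic-distance criterion that ranks candidate model organisms by
    evolutionary proximity to a reference species within each MMP class. A
    fully seeded simulator of class-structured gene families with injected
    corruptions (fragments, duplicates, mislabels, generic labels) provides
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
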