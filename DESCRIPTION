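Package: phyloforge
Title: Collection-Aware Phylogenetic Tree Comparison, Supertrees and Project Management
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale engine for comparative phylogenetics: an ordered, annotated
    tree model with exact Newick round-tripping; collection-aware tree edition
    (multi-level outgroup rerooting, subtree swaps, restriction to common taxa,
    coordinated renaming and coloring); pairwise comparison via Robinson-Foulds
    bipartition distance, rooted maximum agreement subtrees with per-leaf agreement
    classification, and tanglegram tip-order harmonization; matrix representation
    with parsimony (MRP) supertree inference with Fitch parsimony scoring under
    missing data and exhaustive branch-and-bound or heuristic tree search; a
    file-backed project store with collections, members, privacy, import limits,
    timeline, backups and a single-writer control token; and minimal SVG export
    honoring agreement shading. A command-line interface binds all components.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    phangorn,
    xml2,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
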