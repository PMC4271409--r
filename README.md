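# phyloforge

**phyloforge** is a desk-scale R engine for *comparative phylogenetics*: the
cluster of tasks a systematist performs when several evolutionary trees —
gene trees against a species tree, host against parasite trees, trees from
competing inference runs — must be edited into comparable form, compared
quantitatively, and summarized into consensus or supertrees, all while the
underlying tree collections are managed as a shared project. It is written
for evolutionary biologists and tool builders who want those operations as
composable library functions and a thin command-line interface rather than a
web application.

## What it computes

* **An ordered, annotated tree model with exact Newick round-tripping.**
  Child order is part of the model (it is the displayed tip order), internal
  numeric labels are read as support values, and `parse_newick()` /
  `write_newick()` are exact inverses on topology, labels, branch lengths,
  supports and child order.
* **Collection-aware tree edition**: restriction to common taxa
  (`restrict_to_taxa()`, `common_taxa()`), multi-level outgroup rerooting
  (`reroot_outgroup()`, `reroot_collection()`) that scans outgroup levels
  outermost-first and preserves the unrooted bipartition set, subtree swaps
  at an MRCA (`manual_swap()`), and coordinated renaming and coloring across
  trees (`rename_taxa()`, `set_color()`).
* **Robinson–Foulds distance** (`rf_distance()`): both trees are restricted
  to their common taxa, and the distance is the size of the symmetric
  difference of their nontrivial unrooted bipartition sets,
  `RF(T1, T2) = |Σ(T1) Δ Σ(T2)|`, reported as the full symmetric-difference
  count together with the common-taxon count.
* **Rooted maximum agreement subtrees** (`mast()`): a dynamic program over
  node pairs computes a maximum-cardinality taxon set `S` on which the two
  rooted trees induce isomorphic subtrees, with multifurcations handled by
  maximum-weight matching of child subproblems and deterministic
  (lexicographically smallest) tie-breaking. Every leaf is classified as
  `in_consensus`, `conflicting`, or `tree_specific` — the classification
  that drives grey-shading in the SVG export.
* **Tanglegram untangling** (`auto_swap()`, `crossing_count()`): an
  alternating barycenter heuristic reorders children so tips appear in the
  same order as far as possible; the crossing count (inversions between the
  two tip orders over common taxa) never increases.
* **MRP supertrees** (`mrp_matrix()`, `mp_search()`, `mrp_supertree()`):
  Baum–Ragan coding turns every clade of every rooted source tree into a
  binary character (members 1, other taxa of that source 0, absent taxa `?`)
  over the union of taxa plus a synthetic all-zero outgroup; Fitch parsimony
  with missing data scores candidate topologies (`fitch_length()`,
  `matrix_parsimony_score()`); search is exhaustive with branch-and-bound up
  to a configurable taxon threshold (returning *all* most-parsimonious
  trees) and seeded random-addition + NNI hill climbing beyond it; the
  strict consensus of the MP trees (`strict_consensus()`) is rooted on the
  synthetic outgroup and returned.
* **A file-backed project store** reproducing single-writer collaboration
  semantics: two named collections per project, members and privacy status,
  import limits enforced atomically (10,000 trees and 5,000 distinct taxa
  per project, 1,000 trees per import), an append-only timeline, named
  backups with exact restore, and a control token such that at most one
  member can mutate shared state at any moment (`create_project()`,
  `import_trees()`, `request_control()`, `resolve_request()`,
  `take_control()`, `check_access()`, `backup()`, `restore()`,
  `save_project()`, `load_project()`).
* **Minimal SVG export** (`render_svg()`, `render_pair()`): rectangular
  phylograms, side-by-side or face-to-face (mirrored) pairs, honoring color
  annotations and agreement shading; output is deterministic, well-formed
  SVG 1.1.
* **A fixture generator** (`random_trees()`, `split_cover_subtrees()`)
  producing uniformly random rooted binary topologies and split-covering
  induced subtrees for supertree experiments.

## Worked example

```r
library(phyloforge)

gene <- parse_newick("((((human,chimp),gorilla),orang),((mouse,rat),dog));")
spc  <- parse_newick("(((human,(gorilla,chimp)),orang),((mouse,dog),(rat,cat)));")

rf_distance(gene, spc)
#> Robinson-Foulds distance: 4 (over 7 common taxa)

mast(gene, spc)
#> Maximum agreement subtree: 5 taxa
#>   chimp, dog, gorilla, mouse, orang
#> tree 1: 5 in consensus, 2 conflicting, 0 tree-specific
#> tree 2: 5 in consensus, 2 conflicting, 1 tree-specific

write_newick(mrp_supertree(list(gene, spc)))
#> [1] "(((cat,rat),dog,mouse),((chimp,gorilla,human),orang));"

auto_swap(gene, spc)$layout
#> tanglegram layout: 0 crossings over 7 common taxa
```

Reading the output: the two trees share 7 taxa and disagree on 4 of their
restricted bipartitions (2 per tree). The largest taxon set on which they
agree exactly has 5 members; `human` and `rat` are placed incompatibly
(`conflicting`), and `cat`, present in only one tree, is `tree_specific` —
both classes would be shaded grey by `render_pair()`. The MRP supertree
keeps the structure the trees agree on and collapses the conflicting parts
into multifurcations, and the tanglegram layout after `auto_swap()` has no
crossings.

The same operations are available from a shell via the wrapper in
`inst/cli/phyloforge` (subcommands `rf`, `mast`, `autoswap`, `reroot`,
`restrict`, `rename`, `color`, `mrp`, `consensus`, `render`, `fixtures`,
`project …`; exit codes 0/1/2 for success/domain error/usage error).

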