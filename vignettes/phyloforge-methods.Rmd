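---
title: "Methods and design choices in phyloforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in phyloforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloforge)
```

phyloforge bundles the computations behind comparative tree work: edition of
tree collections into comparable form, pairwise comparison, supertree
inference, and a file-backed project store with single-writer collaboration
semantics. This vignette explains the models and procedures, the parameters
that matter, and the choices made where the design was genuinely open.

## The tree model and the Newick dialect

A tree is a rooted, *ordered* structure: every node carries an ordered list
of children, and that order is meaningful — it is the tip order a drawing
displays, the object `manual_swap()` and `auto_swap()` manipulate. Nodes
carry an optional non-negative branch length to their parent, an optional
support value, and (on leaves) a free-form annotation map used for colors.
Leaf labels must be unique and non-empty; internal nodes always have at
least two children (unary nodes arising from pruning are suppressed).

The Newick dialect follows the most common interchange behavior among tree
tools: single quotes delimit labels containing specials (with `''` escaping
a quote), underscores pass through verbatim rather than becoming spaces, and
an internal-node label that is fully numeric is stored as a support value
while any other internal label is a name. `write_newick()` is an exact
inverse of `parse_newick()`: branch lengths are re-emitted through a
shortest-exact decimal representation with a `%.17g` fallback, so the
round trip preserves every double bit-for-bit. Annotations are not part of
Newick; they persist through a CSV sidecar (`taxon,key,value`).

## Edition semantics

**Restriction.** `restrict_to_taxa()` returns the induced subtree: pruned
leaves removed, unary nodes suppressed with their branch lengths summed. A
sum involving an absent length is absent — inventing a number where the
input had none would silently fabricate data. Restriction preserves every
rooted triplet among surviving taxa; the test suite checks this
exhaustively on random trees.

**Rerooting.** `reroot_outgroup()` takes a multi-level outgroup: levels are
scanned outermost-first and the first level with at least one representative
in the tree becomes the active outgroup, which accommodates tree sets where
the preferred outgroup taxon is missing from some trees. The tree is
rerooted on the edge separating the MRCA of the representatives from the
rest. Three conventions are ours where the behavior was open:

* the split edge's length is divided *equally* between the two new root
  children (the least informative choice; absent lengths stay absent);
* a non-monophyletic outgroup reroots on the edge above its MRCA anyway,
  with a `non-monophyletic outgroup` warning — gene trees frequently fail
  outgroup monophyly and a hard failure would make joint rerooting of a
  collection useless;
* when no level has a representative the tree is returned unchanged with a
  warning, and `reroot_collection()` aggregates such outcomes into a
  per-tree report instead of aborting — collection-level edits are
  best-effort across heterogeneous trees, never partial-failure aborts.

Rerooting never changes the unrooted bipartition set (RF distance between
input and output is 0), which the suite verifies against an independent
split enumeration.

**Coloring.** `set_color()` annotates leaves. When a whole subtree is
selected, the leaves below it are annotated; the renderer independently
greys the internal edges of subtrees whose every leaf is outside a
consensus, so "subtree coloring" is recovered at drawing time.

## Comparison

**Robinson–Foulds.** `rf_distance()` first restricts both trees to their
common taxa, as is standard when leaf sets differ, then counts the symmetric
difference of the nontrivial *unrooted* bipartition sets. Two conventions
are worth stating: the distance is unrooted (the convention of the classic
`treedist`-style tools this reproduces), and the *full* symmetric-difference
count is reported, not its half. The common-taxon count is returned
alongside so that distances over different overlaps are not confused.
Bipartitions are stored canonically as the side not containing the
lexicographically smallest taxon, which makes set operations on splits
well-defined.

**Rooted MAST.** `mast()` computes a maximum agreement subtree of two
*rooted* trees — the display model is rooted, and a rooted agreement is what
grey-shading two drawn trees requires. The dynamic program fills a table
over node pairs `(u, v)`: a leaf matches a subtree containing its label;
for two internal nodes the best of (descend into a child of `v`, descend
into a child of `u`, match children of `u` against children of `v`) is
taken, with the matching solved exactly by a bitmask dynamic program over
the smaller child list (children lists are small in practice, so the
`O(m·2^k·k)` assignment is negligible and handles multifurcations
correctly). Agreement sets can tie; rather than choosing one at random, the
default tie-break prefers the lexicographically smallest taxon set under a
fixed evaluation order, so results are reproducible, and
`tie_break = "random"` with a seed samples ties when randomization is
wanted. The per-leaf classification (`in_consensus` / `conflicting` /
`tree_specific`) always partitions each tree's leaf set — `conflicting`
means present in both trees but outside the agreement set, `tree_specific`
means absent from the other tree.

**Tip-order harmonization.** The objective of `auto_swap()` is the number of
pairwise inversions between the two tip orders restricted to common taxa,
which equals the crossing count of a straight-connector tanglegram. The
heuristic is the standard barycenter method for crossing reduction:
holding one tree fixed, every internal node of the other sorts its children
by the mean rank of their common leaves in the fixed order (children with no
common leaves keep their relative order after the others; ties break by
smallest leaf label), and the roles alternate up to `max_rounds` times
(default 10) or until a fixpoint. Because barycenter passes are not
individually monotone, the implementation tracks the best configuration
seen — including the input — and returns that, which guarantees the
crossing count never increases. Only child orders change, never topology,
and the procedure is deterministic.

## MRP supertrees

**Coding.** `mrp_matrix()` implements Baum–Ragan coding on *rooted* source
trees: one binary character per nontrivial clade, with clade members `1`,
the source tree's other taxa `0`, and taxa absent from that source `?`. A
synthetic all-zero outgroup row, `__MRP_ROOT__`, is appended; it lets the
unrooted parsimony result be rooted at the end of the pipeline. Characters
are ordered by source tree and clade preorder, so the matrix is
deterministic and permutation-equivariant in the taxa.

**Scoring.** Parsimony is equal-weight Fitch (unordered) with `?` treated
as "either state". The R-level `fitch_length()` uses Hartigan's voting
generalization so multifurcating trees are scored exactly; the compiled
scorer used by tree search roots the tree at a leaf and applies the
sequential intersection/union rule, which is exact for binary characters.
The two paths, a brute-force assignment enumeration, and an external
parsimony implementation are cross-checked in the tests.

**Search.** Up to `exhaustive_threshold` taxa (default 9, i.e. 135,135
unrooted binary topologies — exhaustive search stays in seconds at that
size) every topology is enumerated by stepwise leaf insertion with
branch-and-bound pruning (a partial tree's score never decreases when a
leaf is added), and *all* minimum-score topologies are returned. Beyond the
threshold, seeded random-addition starts followed by
nearest-neighbor-interchange hill climbing return the best set found.
Random addition with NNI can stall in local optima on conflict-heavy
matrices, so the default is 20 starts; with enough starts the heuristic
matches the exhaustive optimum on every small matrix in the test suite. The
MP set is deduplicated by bipartition set.

**Consensus and rooting.** Which single MP tree a black-box parsimony run
would report is arbitrary; phyloforge instead exposes the full MP set and
returns the *strict consensus* — the tree containing exactly the clades
present in every MP tree, multifurcating where they disagree. Consensus is
clade-based (rooted): all MP trees emerge from the search rooted at the
synthetic outgroup, so the clade intersection realizes exactly the
intersection of their split sets, and identity inputs reproduce themselves.
`mrp_supertree()` finally removes the synthetic outgroup leaf, yielding a
rooted supertree on the union of the source taxa. Supertrees carry no
branch lengths or supports: the characters contain no length information,
and inventing supports from character fit would overstate the evidence.

## Synthetic data

`random_trees()` draws *uniformly* random rooted binary labelled topologies
by sequential random leaf attachment: a tree with `k` leaves offers
`2k - 1` attachment positions (every parent edge plus above the root), so
the product over insertions reproduces the `(2n-3)!!` count exactly — the
suite checks all 15 rooted 4-leaf shapes appear with uniform frequencies.
A `missing_frac` parameter drops a random taxon subset from each tree,
emulating the unequal leaf sets of gene trees (genes are lost along
lineages); at least two taxa are always retained. Trees are topologies
only: no branch lengths, no rate heterogeneity, no correlated discord
between trees (as incomplete lineage sorting or transfers would produce).
Tests passing on these fixtures therefore demonstrate combinatorial
correctness of the algorithms, not robustness to the error structure of
real inference pipelines.

For supertree recovery experiments, `split_cover_subtrees()` derives one
induced subtree per internal edge of a binary model tree: the nearest leaf
in each of the four subtrees around the edge (the edge's *short quartet*)
plus the next-nearest leaf, five taxa in all. Short quartets determine a
binary tree (the dyadic-closure property), so the resulting collection is a
*defining* input: the model is the unique binary tree displaying all the
induced subtrees. That condition is what makes exact recovery a fair test
of the pipeline — with arbitrary random subtree sets several
maximum-parsimony trees can display every source, the strict consensus
correctly loses resolution, and no method could return the model with
certainty; the suite covers that regime separately by checking that every
supertree split remains compatible with the model.

## The project store

A project pools exactly two named collections (renameable, matching the
two-collection working style of gene-vs-species or host-vs-parasite
comparisons), members with one administrator, a privacy status, a todo
list, an append-only timeline, named backups, limits, and a control token.
Decisions where the behavior was open:

* the control token starts vacant; the first request is granted
  immediately, later requests queue and are decided by the holder or the
  administrator, and the administrator can take the token at any moment.
  Declined requesters may re-request immediately.
* a member who detaches their synchronized view keeps read access but has
  every mutating call rejected until re-attaching.
* limits (defaults: 10,000 trees and 5,000 distinct taxa per project,
  1,000 trees per import; the taxon cap counts taxa per *project*) are
  checked before any mutation, so a rejected import leaves the project
  bit-identical.
* project names are not unique keys; an opaque generated id is.
* persistence is one directory per project — Newick files and annotation
  CSVs per collection, a JSON metadata document, backups as
  subdirectories — chosen over a database so project state stays
  dependency-free and diff-able.

## Rendering

The SVG export is deliberately minimal: rectangular phylograms only, branch
lengths drawn when every branch has one and unit lengths otherwise, one
text element per leaf with y-positions following child order. Its purpose
is to make highlights verifiable: leaf colors come from annotations;
agreement shading greys the labels of `conflicting` and `tree_specific`
leaves and the edges of subtrees consisting entirely of such leaves
(default grey `#b8b8b8`, adjustable in `render_spec()` along with leaf
spacing and font size, both in pixels). Face-to-face pairs mirror the
second tree by reflecting x-coordinates and right-anchoring labels.
Rendering is pure: identical inputs give byte-identical documents.

## Numerical and degenerate-input choices

* Branch lengths are doubles end to end; equality in round-trip tests is
  bit-level. Negative lengths are rejected at parse time.
* Restriction to fewer than two taxa, RF with fewer than four common taxa,
  MAST with no common taxa, and consensus over unequal taxon sets are
  errors, not silent degenerate outputs.
* Matrices with zero characters make every topology optimal; exhaustive
  search then returns all of them, and `mrp_supertree()` short-circuits to
  the star tree.
* All stochastic components (fixture generation, heuristic search starts,
  optional MAST tie sampling) take explicit seeds and restore the caller's
  RNG state.

## Validation scale and limitations

The validation suite runs at desk scale, chosen so the full suite completes
in about a minute: RF against a naive enumeration oracle on 200 random
pairs of 4–16 taxa; MAST against exhaustive subset search on 100 pairs with
up to 7 common taxa plus agreement-set validity on 20 pairs of 12; Fitch
against brute-force assignment enumeration on 100 instances of up to 6
leaves; supertree recovery on 9-taxon models over 10 replicates (exhaustive
search over the 10-taxon space including the synthetic outgroup);
collaboration safety over 1,000 random event sequences.

Known limitations: MAST is rooted only; RF is the only tree distance
(no quartet, SPR or TBR distances); supertree search beyond the exhaustive
threshold is heuristic with no optimality certificate; the renderer is not
publication-grade typography; and the project store models roles and the
control protocol, not authentication or real-time synchronization.
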