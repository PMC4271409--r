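# -- random-tree fixture generator --------------------------------------------

# Attach a new leaf to a uniformly chosen position of a rooted tree: any of
# the 2k-2 parent edges or above the root (2k-1 positions for k leaves).
# Sequential uniform attachment yields the uniform distribution over rooted
# binary labelled topologies.
attach_leaf <- function(tree, label, choice) {
  paths <- list()
  collect <- function(node, path) {
    if (length(path)) paths[[length(paths) + 1L]] <<- path
    for (i in seq_along(node$children))
      collect(node$children[[i]], c(path, i))
  }
  collect(tree, integer(0))
  leaf <- pf_node(label = label)
  if (choice > length(paths)) {  # above the root
    return(as_phytree(pf_node(children = list(unclass_node(tree), leaf))))
  }
  p <- paths[[choice]]
  old <- get_at(tree, p)
  as_phytree(set_at(tree, p, pf_node(children = list(old, leaf))))
}

unclass_node <- function(node) { attributes(node) <- list(names = names(node)); node }

# One uniformly random rooted binary topology on the given labels.
random_topology <- function(labels) {
  tree <- as_phytree(pf_node(children = list(pf_node(label = labels[[1]]),
                                             pf_node(label = labels[[2]]))))
  for (k in seq_along(labels)[-(1:2)]) {
    n_pos <- 2L * (k - 1L) - 1L
    tree <- attach_leaf(tree, labels[[k]], sample.int(n_pos, 1L))
  }
  tree
}

#' Split-covering induced subtrees of a model tree
#'
#' Builds one induced subtree per internal edge of the unrooted model tree:
#' each contains the nearest leaf in each of the four subtrees around that
#' edge (its "short quartet") plus the next-nearest leaf. By the dyadic
#' closure property of short quartets, the resulting collection of induced
#' subtrees determines the binary model tree, making it the canonical input
#' for supertree-recovery experiments; every model split is witnessed and
#' every taxon appears in at least one subtree.
#'
#' @param model a binary `phytree`
#' @param size taxa per subtree (default 5: the short quartet plus one)
#' @return list of `phytree`, one per internal edge of the unrooted model
#' @export
split_cover_subtrees <- function(model, size = 5L) {
  stopifnot(size >= 4)
  g <- flatten_graph(model)
  nn <- length(g$adj)
  isleaf <- vapply(g$nodes, function(n) n$leaf, logical(1))
  labs <- vapply(g$nodes, function(n)
    if (n$leaf) n$label else NA_character_, character(1))
  # leaves ordered by distance from `start`, never crossing into `block`
  leaves_by_distance <- function(start, block) {
    d <- rep(NA_integer_, nn)
    d[block] <- -1L
    d[start] <- 0L
    q <- start
    while (length(q)) {
      v <- q[[1]]
      q <- q[-1]
      for (w in g$adj[[v]]) if (is.na(d[w])) { d[w] <- d[v] + 1L; q <- c(q, w) }
    }
    lv <- which(isleaf & !is.na(d) & d >= 0L)
    lv[order(d[lv], labs[lv])]
  }
  internal <- which(!isleaf & lengths(g$adj) > 0L)
  sets <- list()
  for (u in internal) for (v in g$adj[[u]]) {
    if (v < u || isleaf[v]) next  # each internal edge once
    dirs <- c(lapply(g$adj[[u]][g$adj[[u]] != v], leaves_by_distance, block = u),
              lapply(g$adj[[v]][g$adj[[v]] != u], leaves_by_distance, block = v))
    four <- vapply(dirs, function(o) labs[o[[1]]], character(1))
    rest <- setdiff(labs[unlist(dirs)], four)
    sets[[length(sets) + 1L]] <-
      c(four, rest[seq_len(min(size - length(four), length(rest)))])
  }
  lapply(sets, restrict_to_taxa, tree = model)
}

#' Generate random tree fixtures
#'
#' Uniformly random rooted binary topologies built by sequential random leaf
#' attachment; each tree is then restricted to a random taxon subset dropping
#' `missing_frac` of the taxa (emulating unequal leaf sets across gene
#' trees). Deterministic given `seed`; the caller's RNG stream is left
#' untouched.
#'
#' @param n_taxa number of taxa in the full label pool (labels `t01`, `t02`,
#'   ...)
#' @param n_trees number of trees to generate
#' @param missing_frac fraction of taxa dropped from each tree, in `[0, 1)`;
#'   at least 2 taxa are always retained
#' @param seed integer seed
#' @return list of `phytree`
#' @export
random_trees <- function(n_taxa, n_trees = 1L, missing_frac = 0, seed = 1L) {
  stopifnot(n_taxa >= 2, n_trees >= 1, missing_frac >= 0, missing_frac < 1)
  labels <- sprintf("t%02d", seq_len(n_taxa))
  with_seed(seed, {
    lapply(seq_len(n_trees), function(i) {
      tree <- random_topology(sample(labels))
      n_drop <- min(floor(missing_frac * n_taxa), n_taxa - 2L)
      if (n_drop > 0) {
        keep <- setdiff(labels, sample(labels, n_drop))
        tree <- restrict_to_taxa(tree, keep)
      }
      tree
    })
  })
}
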