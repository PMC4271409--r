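# Independent oracles built on ape/phangorn structures, used to cross-check
# the package's own implementations. They share no code path with the
# package beyond Newick text as the interchange format.

to_ape <- function(tree) ape::read.tree(text = write_newick(tree))

# children lists of an ape phylo, indexed by node id
ape_children <- function(tr) {
  kids <- vector("list", max(tr$edge))
  for (i in seq_len(nrow(tr$edge)))
    kids[[tr$edge[i, 1]]] <- c(kids[[tr$edge[i, 1]]], tr$edge[i, 2])
  kids
}

# tip labels below every node of an ape phylo
ape_clade_tips <- function(tr) {
  kids <- ape_children(tr)
  n <- length(tr$tip.label)
  below <- function(v) {
    if (v <= n) return(tr$tip.label[v])
    unlist(lapply(kids[[v]], below), use.names = FALSE)
  }
  root <- setdiff(tr$edge[, 1], tr$edge[, 2])[1]
  internal <- setdiff(unique(tr$edge[, 1]), root)
  lapply(internal, below)
}

# canonical keys of the nontrivial unrooted splits of an ape phylo
oracle_split_keys <- function(tr) {
  taxa <- sort(tr$tip.label)
  anchor <- taxa[1]
  keys <- vapply(ape_clade_tips(tr), function(cl) {
    if (length(cl) < 2 || length(taxa) - length(cl) < 2) return(NA_character_)
    side <- if (anchor %in% cl) setdiff(taxa, cl) else cl
    paste(sort(side), collapse = "\x1f")
  }, character(1))
  unique(keys[!is.na(keys)])
}

# naive RF: restrict with ape::keep.tip, enumerate splits, symmetric diff
oracle_rf <- function(t1, t2) {
  a1 <- to_ape(t1)
  a2 <- to_ape(t2)
  common <- intersect(a1$tip.label, a2$tip.label)
  k1 <- oracle_split_keys(ape::keep.tip(a1, common))
  k2 <- oracle_split_keys(ape::keep.tip(a2, common))
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

# canonical rooted-topology string of an ape phylo
oracle_canon <- function(tr) {
  kids <- ape_children(tr)
  n <- length(tr$tip.label)
  canon <- function(v) {
    if (v <= n) return(tr$tip.label[v])
    paste0("(", paste(sort(vapply(kids[[v]], canon, character(1))),
                      collapse = ","), ")")
  }
  canon(setdiff(tr$edge[, 1], tr$edge[, 2])[1])
}

# exhaustive rooted MAST size by subset search over the common taxa
oracle_mast_size <- function(t1, t2) {
  a1 <- to_ape(t1)
  a2 <- to_ape(t2)
  common <- sort(intersect(a1$tip.label, a2$tip.label))
  agree <- function(S) {
    identical(oracle_canon(ape::keep.tip(a1, S)),
              oracle_canon(ape::keep.tip(a2, S)))
  }
  for (k in seq(length(common), 2)) {
    hits <- utils::combn(common, k, agree)
    if (any(hits)) return(k)
  }
  if (length(common) >= 1) 1L else 0L
}

# brute-force small parsimony: enumerate every assignment of {0,1} to the
# internal nodes (and to '?' leaves), count differing edges, take the minimum
oracle_fitch <- function(tree, character) {
  nodes <- list()   # list(parent index, leaf label or NA)
  walk <- function(node, parent) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(parent = parent,
                         label = if (length(node$children)) NA_character_
                                 else node$label)
    for (ch in node$children) walk(ch, id)
  }
  walk(tree, 0L)
  fixed <- vapply(nodes, function(nd) {
    if (is.na(nd$label)) return(NA_integer_)
    s <- as.character(character[[nd$label]])
    if (s == "?" || is.na(s)) NA_integer_ else as.integer(s)
  }, integer(1))
  free <- which(is.na(fixed))
  best <- Inf
  for (code in seq_len(2^length(free)) - 1L) {
    st <- fixed
    st[free] <- bitwAnd(bitwShiftR(code, seq_along(free) - 1L), 1L)
    cost <- 0L
    for (i in seq_along(nodes))
      if (nodes[[i]]$parent > 0L && st[i] != st[nodes[[i]]$parent])
        cost <- cost + 1L
    if (cost < best) best <- cost
  }
  best
}

# phangorn cross-check of a parsimony score (trees must share the taxon set)
phangorn_score <- function(tree, chars_matrix) {
  taxa <- rownames(chars_matrix)
  dat <- phangorn::phyDat(chars_matrix, type = "USER",
                          levels = c("0", "1"), ambiguity = "?")
  phangorn::parsimony(ape::unroot(to_ape(tree)), dat)
}

# random branch lengths for round-trip testing
add_random_lengths <- function(node) {
  node$children <- lapply(node$children, function(ch) {
    ch$length <- round(stats::runif(1, 0.01, 5), 4)
    add_random_lengths(ch)
  })
  node
}

scramble_children <- function(node) {
  if (!length(node$children)) return(node)
  node$children <-
    lapply(node$children, scramble_children)[sample(length(node$children))]
  node
}

# a pair of random trees with at least `min_common` shared taxa
random_pair <- function(n, seed, missing_frac = 0, min_common = 4) {
  repeat {
    tt <- random_trees(n, 2, missing_frac = missing_frac, seed = seed)
    if (length(common_taxa(tt)) >= min_common) return(tt)
    seed <- seed + 10000L
  }
}
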