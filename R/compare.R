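# -- bipartitions and Robinson-Foulds ----------------------------------------

SPLIT_SEP <- "\x1f"

set_key <- function(x) paste(sort(x), collapse = SPLIT_SEP)

# All clades (leaf sets below internal non-root nodes) of a rooted tree.
clade_list <- function(tree) {
  out <- list()
  walk <- function(node, at_root) {
    if (is_leaf(node)) return(node$label)
    below <- lapply(node$children, walk, at_root = FALSE)
    lv <- unlist(below, use.names = FALSE)
    if (!at_root) out[[length(out) + 1L]] <<- lv
    lv
  }
  walk(tree, TRUE)
  out
}

# Canonical keys of the nontrivial unrooted splits of a tree.
split_keys <- function(tree) {
  taxa <- tree_leaves(tree)
  ntax <- length(taxa)
  anchor <- min(taxa)
  keys <- vapply(clade_list(tree), function(cl) {
    if (length(cl) < 2L || ntax - length(cl) < 2L) return(NA_character_)
    side <- if (anchor %in% cl) setdiff(taxa, cl) else cl
    set_key(side)
  }, character(1))
  unique(keys[!is.na(keys)])
}

#' Nontrivial bipartitions of a tree
#'
#' One bipartition per internal edge of the unrooted version of the tree;
#' trivial splits (a single leaf against the rest) are excluded and the
#' artificial root edge contributes no duplicate. Each bipartition is stored
#' canonically as the side not containing the lexicographically smallest
#' taxon.
#'
#' @param tree a `phytree`
#' @return list of `bipartition` objects, each with fields `side` (canonical)
#'   and `other`
#' @export
bipartitions <- function(tree) {
  taxa <- sort(tree_leaves(tree))
  keys <- split_keys(tree)
  lapply(keys, function(k) {
    side <- strsplit(k, SPLIT_SEP, fixed = TRUE)[[1]]
    structure(list(side = side, other = setdiff(taxa, side)),
              class = "bipartition")
  })
}

#' @export
print.bipartition <- function(x, ...) {
  cat("{", paste(x$side, collapse = ","), "} | {",
      paste(x$other, collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' Robinson-Foulds distance between two trees
#'
#' Both trees are first restricted to their common taxa (unary nodes
#' suppressed); the distance is the size of the symmetric difference of their
#' nontrivial unrooted bipartition sets — the full symmetric-difference count,
#' not its half.
#'
#' @param t1,t2 `phytree` objects
#' @return list with `n_common` (number of shared taxa) and `distance`
#' @export
rf_distance <- function(t1, t2) {
  common <- common_taxa(list(t1, t2))
  if (length(common) < 4)
    stop("distance undefined: fewer than 4 common taxa (",
         length(common), ")", call. = FALSE)
  k1 <- split_keys(restrict_to_taxa(t1, common))
  k2 <- split_keys(restrict_to_taxa(t2, common))
  structure(list(n_common = length(common),
                 distance = length(setdiff(k1, k2)) + length(setdiff(k2, k1))),
            class = "rf_dist")
}

#' @export
print.rf_dist <- function(x, ...) {
  cat("Robinson-Foulds distance:", x$distance,
      "(over", x$n_common, "common taxa)\n")
  invisible(x)
}

#' Canonical key of a rooted topology
#'
#' A label-sorted parenthesized form identifying the rooted topology up to
#' child order, ignoring branch lengths and supports. Two trees have equal
#' keys iff their rooted topologies are isomorphic with matching leaf labels.
#'
#' @param tree a `phytree`
#' @return character(1)
#' @export
topology_key <- function(tree) {
  walk <- function(node) {
    if (is_leaf(node)) return(node$label)
    paste0("(", paste(sort(vapply(node$children, walk, character(1))),
                      collapse = ","), ")")
  }
  walk(tree)
}

# -- rooted maximum agreement subtree ----------------------------------------

# Postorder flattening: nodes[[i]] has $children (ids), $label, $leafset
flatten_post <- function(tree) {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  walk <- function(node) {
    kids <- vapply(node$children, walk, integer(1))
    id <- length(env$nodes) + 1L
    leafset <- if (length(kids))
      sort(unlist(lapply(kids, function(k) env$nodes[[k]]$leafset),
                  use.names = FALSE))
    else node$label
    env$nodes[[id]] <- list(children = kids, label = node$label,
                            leafset = leafset)
    id
  }
  root <- walk(tree)
  list(nodes = env$nodes, root = root)
}

#' Rooted maximum agreement subtree of two trees
#'
#' Computes a maximum-cardinality subset S of the common taxa such that the
#' rooted subtrees induced on S in the two trees are isomorphic (matching
#' leaf labels, ignoring child order, after suppressing unary nodes). The
#' dynamic program runs over node pairs; multifurcations are handled by a
#' maximum-weight matching of child subproblems. Ties are broken
#' deterministically in favor of the lexicographically smallest taxon set;
#' with `tie_break = "random"` and a seed, tied choices are sampled instead.
#'
#' The result classifies every leaf of each tree as `in_consensus` (in S),
#' `conflicting` (common to both trees but outside S), or `tree_specific`
#' (absent from the other tree); the three classes partition each tree's
#' leaf set.
#'
#' @param t1,t2 `phytree` objects, treated as rooted
#' @param tie_break `"lex"` (default, deterministic) or `"random"`
#' @param seed integer seed used when `tie_break = "random"`
#' @return an `agreement` object: fields `mast` (sorted taxon set), `size`,
#'   and `classes` (per-tree named character vectors)
#' @export
mast <- function(t1, t2, tie_break = c("lex", "random"), seed = NULL) {
  tie_break <- match.arg(tie_break)
  lv1 <- tree_leaves(t1); lv2 <- tree_leaves(t2)
  common <- intersect(lv1, lv2)
  if (!length(common)) stop("no common taxa", call. = FALSE)
  if (tie_break == "random" && !is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  f1 <- flatten_post(t1); f2 <- flatten_post(t2)
  n1 <- length(f1$nodes); n2 <- length(f2$nodes)

  empty <- list(size = 0L, set = character(0))
  # cells[[u]][[v]] = list(size, set)
  cells <- vector("list", n1)
  for (u in seq_len(n1)) cells[[u]] <- vector("list", n2)

  pick <- function(cands) {
    sizes <- vapply(cands, `[[`, integer(1), "size")
    top <- which(sizes == max(sizes))
    if (length(top) > 1L) {
      if (tie_break == "random") {
        top <- top[sample.int(length(top), 1L)]
      } else {
        keys <- vapply(cands[top], function(c) set_key(c$set), character(1))
        top <- top[order(keys)][1L]
      }
    }
    cands[[top[1L]]]
  }

  # maximum-weight matching of child subproblems via subset DP over the
  # smaller child list; unmatched children contribute nothing
  match_children <- function(au, bv) {
    if (length(au) > length(bv)) { tmp <- au; au <- bv; bv <- tmp; flip <- TRUE }
    else flip <- FALSE
    m <- length(au); k <- length(bv)
    getcell <- function(i, j) if (flip) cells[[bv[j]]][[au[i]]] else cells[[au[i]]][[bv[j]]]
    # dp[[mask+1]] over prefix of au processed; iterate i = 1..m
    dp <- rep(list(empty), bitwShiftL(1L, k))
    for (i in seq_len(m)) {
      ndp <- dp  # skipping au[i]
      for (mask in seq_len(bitwShiftL(1L, k)) - 1L) {
        base <- dp[[mask + 1L]]
        for (j in seq_len(k)) {
          bit <- bitwShiftL(1L, j - 1L)
          if (bitwAnd(mask, bit) == 0L) {
            w <- getcell(i, j)
            if (w$size > 0L) {
              cand <- list(size = base$size + w$size, set = c(base$set, w$set))
              cur <- ndp[[bitwOr(mask, bit) + 1L]]
              if (cand$size > cur$size ||
                  (cand$size == cur$size && tie_break == "lex" &&
                   set_key(cand$set) < set_key(cur$set)))
                ndp[[bitwOr(mask, bit) + 1L]] <- cand
            }
          }
        }
      }
      dp <- ndp
    }
    pick(dp)
  }

  for (u in seq_len(n1)) {
    nu <- f1$nodes[[u]]
    for (v in seq_len(n2)) {
      nv <- f2$nodes[[v]]
      if (!length(nu$children)) {
        hit <- nu$label %in% nv$leafset && nu$label %in% common
        cells[[u]][[v]] <- if (hit) list(size = 1L, set = nu$label) else empty
      } else if (!length(nv$children)) {
        hit <- nv$label %in% nu$leafset && nv$label %in% common
        cells[[u]][[v]] <- if (hit) list(size = 1L, set = nv$label) else empty
      } else {
        cands <- list()
        for (c in nv$children) cands[[length(cands) + 1L]] <- cells[[u]][[c]]
        for (c in nu$children) cands[[length(cands) + 1L]] <- cells[[c]][[v]]
        cands[[length(cands) + 1L]] <- match_children(nu$children, nv$children)
        cells[[u]][[v]] <- pick(cands)
      }
    }
  }

  S <- sort(cells[[f1$root]][[f2$root]]$set)
  classify <- function(leaves, other) {
    cls <- ifelse(leaves %in% S, "in_consensus",
                  ifelse(leaves %in% other, "conflicting", "tree_specific"))
    names(cls) <- leaves
    cls
  }
  res <- structure(list(mast = S, size = length(S),
                        classes = list(classify(lv1, lv2), classify(lv2, lv1))),
                   class = "agreement")
  # the three classes partition each tree's leaf set by construction; check
  stopifnot(sort(names(res$classes[[1]])) %in% sort(lv1),
            sort(names(res$classes[[2]])) %in% sort(lv2))
  res
}

#' @export
print.agreement <- function(x, ...) {
  cat("Maximum agreement subtree:", x$size, "taxa\n")
  cat(" ", paste(x$mast, collapse = ", "), "\n")
  for (i in 1:2) {
    cl <- x$classes[[i]]
    cat("tree ", i, ": ", sum(cl == "in_consensus"), " in consensus, ",
        sum(cl == "conflicting"), " conflicting, ",
        sum(cl == "tree_specific"), " tree-specific\n", sep = "")
  }
  invisible(x)
}

#' Export an agreement classification as CSV
#'
#' @param agreement an `agreement` from [mast()]
#' @param path output CSV path (columns taxon,tree,class)
#' @return `path`, invisibly
#' @export
write_agreement_csv <- function(agreement, path) {
  df <- do.call(rbind, lapply(1:2, function(i) {
    cl <- agreement$classes[[i]]
    data.frame(taxon = names(cl), tree = i, class = unname(cl))
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# -- tanglegram tip-order harmonization --------------------------------------

#' Count tanglegram crossings between two tip orders
#'
#' The number of pairs of common taxa appearing in opposite relative order in
#' the two sequences (inversions); this equals the number of line crossings
#' of a straight-connector tanglegram.
#'
#' @param order1,order2 character vectors of tip labels
#' @return non-negative integer
#' @export
crossing_count <- function(order1, order2) {
  common <- intersect(order1, order2)
  if (length(common) < 2) return(0L)
  a <- order1[order1 %in% common]
  pos <- match(a, order2[order2 %in% common])
  inv <- 0L
  for (i in seq_len(length(pos) - 1L))
    inv <- inv + sum(pos[(i + 1L):length(pos)] < pos[i])
  as.integer(inv)
}

# One barycenter pass: reorder every internal node of `mobile` by the mean
# rank of each child's common leaves in `ranks` (a named rank vector).
# Children with no common leaves are placed after the others, preserving
# their previous relative order; ties broken by smallest leaf label.
barycenter_pass <- function(mobile, ranks) {
  reorder_node <- function(node) {
    if (is_leaf(node)) return(node)
    node$children <- lapply(node$children, reorder_node)
    info <- lapply(node$children, function(ch) {
      lv <- tree_leaves(ch)
      r <- ranks[lv[lv %in% names(ranks)]]
      list(mean = if (length(r)) mean(r) else NA_real_,
           minlab = min(lv))
    })
    has <- !vapply(info, function(x) is.na(x$mean), logical(1))
    means <- vapply(info, `[[`, numeric(1), "mean")
    minlab <- vapply(info, `[[`, character(1), "minlab")
    ord <- c(which(has)[order(means[has], minlab[has])], which(!has))
    node$children <- node$children[ord]
    node
  }
  as_phytree(reorder_node(mobile))
}

#' Harmonize the tip orders of two trees (tanglegram untangling)
#'
#' Alternating barycenter heuristic: holding one tree's tip order fixed, each
#' internal node of the other tree sorts its children by the mean rank of
#' their common leaves in the fixed order; the roles alternate for up to
#' `max_rounds` rounds or until a fixpoint. Only child orders change, never
#' the topology, and the returned configuration never has more crossings than
#' the input.
#'
#' @param t1,t2 `phytree` objects
#' @param max_rounds maximum number of alternating rounds (default 10)
#' @param seed accepted for interface stability; the heuristic is
#'   deterministic and does not consume randomness
#' @return list with `t1`, `t2` (reordered trees) and `layout` (a
#'   `tanglegram_layout`: `order1`, `order2`, `crossings`)
#' @export
auto_swap <- function(t1, t2, max_rounds = 10L, seed = NULL) {
  score <- function(a, b) crossing_count(tree_leaves(a), tree_leaves(b))
  best <- list(t1 = t1, t2 = t2, cross = score(t1, t2))
  cur1 <- t1; cur2 <- t2
  for (r in seq_len(max_rounds)) {
    o1 <- tree_leaves(cur1)
    prev2 <- tree_leaves(cur2)
    cur2 <- barycenter_pass(cur2, setNames(seq_along(o1), o1))
    o2 <- tree_leaves(cur2)
    cur1 <- barycenter_pass(cur1, setNames(seq_along(o2), o2))
    cr <- score(cur1, cur2)
    if (cr < best$cross) best <- list(t1 = cur1, t2 = cur2, cross = cr)
    if (identical(tree_leaves(cur1), o1) && identical(o2, prev2))
      break  # fixpoint
  }
  layout <- structure(list(order1 = tree_leaves(best$t1),
                           order2 = tree_leaves(best$t2),
                           crossings = best$cross),
                      class = "tanglegram_layout")
  list(t1 = best$t1, t2 = best$t2, layout = layout)
}

#' @export
print.tanglegram_layout <- function(x, ...) {
  cat("tanglegram layout:", x$crossings, "crossings over",
      length(intersect(x$order1, x$order2)), "common taxa\n")
  invisible(x)
}

#' @importFrom stats setNames
NULL
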