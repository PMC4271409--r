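# -- tree edition -------------------------------------------------------------

# Branch-length sum under pruning semantics: absent (NA) dominates.
na_sum <- function(a, b) {
  if (is.na(a) || is.na(b)) NA_real_ else a + b
}

#' Taxa common to a set of trees
#'
#' @param trees list of `phytree`
#' @return character vector: the intersection of the leaf sets (may be empty)
#' @export
common_taxa <- function(trees) {
  if (inherits(trees, "phytree")) trees <- list(trees)
  stopifnot(length(trees) >= 1)
  sort(Reduce(intersect, lapply(trees, tree_leaves)))
}

#' Restrict a tree to a subset of its taxa
#'
#' Returns the subtree induced by `keep`: leaves outside `keep` are pruned and
#' unary nodes arising from the pruning are suppressed, their branch lengths
#' summed (absent lengths stay absent). The relative nesting of the surviving
#' taxa is unchanged.
#'
#' @param tree a `phytree`
#' @param keep character vector of taxon labels to keep
#' @return the induced `phytree`
#' @export
restrict_to_taxa <- function(tree, keep) {
  surv <- intersect(tree_leaves(tree), keep)
  if (length(surv) < 2)
    stop("restriction would leave a degenerate tree (",
         length(surv), " surviving taxa)", call. = FALSE)
  prune <- function(node) {
    if (is_leaf(node)) {
      if (node$label %in% keep) return(node)
      return(NULL)
    }
    kids <- Filter(Negate(is.null), lapply(node$children, prune))
    if (length(kids) == 0L) return(NULL)
    if (length(kids) == 1L) {
      child <- kids[[1]]
      child$length <- na_sum(node$length, child$length)
      return(child)
    }
    node$children <- kids
    node
  }
  out <- prune(tree)
  out$length <- NA_real_  # the induced root has no parent edge
  as_phytree(out)
}

#' Swap two subtrees below their most recent common ancestor
#'
#' Locates the MRCA of the two named taxa and exchanges, in the child order of
#' that node, the two child subtrees containing them. The unordered topology
#' is unchanged; applying the same swap twice restores the original order.
#'
#' @param tree a `phytree`
#' @param taxonA,taxonB leaf labels of two distinct taxa
#' @return the reordered `phytree`
#' @export
manual_swap <- function(tree, taxonA, taxonB) {
  if (identical(taxonA, taxonB))
    stop("cannot swap a taxon with itself: ", taxonA, call. = FALSE)
  pa <- node_path(tree, taxonA)
  if (is.null(pa)) stop("unknown taxon: ", taxonA, call. = FALSE)
  pb <- node_path(tree, taxonB)
  if (is.null(pb)) stop("unknown taxon: ", taxonB, call. = FALSE)
  m <- mrca_path(tree, c(taxonA, taxonB))
  k <- length(m)
  ia <- pa[[k + 1L]]
  ib <- pb[[k + 1L]]
  anc <- get_at(tree, m)
  tmp <- anc$children[[ia]]
  anc$children[[ia]] <- anc$children[[ib]]
  anc$children[[ib]] <- tmp
  as_phytree(set_at(tree, m, anc))
}

#' Rename taxa across one or several trees
#'
#' @param trees a `phytree` or list of them
#' @param mapping named character vector, `old label -> new label`; must be
#'   injective. Trees lacking an old label are unchanged for that entry.
#' @return list of renamed `phytree` (a single tree input returns a single tree)
#' @export
rename_taxa <- function(trees, mapping) {
  single <- inherits(trees, "phytree")
  if (single) trees <- list(trees)
  stopifnot(is.character(mapping), !is.null(names(mapping)))
  if (anyDuplicated(mapping))
    stop("rename mapping is not injective: duplicate new name '",
         mapping[duplicated(mapping)][[1]], "'", call. = FALSE)
  nm <- names(trees)
  out <- lapply(seq_along(trees), function(i) {
    tr <- trees[[i]]
    lv <- tree_leaves(tr)
    hits <- intersect(names(mapping), lv)
    newlv <- lv
    newlv[match(hits, lv)] <- mapping[hits]
    if (anyDuplicated(newlv)) {
      clash <- newlv[duplicated(newlv)][[1]]
      id <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else paste("tree", i)
      stop("renaming collides on label '", clash, "' in ", id, call. = FALSE)
    }
    as_phytree(map_leaves(tr, function(leaf) {
      if (leaf$label %in% names(mapping)) leaf$label <- mapping[[leaf$label]]
      leaf
    }))
  })
  names(out) <- nm
  if (single) out[[1]] else out
}

#' Color taxa across one or several trees
#'
#' Sets the `color` annotation on every matching leaf of every given tree, in
#' a coordinated way; leaves outside `taxa` are untouched.
#'
#' @param trees a `phytree` or list of them
#' @param taxa character vector of taxon labels to color
#' @param color a CSS-style color token (e.g. `"red"`, `"#ff0000"`)
#' @return the annotated tree(s)
#' @export
set_color <- function(trees, taxa, color) {
  single <- inherits(trees, "phytree")
  if (single) trees <- list(trees)
  stopifnot(is.character(color), length(color) == 1)
  out <- lapply(trees, function(tr) {
    as_phytree(map_leaves(tr, function(leaf) {
      if (leaf$label %in% taxa) leaf$annot["color"] <- color
      leaf
    }))
  })
  names(out) <- names(trees)
  if (single) out[[1]] else out
}

# -- rerooting ----------------------------------------------------------------

#' Multi-level outgroup specification
#'
#' Levels are scanned outermost-first: the first level with at least one
#' representative among a tree's leaves becomes the active outgroup for that
#' tree.
#'
#' @param ... one character vector of taxon labels per level, outermost first
#' @return an `outgroup_spec`
#' @export
outgroup_spec <- function(...) {
  levels <- list(...)
  if (length(levels) == 1 && is.list(levels[[1]])) levels <- levels[[1]]
  if (!length(levels)) stop("an outgroup spec needs at least one level", call. = FALSE)
  for (lv in levels)
    if (!is.character(lv) || !length(lv))
      stop("every outgroup level must be a non-empty character vector", call. = FALSE)
  structure(levels, class = "outgroup_spec")
}

# Flatten a rooted tree into an unrooted weighted graph. A binary root is
# spliced out (its two incident edges merged, lengths summed, support taken
# from whichever side carries one) so that the unrooted split set is faithful.
flatten_graph <- function(tree) {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  env$nodes <- list()
  env$adj <- list()
  env$elen <- list()
  env$esup <- list()
  ekey <- function(a, b) paste0(min(a, b), "|", max(a, b))
  walk <- function(node, parent) {
    env$n <- env$n + 1L
    id <- env$n
    env$nodes[[id]] <- list(label = node$label, annot = node$annot,
                            leaf = is_leaf(node))
    env$adj[[id]] <- if (parent > 0L) parent else integer(0)
    if (parent > 0L) {
      env$adj[[parent]] <- c(env$adj[[parent]], id)
      env$elen[[ekey(parent, id)]] <- node$length
      env$esup[[ekey(parent, id)]] <- node$support
    }
    for (ch in node$children) walk(ch, id)
    id
  }
  walk(tree, 0L)
  g <- list(nodes = env$nodes, adj = env$adj, elen = env$elen, esup = env$esup,
            ekey = ekey, root = 1L, spliced = FALSE)
  if (length(g$adj[[1L]]) == 2L) {
    c1 <- g$adj[[1L]][1]; c2 <- g$adj[[1L]][2]
    k1 <- ekey(1L, c1); k2 <- ekey(1L, c2); k12 <- ekey(c1, c2)
    g$elen[[k12]] <- na_sum(g$elen[[k1]], g$elen[[k2]])
    s1 <- g$esup[[k1]]; s2 <- g$esup[[k2]]
    g$esup[[k12]] <- if (!is.na(s1)) s1 else s2
    g$adj[[c1]][g$adj[[c1]] == 1L] <- c2
    g$adj[[c2]][g$adj[[c2]] == 1L] <- c1
    g$adj[[1L]] <- integer(0)
    g$spliced <- TRUE
    g$old_children <- c(c1, c2)
  }
  g
}

# Rebuild a rooted tree from the unrooted graph, placing the new root on the
# edge (a, b) with the a-side first. The edge's length is divided equally
# between the two new root children; an absent length stays absent.
build_rooted <- function(g, a, b) {
  L <- g$elen[[g$ekey(a, b)]]
  half <- if (is.null(L) || is.na(L)) NA_real_ else L / 2
  sup <- g$esup[[g$ekey(a, b)]]
  if (is.null(sup)) sup <- NA_real_
  mk <- function(v, from, len, support) {
    info <- g$nodes[[v]]
    if (info$leaf)
      return(pf_node(label = info$label, length = len, annot = info$annot))
    nbrs <- g$adj[[v]]
    nbrs <- nbrs[nbrs != from]
    kids <- lapply(nbrs, function(w) {
      k <- g$ekey(v, w)
      s <- g$esup[[k]]
      mk(w, v, g$elen[[k]] %||% NA_real_, if (is.null(s)) NA_real_ else s)
    })
    pf_node(label = info$label, length = len, support = support,
            children = kids)
  }
  root <- pf_node(children = list(mk(a, b, half, sup), mk(b, a, half, sup)))
  as_phytree(root)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Reroot a tree on a (possibly multi-level) outgroup
#'
#' Scans the outgroup levels outermost-first; the first level with at least
#' one representative among the tree's leaves is the active outgroup. The
#' tree is rerooted on the edge separating the MRCA of the representatives
#' from the rest of the tree; the unrooted bipartition set is unchanged and
#' the split edge's length is divided equally between the two new root
#' children. When no level has a representative the tree is returned
#' unchanged with a warning; a non-monophyletic outgroup is rerooted on the
#' edge above its MRCA with a warning.
#'
#' @param tree a `phytree`
#' @param spec an [outgroup_spec()] (a plain character vector is accepted as a
#'   single level)
#' @param quiet suppress R-level warnings (they are always attached to the
#'   result as the `reroot_warnings` attribute)
#' @return the rerooted `phytree`
#' @export
reroot_outgroup <- function(tree, spec, quiet = FALSE) {
  if (is.character(spec)) spec <- outgroup_spec(spec)
  stopifnot(inherits(spec, "outgroup_spec"))
  lv <- tree_leaves(tree)
  warnings <- character(0)
  reps <- NULL
  for (level in spec) {
    hit <- intersect(level, lv)
    if (length(hit)) { reps <- hit; break }
  }
  if (is.null(reps)) {
    warnings <- "no outgroup representative at any level; tree unchanged"
    if (!quiet) warning(warnings, call. = FALSE)
    attr(tree, "reroot_warnings") <- warnings
    return(tree)
  }
  if (length(reps) == length(lv)) {
    warnings <- "outgroup covers every taxon; tree unchanged"
    if (!quiet) warning(warnings, call. = FALSE)
    attr(tree, "reroot_warnings") <- warnings
    return(tree)
  }
  m <- mrca_path(tree, reps)
  clade <- tree_leaves(get_at(tree, m))
  if (length(m) == 0L) {
    # MRCA of the outgroup is the current root: try to separate via the
    # complement's MRCA instead.
    comp <- setdiff(lv, reps)
    mc <- mrca_path(tree, comp)
    if (length(mc) == 0L)
      stop("outgroup not monophyletic: cannot find a separating edge",
           call. = FALSE)
    cl <- tree_leaves(get_at(tree, mc))
    if (!setequal(cl, comp))
      stop("outgroup not monophyletic: complement is not a clade", call. = FALSE)
    m <- mc
    clade <- cl
  } else if (!setequal(clade, reps)) {
    warnings <- c(warnings, "non-monophyletic outgroup")
    if (!quiet) warning("non-monophyletic outgroup", call. = FALSE)
  }
  g <- flatten_graph(tree)
  # graph id of the MRCA: preorder position = 1 + number of nodes visited
  # before it; recompute by walking the path.
  gid <- graph_id_of_path(tree, m)
  parent_gid <- graph_id_of_path(tree, m[-length(m)])
  if (g$spliced && parent_gid == 1L) {
    other <- g$old_children[g$old_children != gid]
    a <- gid; b <- other
  } else {
    a <- gid; b <- parent_gid
  }
  out <- build_rooted(g, a, b)
  # present the outgroup side first
  if (!all(reps %in% tree_leaves(out$children[[1]]))) {
    out$children <- out$children[c(2, 1)]
  }
  attr(out, "reroot_warnings") <- warnings
  out
}

# Preorder id (as assigned by flatten_graph) of the node at a child-index path.
graph_id_of_path <- function(tree, path) {
  count <- function(node) {
    if (is_leaf(node)) return(1L)
    1L + sum(vapply(node$children, count, integer(1)))
  }
  id <- 1L
  node <- tree
  for (i in path) {
    if (i > 1L)
      for (j in seq_len(i - 1L)) id <- id + count(node$children[[j]])
    id <- id + 1L
    node <- node$children[[i]]
  }
  id
}

# -- collections --------------------------------------------------------------

#' Create an ordered, named collection of trees
#'
#' @param name collection name
#' @param trees named list of `phytree`; names must be unique and the order is
#'   user-controlled and stable under edits
#' @return a `tree_collection`
#' @export
tree_collection <- function(name, trees = list()) {
  stopifnot(is.character(name), length(name) == 1)
  if (length(trees)) {
    if (is.null(names(trees)) || any(!nzchar(names(trees))))
      stop("every tree in a collection must be named", call. = FALSE)
    if (anyDuplicated(names(trees)))
      stop("duplicate tree name in collection: ",
           names(trees)[duplicated(names(trees))][[1]], call. = FALSE)
  }
  structure(list(name = name, trees = trees), class = "tree_collection")
}

#' @export
print.tree_collection <- function(x, ...) {
  cat("<tree_collection> '", x$name, "': ", length(x$trees), " trees\n", sep = "")
  for (nm in names(x$trees))
    cat("  ", nm, " (", n_leaves(x$trees[[nm]]), " leaves)\n", sep = "")
  invisible(x)
}

#' @export
length.tree_collection <- function(x) length(x$trees)

#' Reroot every tree of a collection on a shared outgroup spec
#'
#' [reroot_outgroup()] is applied to each tree independently; trees for which
#' rerooting fails (or finds no representative) are left unchanged. A per-tree
#' report is attached as the `report` attribute (columns `tree`, `status`,
#' `message`).
#'
#' @param collection a `tree_collection`
#' @param spec an [outgroup_spec()]
#' @return the rerooted `tree_collection`
#' @export
reroot_collection <- function(collection, spec) {
  stopifnot(inherits(collection, "tree_collection"))
  rows <- list()
  for (nm in names(collection$trees)) {
    res <- tryCatch(reroot_outgroup(collection$trees[[nm]], spec, quiet = TRUE),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[nm]] <- data.frame(tree = nm, status = "error",
                               message = conditionMessage(res))
    } else {
      w <- attr(res, "reroot_warnings")
      attr(res, "reroot_warnings") <- NULL
      changed <- !length(w) || !any(grepl("unchanged", w))
      collection$trees[[nm]] <- res
      rows[[nm]] <- data.frame(
        tree = nm,
        status = if (length(w)) "warning" else "ok",
        message = if (length(w)) paste(w, collapse = "; ") else "")
    }
  }
  report <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
            else data.frame(tree = character(0), status = character(0),
                            message = character(0))
  attr(collection, "report") <- report
  collection
}
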