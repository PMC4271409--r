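# -- MRP supertree inference --------------------------------------------------

MRP_ROOT <- "__MRP_ROOT__"

# Nontrivial clades (leaf sets below internal non-root nodes) in preorder.
clades_preorder <- function(tree) {
  out <- list()
  walk <- function(node, at_root) {
    if (is_leaf(node)) return(invisible(NULL))
    if (!at_root) out[[length(out) + 1L]] <<- tree_leaves(node)
    for (ch in node$children) walk(ch, FALSE)
  }
  walk(tree, TRUE)
  out
}

#' Baum-Ragan matrix representation of a set of source trees
#'
#' Encodes each nontrivial clade of each rooted source tree as one binary
#' character: taxa inside the clade score 1, other taxa of that source tree
#' score 0, taxa absent from that source tree score `?`. A synthetic all-zero
#' outgroup row named `__MRP_ROOT__` is appended, which later allows the
#' parsimony result to be rooted. Characters are ordered by (source tree
#' order, clade preorder). Source trees with fewer than 3 leaves contribute
#' no characters (with a warning).
#'
#' @param source_trees list of `phytree` (optionally named)
#' @return an `mrp_matrix`: fields `taxa` (ordered, synthetic outgroup last),
#'   `chars` (taxa x characters matrix over `"0"`, `"1"`, `"?"`), and
#'   `provenance` (data frame: character, tree, clade)
#' @export
mrp_matrix <- function(source_trees) {
  if (inherits(source_trees, "phytree")) source_trees <- list(source_trees)
  stopifnot(length(source_trees) >= 1)
  nm <- names(source_trees)
  if (is.null(nm)) nm <- rep("", length(source_trees))
  nm[!nzchar(nm)] <- paste0("tree_", which(!nzchar(nm)))
  taxa <- sort(Reduce(union, lapply(source_trees, tree_leaves)))
  if (MRP_ROOT %in% taxa)
    stop("taxon label '", MRP_ROOT, "' is reserved", call. = FALSE)
  taxa <- c(taxa, MRP_ROOT)
  cols <- list()
  prov <- list()
  for (i in seq_along(source_trees)) {
    tr <- source_trees[[i]]
    lv <- tree_leaves(tr)
    if (length(lv) < 3) {
      warning("source tree '", nm[i],
              "' has fewer than 3 leaves and contributes no characters",
              call. = FALSE)
      next
    }
    for (cl in clades_preorder(tr)) {
      col <- rep("?", length(taxa))
      names(col) <- taxa
      col[lv] <- "0"
      col[cl] <- "1"
      col[MRP_ROOT] <- "0"
      cols[[length(cols) + 1L]] <- col
      prov[[length(prov) + 1L]] <- data.frame(
        tree = nm[i], clade = paste(sort(cl), collapse = ","))
    }
  }
  chars <- if (length(cols)) do.call(cbind, cols)
           else matrix(character(0), nrow = length(taxa), ncol = 0,
                       dimnames = list(taxa, NULL))
  if (length(cols)) {
    colnames(chars) <- paste0("c", seq_along(cols))
    rownames(chars) <- taxa
  }
  provenance <- if (length(prov))
    cbind(data.frame(character = colnames(chars)), do.call(rbind, prov))
  else data.frame(character = character(0), tree = character(0),
                  clade = character(0))
  structure(list(taxa = taxa, chars = chars, provenance = provenance),
            class = "mrp_matrix")
}

#' @export
print.mrp_matrix <- function(x, ...) {
  cat("<mrp_matrix> ", length(x$taxa), " taxa x ", ncol(x$chars),
      " characters (from ", length(unique(x$provenance$tree)),
      " source trees)\n", sep = "")
  invisible(x)
}

# Leaf state bitmask: "0"/0 -> 1, "1"/1 -> 2, "?"/NA -> 3.
state_mask <- function(x) {
  x <- as.character(x)
  out <- integer(length(x))
  out[x == "0"] <- 1L
  out[x == "1"] <- 2L
  out[x == "?" | is.na(x)] <- 3L
  if (any(out == 0L))
    stop("invalid character state: ", x[out == 0L][[1]], call. = FALSE)
  out
}

#' Parsimony length of one binary character on a tree
#'
#' Minimum number of state changes on the (possibly multifurcating) tree for
#' an unordered binary character, with `?` treated as "either state"
#' (Fitch's algorithm, generalized to polytomies by Hartigan's voting rule).
#'
#' @param tree a `phytree`
#' @param character named vector over the leaves with values `"0"`, `"1"`,
#'   `"?"` (or 0, 1, NA)
#' @return integer: minimum number of changes
#' @export
fitch_length <- function(tree, character) {
  lv <- tree_leaves(tree)
  if (!all(lv %in% names(character)))
    stop("character lacks states for: ",
         paste(setdiff(lv, names(character)), collapse = ", "), call. = FALSE)
  masks <- state_mask(character)
  names(masks) <- names(character)
  hart <- function(node) {
    if (is_leaf(node)) return(list(set = masks[[node$label]], cost = 0L))
    sub <- lapply(node$children, hart)
    sets <- vapply(sub, `[[`, integer(1), "set")
    cost <- sum(vapply(sub, `[[`, integer(1), "cost"))
    n0 <- sum(bitwAnd(sets, 1L) > 0L)
    n1 <- sum(bitwAnd(sets, 2L) > 0L)
    K <- max(n0, n1)
    set <- 0L
    if (n0 == K) set <- bitwOr(set, 1L)
    if (n1 == K) set <- bitwOr(set, 2L)
    list(set = set, cost = cost + length(sets) - K)
  }
  hart(tree)$cost
}

#' Total parsimony score of a tree on an MRP matrix
#'
#' @param tree a `phytree` whose leaf set equals the matrix taxa
#' @param matrix an [mrp_matrix()]
#' @return integer: sum of [fitch_length()] over all characters
#' @export
matrix_parsimony_score <- function(tree, matrix) {
  stopifnot(inherits(matrix, "mrp_matrix"))
  lv <- tree_leaves(tree)
  if (!setequal(lv, matrix$taxa))
    stop("tree leaves do not match matrix taxa", call. = FALSE)
  if (ncol(matrix$chars) == 0) return(0L)
  sum(vapply(seq_len(ncol(matrix$chars)), function(j) {
    fitch_length(tree, matrix$chars[, j])
  }, integer(1)))
}

#' Search settings for maximum-parsimony tree search
#'
#' @param exhaustive_threshold exhaustive enumeration is used up to this many
#'   taxa (default 9; 135,135 unrooted binary topologies at n = 9)
#' @param starts number of random-addition starts in heuristic mode
#'   (default 20)
#' @param max_rounds maximum nearest-neighbor-interchange improvement rounds
#'   per start
#' @param seed integer seed driving the random addition orders
#' @return a `search_config`
#' @export
search_config <- function(exhaustive_threshold = 9L, starts = 20L,
                          max_rounds = 50L, seed = 1L) {
  stopifnot(exhaustive_threshold >= 4, starts >= 1, max_rounds >= 1)
  structure(list(exhaustive_threshold = as.integer(exhaustive_threshold),
                 starts = as.integer(starts),
                 max_rounds = as.integer(max_rounds),
                 seed = as.integer(seed)),
            class = "search_config")
}

# Run code under a seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

# Convert a 0-based unrooted edge matrix (leaves 0..n-1 in `taxa` order) to a
# rooted phytree: the internal node adjacent to `root_taxon` becomes the root
# with that leaf as its first child. The nontrivial split set is preserved.
edges_to_phytree <- function(edges, taxa, root_taxon = taxa[[1]]) {
  n <- length(taxa)
  nn <- max(edges) + 1L
  adj <- vector("list", nn)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1] + 1L; b <- edges[i, 2] + 1L
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  r <- match(root_taxon, taxa)
  build <- function(u, from) {
    if (u <= n) return(pf_node(label = taxa[[u]]))
    kids <- adj[[u]][adj[[u]] != from]
    pf_node(children = lapply(kids, build, from = u))
  }
  v <- adj[[r]][[1]]
  kids <- adj[[v]][adj[[v]] != r]
  as_phytree(pf_node(children = c(list(pf_node(label = root_taxon)),
                                  lapply(kids, build, from = v))))
}

# phytree -> 0-based unrooted edge matrix in `taxa` leaf order (binary trees)
phytree_to_edges <- function(tree, taxa) {
  g <- flatten_graph(tree)
  ids <- integer(length(g$nodes))
  n <- length(taxa)
  nexti <- n
  for (i in seq_along(g$nodes)) {
    if (g$nodes[[i]]$leaf) ids[i] <- match(g$nodes[[i]]$label, taxa) - 1L
    else if (length(g$adj[[i]])) { nexti <- nexti + 1L; ids[i] <- nexti - 1L }
    else ids[i] <- -1L  # spliced-out old root
  }
  rows <- list()
  for (i in seq_along(g$adj))
    for (j in g$adj[[i]])
      if (i < j) rows[[length(rows) + 1L]] <- c(ids[i], ids[j])
  do.call(rbind, rows)
}

mrp_states <- function(matrix) {
  if (ncol(matrix$chars) == 0)
    return(base::matrix(integer(0), nrow = length(matrix$taxa), ncol = 0))
  apply(matrix$chars, 2, state_mask)
}

dedup_by_splits <- function(trees) {
  keys <- vapply(trees, function(t) set_key(split_keys(t)), character(1))
  trees[!duplicated(keys)]
}

nni_neighbors <- function(edges, n) {
  out <- list()
  E <- nrow(edges)
  for (i in seq_len(E)) {
    u <- edges[i, 1]; v <- edges[i, 2]
    if (u < n || v < n) next  # internal edges only
    urows <- which((edges[, 1] == u | edges[, 2] == u) & seq_len(E) != i)
    vrows <- which((edges[, 1] == v | edges[, 2] == v) & seq_len(E) != i)
    x_row <- urows[[1]]
    x <- if (edges[x_row, 1] == u) edges[x_row, 2] else edges[x_row, 1]
    for (y_row in vrows) {
      y <- if (edges[y_row, 1] == v) edges[y_row, 2] else edges[y_row, 1]
      e2 <- edges
      e2[x_row, ] <- c(u, y)
      e2[y_row, ] <- c(v, x)
      out[[length(out) + 1L]] <- e2
    }
  }
  out
}

heuristic_search_one <- function(states, n, order, max_rounds) {
  score <- function(e) fitch_score_cpp(e, n, states)
  # random-addition greedy start
  edges <- rbind(c(n, order[1]), c(n, order[2]), c(n, order[3]))
  for (k in seq(4, n)) {
    leaf <- order[k]
    v <- n + k - 3L
    best_e <- NULL; best_s <- Inf
    for (i in seq_len(nrow(edges))) {
      e2 <- rbind(edges, c(v, edges[i, 2]), c(v, leaf))
      e2[i, 2] <- v
      s <- score(e2)
      if (s < best_s) { best_s <- s; best_e <- e2 }
    }
    edges <- best_e
  }
  cur_s <- score(edges)
  # NNI hill climbing
  for (round in seq_len(max_rounds)) {
    improved <- FALSE
    for (nb in nni_neighbors(edges, n)) {
      s <- score(nb)
      if (s < cur_s) {
        edges <- nb; cur_s <- s; improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  list(edges = edges, score = cur_s)
}

#' Maximum-parsimony tree search on an MRP matrix
#'
#' With at most `exhaustive_threshold` taxa, every unrooted binary topology
#' is enumerated (with branch-and-bound pruning) and *all* minimum-score
#' topologies are returned. Beyond the threshold, seeded random-addition
#' starts followed by nearest-neighbor-interchange hill climbing return the
#' best-scoring set found. Results are deduplicated by bipartition set; the
#' attained score is attached as the `score` attribute.
#'
#' @param matrix an [mrp_matrix()]
#' @param config a [search_config()]
#' @return list of `phytree` (each rooted at the synthetic outgroup when
#'   present), with attribute `score`
#' @export
mp_search <- function(matrix, config = search_config()) {
  stopifnot(inherits(matrix, "mrp_matrix"), inherits(config, "search_config"))
  taxa <- matrix$taxa
  n <- length(taxa)
  if (n < 4) stop("tree search needs at least 4 taxa", call. = FALSE)
  states <- mrp_states(matrix)
  root_taxon <- if (MRP_ROOT %in% taxa) MRP_ROOT else taxa[[1]]
  if (n <= config$exhaustive_threshold) {
    res <- mp_exhaustive_cpp(states)
    if (isTRUE(res$truncated))
      warning("optimal tree set truncated", call. = FALSE)
    trees <- lapply(res$trees, edges_to_phytree, taxa = taxa,
                    root_taxon = root_taxon)
    score <- res$score
  } else {
    best_s <- Inf
    kept <- list()
    for (s in seq_len(config$starts)) {
      order <- with_seed(config$seed + s, sample.int(n)) - 1L
      # node ids are 0-based for the C scorer
      r <- heuristic_search_one(states, n, order, config$max_rounds)
      if (r$score < best_s) { best_s <- r$score; kept <- list(r$edges) }
      else if (r$score == best_s) kept[[length(kept) + 1L]] <- r$edges
    }
    trees <- lapply(kept, edges_to_phytree, taxa = taxa,
                    root_taxon = root_taxon)
    score <- best_s
  }
  trees <- dedup_by_splits(trees)
  attr(trees, "score") <- as.integer(score)
  trees
}

# -- strict consensus ---------------------------------------------------------

# Build the multifurcating rooted tree realizing exactly the given clades
# (lists of taxon labels; pairwise compatible, i.e. nested or disjoint).
tree_from_clades <- function(taxa, clades) {
  if (length(clades)) {
    ord <- order(-vapply(clades, length, integer(1)),
                 vapply(clades, set_key, character(1)))
    clades <- clades[ord]
  }
  assemble <- function(members, pool) {
    inside <- Filter(function(cl) all(cl %in% members) &&
                       length(cl) < length(members), pool)
    kids <- list()
    covered <- character(0)
    for (cl in inside) {
      if (any(cl %in% covered)) next  # nested inside a maximal clade
      kids[[length(kids) + 1L]] <- assemble(cl, inside)
      covered <- c(covered, cl)
    }
    for (lf in sort(setdiff(members, covered)))
      kids[[length(kids) + 1L]] <- pf_node(label = lf)
    if (length(kids) == 1L) return(kids[[1]])
    pf_node(children = kids)
  }
  as_phytree(assemble(taxa, clades))
}

#' Strict consensus of rooted trees on a common taxon set
#'
#' Returns the rooted tree containing exactly the clades present in every
#' input tree, multifurcating where they disagree. For inputs sharing a
#' common rooting this realizes exactly the intersection of their nontrivial
#' bipartition sets.
#'
#' @param trees list of `phytree`, all on the same taxon set
#' @return a `phytree`
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phytree")) trees <- list(trees)
  stopifnot(length(trees) >= 1)
  taxa <- sort(tree_leaves(trees[[1]]))
  for (t in trees[-1])
    if (!setequal(tree_leaves(t), taxa))
      stop("strict consensus requires identical taxon sets", call. = FALSE)
  keysets <- lapply(trees, function(t)
    unique(vapply(clade_list(t), set_key, character(1))))
  keys <- Reduce(intersect, keysets)
  clades <- lapply(keys, function(k) strsplit(k, SPLIT_SEP, fixed = TRUE)[[1]])
  tree_from_clades(taxa, clades)
}

#' MRP supertree of a set of source trees
#'
#' Pipeline: Baum-Ragan matrix coding ([mrp_matrix()]), maximum-parsimony
#' search ([mp_search()]), strict consensus of all most-parsimonious trees,
#' rooting on the synthetic outgroup, and removal of the synthetic outgroup
#' leaf. Returns a rooted supertree on the union of the source taxa.
#'
#' @param source_trees list of `phytree`, each with at least 3 leaves
#' @param config a [search_config()]
#' @return a rooted `phytree` on the union of the source-tree taxa
#' @export
mrp_supertree <- function(source_trees, config = search_config()) {
  if (inherits(source_trees, "phytree")) source_trees <- list(source_trees)
  m <- mrp_matrix(source_trees)
  taxa <- m$taxa
  if (length(taxa) < 5)  # incl. synthetic outgroup
    stop("supertree needs at least 4 source taxa", call. = FALSE)
  real_taxa <- setdiff(taxa, MRP_ROOT)
  if (ncol(m$chars) == 0) {  # no grouping signal: star tree
    return(as_phytree(pf_node(children = lapply(sort(real_taxa),
                                                function(l) pf_node(label = l)))))
  }
  mp <- mp_search(m, config)
  # all MP trees are rooted at the synthetic outgroup, so the clade-based
  # strict consensus realizes exactly the intersected split sets
  cons <- strict_consensus(mp)
  idx <- which(vapply(cons$children, function(ch)
    is_leaf(ch) && ch$label == MRP_ROOT, logical(1)))
  stopifnot(length(idx) == 1L)
  cons$children <- cons$children[-idx]
  if (length(cons$children) == 1L) {
    out <- cons$children[[1]]
    out$length <- NA_real_
  } else out <- cons
  as_phytree(out)
}

# -- matrix export ------------------------------------------------------------

#' Export an MRP matrix as a NEXUS DATA block
#' @param matrix an [mrp_matrix()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_mrp_nexus <- function(matrix, path) {
  stopifnot(inherits(matrix, "mrp_matrix"))
  lines <- c("#NEXUS", "BEGIN DATA;",
             sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(matrix$taxa),
                     ncol(matrix$chars)),
             "  FORMAT SYMBOLS=\"01\" MISSING=?;",
             "  MATRIX")
  for (tx in matrix$taxa) {
    row <- if (ncol(matrix$chars)) paste(matrix$chars[tx, ], collapse = "") else ""
    lines <- c(lines, sprintf("    %s %s", gsub("[[:space:]]", "_", tx), row))
  }
  writeLines(c(lines, "  ;", "END;"), path)
  invisible(path)
}

#' Export an MRP matrix in relaxed PHYLIP format
#' @param matrix an [mrp_matrix()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_mrp_phylip <- function(matrix, path) {
  stopifnot(inherits(matrix, "mrp_matrix"))
  lines <- sprintf("%d %d", length(matrix$taxa), ncol(matrix$chars))
  for (tx in matrix$taxa) {
    row <- if (ncol(matrix$chars)) paste(matrix$chars[tx, ], collapse = "") else ""
    lines <- c(lines, sprintf("%s  %s", gsub("[[:space:]]", "_", tx), row))
  }
  writeLines(lines, path)
  invisible(path)
}
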