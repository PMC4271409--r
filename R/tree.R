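#' @useDynLib phyloforge, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif
#' @importFrom utils head read.csv write.csv
NULL

# -- tree node model ----------------------------------------------------------
#
# A tree is its root node: a plain list with fields
#   label    - character(1); "" for unnamed internal nodes
#   length   - numeric(1) branch length to the parent, NA when absent
#   support  - numeric(1) support value read from a numeric internal label, NA otherwise
#   children - ordered list of child nodes (length 0 for leaves); order is
#              significant: it defines the displayed tip order
#   annot    - named character vector of per-leaf annotations (e.g. color)
# The root carries class "phytree". Internal nodes are bare lists.

pf_node <- function(label = "", length = NA_real_, support = NA_real_,
                    children = list(), annot = NULL) {
  list(label = label, length = length, support = support,
       children = children, annot = annot)
}

as_phytree <- function(node) {
  class(node) <- c("phytree", "list")
  node
}

#' Test whether a node is a leaf
#' @param node a tree node
#' @return logical(1)
#' @keywords internal
is_leaf <- function(node) length(node$children) == 0L

#' Leaf labels of a tree in tip (display) order
#'
#' @param tree a `phytree`
#' @return character vector of leaf labels, ordered as displayed top to bottom
#' @export
tree_leaves <- function(tree) {
  if (is_leaf(tree)) return(tree$label)
  unlist(lapply(tree$children, tree_leaves), use.names = FALSE)
}

#' Number of leaves of a tree
#' @param tree a `phytree`
#' @return integer(1)
#' @export
n_leaves <- function(tree) length(tree_leaves(tree))

#' Validate the structural invariants of a tree
#'
#' Checks that leaf labels are unique and non-empty and that no internal node
#' is unary (every internal node has at least two children).
#'
#' @param tree a `phytree`
#' @return the tree, invisibly; errors on violation
#' @export
validate_tree <- function(tree) {
  lv <- tree_leaves(tree)
  if (any(!nzchar(lv)))
    stop("tree has an empty leaf label", call. = FALSE)
  dup <- lv[duplicated(lv)]
  if (length(dup))
    stop("duplicate leaf label: ", dup[[1]], call. = FALSE)
  check_arity <- function(node, at_root) {
    k <- length(node$children)
    if (k == 1L)
      stop("unary internal node (", if (nzchar(node$label)) node$label else "unnamed",
           ")", call. = FALSE)
    for (ch in node$children) check_arity(ch, FALSE)
  }
  check_arity(tree, TRUE)
  invisible(tree)
}

# Path of child indices from the root to the leaf with the given label,
# or NULL when absent. integer(0) means the root itself is that leaf.
node_path <- function(node, label) {
  if (is_leaf(node)) {
    if (identical(node$label, label)) return(integer(0))
    return(NULL)
  }
  for (i in seq_along(node$children)) {
    p <- node_path(node$children[[i]], label)
    if (!is.null(p)) return(c(i, p))
  }
  NULL
}

get_at <- function(node, path) {
  for (i in path) node <- node$children[[i]]
  node
}

set_at <- function(node, path, value) {
  if (!length(path)) return(value)
  node$children[[path[[1]]]] <- set_at(node$children[[path[[1]]]], path[-1], value)
  node
}

# Longest common prefix of the root->leaf paths of the given labels: the MRCA.
mrca_path <- function(tree, labels) {
  paths <- lapply(labels, function(l) {
    p <- node_path(tree, l)
    if (is.null(p)) stop("unknown taxon: ", l, call. = FALSE)
    p
  })
  p0 <- paths[[1]]
  k <- length(p0)
  for (p in paths[-1]) {
    k <- min(k, length(p))
    while (k > 0 && !identical(p0[seq_len(k)], p[seq_len(k)])) k <- k - 1L
  }
  p0[seq_len(k)]
}

# Apply a function to every leaf node, rebuilding the tree.
map_leaves <- function(node, f) {
  if (is_leaf(node)) return(f(node))
  node$children <- lapply(node$children, map_leaves, f = f)
  node
}

#' @export
print.phytree <- function(x, ...) {
  lv <- tree_leaves(x)
  cat("<phytree> ", length(lv), " leaves: ",
      paste(head(lv, 8), collapse = ", "),
      if (length(lv) > 8) ", ..." else "", "\n", sep = "")
  cat(write_newick(x), "\n")
  invisible(x)
}

#' @export
summary.phytree <- function(object, ...) {
  lv <- tree_leaves(object)
  count_internal <- function(n) {
    if (is_leaf(n)) return(0L)
    1L + sum(vapply(n$children, count_internal, integer(1)))
  }
  has_len <- function(n) {
    c(!is.na(n$length), unlist(lapply(n$children, has_len)))
  }
  cat("phytree with", length(lv), "leaves and", count_internal(object),
      "internal nodes\n")
  cat("branch lengths:",
      if (all(has_len(object)[-1])) "complete" else "absent or partial", "\n")
  invisible(object)
}
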