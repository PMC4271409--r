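# Canonical id of an unrooted topology: sorted canonical split keys plus the
# taxon set (distinguishes trees on different taxon sets).
set_key_of <- function(tree) {
  paste(paste(sort(tree_leaves(tree)), collapse = ","),
        paste(sort(phyloforge:::split_keys(tree)), collapse = "|"),
        sep = "::")
}

# A split is addable to a tree iff it is pairwise compatible with every
# split of the tree, restricted to the split's taxon set.
split_compatible_with_tree <- function(b, model) {
  taxa <- c(b$side, b$other)
  X <- b$side
  Y <- b$other
  for (k in phyloforge:::split_keys(model)) {
    A <- intersect(strsplit(k, "\x1f", fixed = TRUE)[[1]], taxa)
    B <- setdiff(taxa, A)
    if (length(intersect(X, A)) && length(intersect(X, B)) &&
        length(intersect(Y, A)) && length(intersect(Y, B)))
      return(FALSE)
  }
  TRUE
}
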