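# -- Newick I/O ---------------------------------------------------------------
#
# Dialect: single-quoted labels with '' escaping; underscores passed through
# verbatim; a fully numeric label on an internal node is stored as a support
# value, any other internal label as a name; branch lengths kept at full
# double precision and re-emitted losslessly.

NEWICK_SPECIALS <- "[][(),:;'[:space:]]"

is_numeric_token <- function(s) {
  grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", s)
}

#' Parse a Newick string into a tree
#'
#' Accepts one `;`-terminated Newick statement. Quoted labels are unescaped,
#' underscores are kept verbatim, a numeric label on an internal node is
#' interpreted as a support value, and branch lengths are preserved at full
#' precision.
#'
#' @param text a single Newick statement, e.g. `"((A:1,B:2)90:0.5,C);"`
#' @return a `phytree`
#' @examples
#' t <- parse_newick("((A:1.5,B:2.0)90:0.3,C:1.0);")
#' tree_leaves(t)
#' @export
parse_newick <- function(text) {
  res <- parse_newick_stream(text, 1L)
  pos <- skip_ws(text, res$pos)
  if (pos <= nchar(text))
    stop("trailing characters after ';' at position ", pos, call. = FALSE)
  res$tree
}

#' Parse a multi-statement Newick string
#'
#' @param text text containing one or more `;`-terminated Newick statements
#' @return list of `phytree`
#' @export
parse_newick_all <- function(text) {
  trees <- list()
  pos <- skip_ws(text, 1L)
  while (pos <= nchar(text)) {
    res <- parse_newick_stream(text, pos)
    trees[[length(trees) + 1L]] <- res$tree
    pos <- skip_ws(text, res$pos)
  }
  trees
}

#' Read trees from a Newick file
#'
#' @param path path to a UTF-8 Newick file with one or more statements
#' @return list of `phytree`
#' @export
read_newick <- function(path) {
  parse_newick_all(paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                         collapse = "\n"))
}

skip_ws <- function(text, pos) {
  n <- nchar(text)
  while (pos <= n && grepl("^[[:space:]]$", substr(text, pos, pos))) pos <- pos + 1L
  pos
}

parse_newick_stream <- function(text, pos) {
  n <- nchar(text)
  pos <- skip_ws(text, pos)
  if (pos > n) stop("empty Newick input", call. = FALSE)

  peek <- function(p) if (p <= n) substr(text, p, p) else ""

  parse_label <- function(p) {
    p <- skip_ws(text, p)
    if (peek(p) == "'") {
      out <- character(0)
      p <- p + 1L
      start <- p
      repeat {
        if (p > n) stop("unterminated quoted label starting at position ",
                        start - 1L, call. = FALSE)
        ch <- peek(p)
        if (ch == "'") {
          if (peek(p + 1L) == "'") { out <- c(out, "'"); p <- p + 2L }
          else { p <- p + 1L; break }
        } else { out <- c(out, ch); p <- p + 1L }
      }
      list(label = paste(out, collapse = ""), pos = p, quoted = TRUE)
    } else {
      start <- p
      while (p <= n && !grepl(NEWICK_SPECIALS, peek(p))) p <- p + 1L
      list(label = substr(text, start, p - 1L), pos = p, quoted = FALSE)
    }
  }

  parse_length <- function(p) {
    p <- skip_ws(text, p)
    if (peek(p) != ":") return(list(length = NA_real_, pos = p))
    p <- skip_ws(text, p + 1L)
    start <- p
    while (p <= n && grepl("[0-9eE.+-]", peek(p))) p <- p + 1L
    tok <- substr(text, start, p - 1L)
    val <- suppressWarnings(as.numeric(tok))
    if (!nzchar(tok) || is.na(val))
      stop("invalid branch length '", tok, "' at position ", start, call. = FALSE)
    if (val < 0)
      stop("negative branch length at position ", start, call. = FALSE)
    list(length = val, pos = p)
  }

  parse_subtree <- function(p) {
    p <- skip_ws(text, p)
    if (peek(p) == "(") {
      p <- p + 1L
      children <- list()
      repeat {
        res <- parse_subtree(p)
        children[[length(children) + 1L]] <- res$node
        p <- skip_ws(text, res$pos)
        if (peek(p) == ",") { p <- p + 1L; next }
        if (peek(p) == ")") { p <- p + 1L; break }
        stop("expected ',' or ')' at position ", p, call. = FALSE)
      }
      lab <- parse_label(p)
      len <- parse_length(lab$pos)
      node <- pf_node(children = children, length = len$length)
      if (nzchar(lab$label)) {
        if (!lab$quoted && is_numeric_token(lab$label))
          node$support <- as.numeric(lab$label)
        else
          node$label <- lab$label
      }
      list(node = node, pos = len$pos)
    } else {
      lab <- parse_label(p)
      if (!nzchar(lab$label))
        stop("expected a leaf label at position ", p, call. = FALSE)
      len <- parse_length(lab$pos)
      list(node = pf_node(label = lab$label, length = len$length), pos = len$pos)
    }
  }

  res <- parse_subtree(pos)
  p <- skip_ws(text, res$pos)
  if (peek(p) != ";")
    stop("missing ';' terminator at position ", p, call. = FALSE)
  tree <- as_phytree(res$node)
  lv <- tree_leaves(tree)
  dup <- lv[duplicated(lv)]
  if (length(dup))
    stop("duplicate leaf label: ", dup[[1]], call. = FALSE)
  list(tree = tree, pos = p + 1L)
}

format_brlen <- function(x) {
  s <- format(x, digits = 15, scientific = FALSE, trim = TRUE)
  if (as.numeric(s) != x) s <- sprintf("%.17g", x)
  s
}

quote_label <- function(label) {
  if (grepl(NEWICK_SPECIALS, label) || label == "")
    paste0("'", gsub("'", "''", label, fixed = TRUE), "'")
  else label
}

#' Serialize a tree to a Newick string
#'
#' Inverse of [parse_newick()]: the round trip preserves topology, labels,
#' branch lengths, support values and child order exactly.
#'
#' @param tree a `phytree`
#' @return a single Newick statement terminated by `;`
#' @export
write_newick <- function(tree) {
  emit <- function(node) {
    if (is_leaf(node)) {
      s <- quote_label(node$label)
    } else {
      s <- paste0("(", paste(vapply(node$children, emit, character(1)),
                             collapse = ","), ")")
      if (nzchar(node$label)) s <- paste0(s, quote_label(node$label))
      else if (!is.na(node$support)) s <- paste0(s, format_brlen(node$support))
    }
    if (!is.na(node$length)) s <- paste0(s, ":", format_brlen(node$length))
    s
  }
  paste0(emit(tree), ";")
}

#' Write trees to a Newick file
#'
#' @param trees a `phytree` or list of them
#' @param path output path; one statement per line
#' @return `path`, invisibly
#' @export
write_newick_file <- function(trees, path) {
  if (inherits(trees, "phytree")) trees <- list(trees)
  writeLines(vapply(trees, write_newick, character(1)), path)
  invisible(path)
}

# -- annotation sidecar (taxon,key,value CSV) ---------------------------------

#' Collect per-leaf annotations as a data frame
#'
#' @param tree a `phytree`
#' @return data.frame with columns `taxon`, `key`, `value`
#' @export
annotations_df <- function(tree) {
  rows <- list()
  walk <- function(node) {
    if (is_leaf(node)) {
      if (length(node$annot))
        rows[[length(rows) + 1L]] <<- data.frame(
          taxon = node$label, key = names(node$annot),
          value = unname(node$annot), stringsAsFactors = FALSE)
    } else lapply(node$children, walk)
  }
  walk(tree)
  if (!length(rows))
    return(data.frame(taxon = character(0), key = character(0),
                      value = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Write leaf annotations to a CSV sidecar
#' @param tree a `phytree`
#' @param path output CSV path (columns taxon,key,value)
#' @return `path`, invisibly
#' @export
write_annotations <- function(tree, path) {
  write.csv(annotations_df(tree), path, row.names = FALSE)
  invisible(path)
}

#' Apply annotations from a CSV sidecar to a tree
#' @param tree a `phytree`
#' @param path CSV path with columns taxon,key,value
#' @return the annotated tree
#' @export
read_annotations <- function(tree, path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  as_phytree(map_leaves(tree, function(leaf) {
    hit <- df[df$taxon == leaf$label, , drop = FALSE]
    if (nrow(hit)) {
      ann <- as.character(hit$value)
      names(ann) <- hit$key
      leaf$annot[names(ann)] <- ann
    }
    leaf
  }))
}
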