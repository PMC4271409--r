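# -- minimal SVG export -------------------------------------------------------
#
# Rectangular phylogram layout only: branch lengths are drawn when every
# branch has one, otherwise unit lengths are used. Rendering is pure: the
# same inputs always produce byte-identical SVG.

#' Rendering options
#'
#' @param orientation `"right"` (tips to the right) or `"face_to_face"` (for
#'   pairs: second tree mirrored so tip labels face inward)
#' @param spacing vertical distance between adjacent leaves, in pixels
#' @param font_size leaf label font size, in pixels
#' @param shade_color fill used for leaves outside the agreement consensus
#' @return a `render_spec`
#' @export
render_spec <- function(orientation = c("right", "face_to_face"),
                        spacing = 18, font_size = 12,
                        shade_color = "#b8b8b8") {
  orientation <- match.arg(orientation)
  stopifnot(spacing > 0, font_size > 0)
  structure(list(orientation = orientation, spacing = spacing,
                 font_size = font_size, shade_color = shade_color),
            class = "render_spec")
}

svg_num <- function(x) sprintf("%.2f", x)

# Geometry of one tree: per-leaf (x, y, label) and line segments.
tree_geometry <- function(tree, spec, tree_width = 260) {
  has_all_lengths <- local({
    ok <- TRUE
    walk <- function(node, at_root) {
      if (!at_root && is.na(node$length)) ok <<- FALSE
      for (ch in node$children) walk(ch, FALSE)
    }
    walk(tree, TRUE)
    ok
  })
  leaves <- list(); segs <- list()
  counter <- new.env(parent = emptyenv()); counter$i <- 0
  place <- function(node, depth) {
    if (is_leaf(node)) {
      counter$i <- counter$i + 1
      y <- counter$i * spec$spacing
      leaves[[length(leaves) + 1L]] <<- list(x = depth, y = y, node = node)
      return(y)
    }
    ys <- vapply(node$children, function(ch) {
      step <- if (has_all_lengths) ch$length else 1
      cy <- place(ch, depth + step)
      segs[[length(segs) + 1L]] <<- list(x1 = depth, y1 = cy,
                                         x2 = depth + step, y2 = cy,
                                         node = ch)
      cy
    }, numeric(1))
    segs[[length(segs) + 1L]] <<- list(x1 = depth, y1 = min(ys),
                                       x2 = depth, y2 = max(ys), node = node)
    mean(range(ys))
  }
  place(tree, 0)
  max_depth <- max(vapply(leaves, `[[`, numeric(1), "x"), 1e-9)
  scale <- tree_width / max_depth
  rescale <- function(e) { e$x1 <- e$x1 * scale; e$x2 <- e$x2 * scale; e }
  list(leaves = lapply(leaves, function(l) { l$x <- l$x * scale; l }),
       segs = lapply(segs, rescale),
       height = (counter$i + 1) * spec$spacing)
}

leaf_fill <- function(node, classes, spec) {
  cls <- if (!is.null(classes)) classes[[node$label]] else "in_consensus"
  if (!is.null(classes) && cls != "in_consensus") return(spec$shade_color)
  col <- node$annot["color"]
  if (length(col) == 1 && !is.na(col)) unname(col) else "#000000"
}

# TRUE for nodes whose every leaf is outside the consensus (greyed edges).
node_all_shaded <- function(node, classes) {
  if (is.null(classes)) return(FALSE)
  all(classes[tree_leaves(node)] != "in_consensus")
}

render_group <- function(tree, spec, classes, x0, y0, mirror = FALSE,
                         tree_width = 260, label_pad = 6, label_space = 110) {
  geo <- tree_geometry(tree, spec, tree_width)
  px <- function(x) if (mirror) x0 + tree_width + label_space - x
                    else x0 + x
  out <- character(0)
  for (s in geo$segs) {
    stroke <- if (node_all_shaded(s$node, classes)) spec$shade_color
              else "#000000"
    out <- c(out, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="1"/>',
      svg_num(px(s$x1)), svg_num(y0 + s$y1), svg_num(px(s$x2)),
      svg_num(y0 + s$y2), stroke))
  }
  for (l in geo$leaves) {
    fill <- leaf_fill(l$node, classes, spec)
    anchor <- if (mirror) "end" else "start"
    tx <- if (mirror) px(l$x) - label_pad else px(l$x) + label_pad
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-size="%s" text-anchor="%s" fill="%s">%s</text>',
      svg_num(tx), svg_num(y0 + l$y + spec$font_size * 0.35),
      svg_num(spec$font_size), anchor, fill, xml_escape(l$node$label)))
  }
  list(svg = out, height = geo$height,
       width = tree_width + label_space)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

svg_document <- function(body, width, height) {
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                        'width="%s" height="%s" version="1.1">\n'),
                 svg_num(width), svg_num(height)),
         paste(body, collapse = "\n"),
         "\n</svg>\n")
}

#' Render a tree as an SVG document
#'
#' One text element per leaf, vertical positions following child order.
#' Leaf `color` annotations are honored; when an agreement classification is
#' given, leaves classed `conflicting` or `tree_specific` (and the edges of
#' subtrees made entirely of such leaves) use the shading color, while
#' `in_consensus` leaves keep their own color.
#'
#' @param tree a `phytree`
#' @param spec a [render_spec()]
#' @param agreement optional `agreement` from [mast()]
#' @param tree_index which side of the agreement this tree is (1 or 2)
#' @return character(1): a well-formed SVG 1.1 document
#' @export
render_svg <- function(tree, spec = render_spec(), agreement = NULL,
                       tree_index = 1L) {
  classes <- if (!is.null(agreement)) agreement$classes[[tree_index]] else NULL
  g <- render_group(tree, spec, classes, x0 = 10, y0 = 0)
  svg_document(g$svg, width = g$width + 20, height = g$height + 10)
}

#' Render two trees side by side or face to face
#'
#' In `face_to_face` orientation the second tree is mirrored so that tip
#' labels face inward; otherwise both trees share the same orientation.
#'
#' @param t1,t2 `phytree` objects
#' @param spec a [render_spec()]
#' @param agreement optional `agreement` from [mast()]; shading is applied to
#'   each side with its own classification
#' @return character(1): a well-formed SVG 1.1 document
#' @export
render_pair <- function(t1, t2, spec = render_spec(), agreement = NULL) {
  c1 <- if (!is.null(agreement)) agreement$classes[[1]] else NULL
  c2 <- if (!is.null(agreement)) agreement$classes[[2]] else NULL
  g1 <- render_group(t1, spec, c1, x0 = 10, y0 = 0)
  mirror <- spec$orientation == "face_to_face"
  x2 <- 10 + g1$width + 60
  g2 <- render_group(t2, spec, c2, x0 = x2, y0 = 0, mirror = mirror)
  svg_document(c(g1$svg, g2$svg),
               width = x2 + g2$width + 20,
               height = max(g1$height, g2$height) + 10)
}
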