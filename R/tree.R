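#' Rooted mutation-labelled tree node
#'
#' The package's tree dialect: a recursive list. Each node carries the
#' variants on the edge to its parent (`edge_variants`, empty at the root),
#' a list of child nodes, and — at tips only — the sample id. Samples
#' sitting on internal haplotypes are attached as zero-mutation tip
#' children, so rho sees their zero-length paths.
#'
#' @param node_id node identifier (unique within the tree).
#' @param edge_variants variant data.frame on the edge to the parent.
#' @param children list of `phylo_node` children.
#' @param tip_samples character vector (length 1 at tips, empty otherwise).
#' @param clade_label optional haplogroup label.
#' @return object of class `phylo_node`.
#' @export
phylo_node <- function(node_id, edge_variants = empty_variants(),
                       children = list(), tip_samples = character(),
                       clade_label = NA_character_) {
  structure(list(node_id = as.character(node_id),
                 edge_variants = edge_variants,
                 children = children,
                 tip_samples = as.character(tip_samples),
                 clade_label = clade_label),
            class = "phylo_node")
}

is_tip <- function(node) length(node$children) == 0L

#' Sample ids at the tips below a node
#' @param node phylo_node.
#' @return character vector of sample ids.
#' @export
tips_below <- function(node) {
  if (is_tip(node)) return(node$tip_samples)
  unlist(lapply(node$children, tips_below), use.names = FALSE)
}

#' Number of tips below a node
#' @param node phylo_node.
#' @export
n_tips <- function(node) length(tips_below(node))

#' Find a node by id
#' @param tree phylo_node root.
#' @param node_id id to find.
#' @return the subtree rooted at `node_id`, or NULL.
#' @export
find_node <- function(tree, node_id) {
  if (identical(tree$node_id, node_id)) return(tree)
  for (ch in tree$children) {
    hit <- find_node(ch, node_id)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

#' All node ids of a tree
#' @param tree phylo_node root.
#' @export
node_ids <- function(tree) {
  c(tree$node_id, unlist(lapply(tree$children, node_ids),
                         use.names = FALSE))
}

#' @export
print.phylo_node <- function(x, ...) {
  cat("<phylo_node> rooted tree at", x$node_id, "with", n_tips(x),
      "tip(s) and", length(node_ids(x)), "node(s)\n")
  invisible(x)
}

#' Newick serialization of a mutation-labelled tree
#'
#' Branch lengths are the number of variants on each edge; internal nodes
#' are labelled with their ids and the edge variant labels are appended to
#' node labels after "|" so the mutation placement survives a text
#' round-trip.
#'
#' @param tree phylo_node root.
#' @param annotate_variants append variant labels to node labels.
#' @return newick string (terminated with ";").
#' @export
to_newick <- function(tree, annotate_variants = TRUE) {
  lab <- function(node) {
    base <- if (is_tip(node)) node$tip_samples else node$node_id
    base <- gsub("[(),:;[:space:]]", "_", base)
    if (annotate_variants && nrow(node$edge_variants) > 0L) {
      base <- paste0(base, "|",
                     paste(variant_labels(node$edge_variants),
                           collapse = "/"))
    }
    base
  }
  rec <- function(node) {
    bl <- nrow(node$edge_variants)
    if (is_tip(node)) return(paste0(lab(node), ":", bl))
    paste0("(", paste(vapply(node$children, rec, character(1)),
                      collapse = ","),
           ")", lab(node), ":", bl)
  }
  paste0(rec(tree), ";")
}

#' Convert to an ape "phylo" tree
#'
#' Uses the newick serialization; branch lengths count mutations per edge.
#'
#' @param tree phylo_node root.
#' @return ape phylo object.
#' @export
as_phylo <- function(tree) {
  ape::read.tree(text = to_newick(tree, annotate_variants = FALSE))
}

#' Edge list of a mutation-labelled tree
#' @param tree phylo_node root.
#' @param path optional TSV output path.
#' @return data.frame parent, child, n_variants, variants.
#' @export
tree_edge_list <- function(tree, path = NULL) {
  rows <- list()
  walk <- function(node) {
    for (ch in node$children) {
      rows[[length(rows) + 1L]] <<- data.frame(
        parent = node$node_id,
        child = if (is_tip(ch)) ch$tip_samples else ch$node_id,
        n_variants = nrow(ch$edge_variants),
        variants = paste(variant_labels(ch$edge_variants), collapse = " "),
        stringsAsFactors = FALSE)
      walk(ch)
    }
  }
  walk(tree)
  out <- if (length(rows) == 0L) {
    data.frame(parent = character(), child = character(),
               n_variants = integer(), variants = character())
  } else do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
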