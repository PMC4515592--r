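#' Founder age of a designated node in a sink region
#'
#' Dates the arrival of lineages in a sink region: rho and sigma are computed
#' exactly as for clade dating but only tips whose region equals
#' `sink_region` contribute mutations and counts, and the age is converted
#' with the supplied (typically fragment-scaled HVS-I) clock. On a node whose
#' descendants are all sink tips this reduces to the plain clade age.
#'
#' @param tree [phylo_node()] root.
#' @param founder_node node id of the designated founder haplotype.
#' @param sink_region region label of the sink (e.g. "Eastern").
#' @param clk [clock()] object.
#' @param regions named character vector mapping sample ids to region labels.
#' @return object of class `founder_result`: a `rho_estimate` row with
#'   `sink_region` and `n_sink_tips` columns.
#' @export
founder_age <- function(tree, founder_node, sink_region, clk, regions) {
  stopifnot(inherits(clk, "clock"), !is.null(names(regions)))
  filt <- function(s) isTRUE(unname(regions[s]) == sink_region)
  node <- find_node(tree, founder_node)
  if (is.null(node)) stop("founder node '", founder_node, "' not in tree")
  n_sink <- sum(vapply(tips_below(node), filt, logical(1)))
  if (n_sink == 0L) {
    stop("no ", sink_region, " tips below node ", founder_node)
  }
  est <- date_node(tree, clk, node_id = founder_node, tip_filter = filt)
  est$sink_region <- sink_region
  est$n_sink_tips <- as.integer(n_sink)
  class(est) <- c("founder_result", class(est))
  est
}

#' Propose founder-node candidates between a source and a sink region
#'
#' Heuristic stand-in for the by-eye choice of "main nodes": a node qualifies
#' when (a) it subtends at least `min_sink_tips` sink-region tips and (b) its
#' own haplotype state is observed in, or ancestral to, a source-region tip
#' (its root-to-node variant set is a subset of some source tip's variant
#' set). Because every ancestor of a qualifying node also qualifies, only
#' minimal qualifying nodes (those with no qualifying descendant) are
#' returned by default. In a tree with no source tips at all only the root
#' can qualify. Results are sorted by the number of subtended sink tips,
#' descending.
#'
#' @param tree [phylo_node()] root.
#' @param regions named character vector mapping sample ids to regions.
#' @param source_region,sink_region region labels.
#' @param min_sink_tips minimum sink tips a candidate must subtend.
#' @param minimal return only minimal qualifying nodes.
#' @return data.frame with columns `node_id`, `n_sink_tips`, `state`
#'   (the node's variant labels, space-separated); zero rows when no node
#'   qualifies.
#' @export
scan_founder_candidates <- function(tree, regions, source_region,
                                    sink_region, min_sink_tips = 3L,
                                    minimal = TRUE) {
  stopifnot(!is.null(names(regions)))
  region_of <- function(s) unname(regions[s])
  all_tips <- tips_below(tree)
  source_tips <- all_tips[region_of(all_tips) %in% source_region]
  # variant-label state of every source tip (root-to-tip accumulation)
  source_states <- list()
  collect <- function(node, acc) {
    acc <- c(acc, variant_labels(node$edge_variants))
    if (is_tip(node) && node$tip_samples %in% source_tips) {
      source_states[[length(source_states) + 1L]] <<- acc
    }
    for (ch in node$children) collect(ch, acc)
  }
  collect(tree, character())

  rows <- list()
  # returns TRUE when a qualifying node exists at or below `node`
  walk <- function(node, acc, is_root) {
    acc <- c(acc, variant_labels(node$edge_variants))
    qualifying_below <- FALSE
    for (ch in node$children) {
      qualifying_below <- walk(ch, acc, FALSE) || qualifying_below
    }
    sink_n <- sum(region_of(tips_below(node)) == sink_region, na.rm = TRUE)
    ancestral <- if (length(source_states) == 0L) {
      is_root
    } else {
      any(vapply(source_states, function(st) all(acc %in% st), logical(1)))
    }
    qualifies <- sink_n >= min_sink_tips && ancestral
    if (qualifies && !(minimal && qualifying_below)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        node_id = node$node_id, n_sink_tips = as.integer(sink_n),
        state = paste(acc, collapse = " "), stringsAsFactors = FALSE)
    }
    qualifies || qualifying_below
  }
  walk(tree, character(), TRUE)
  out <- if (length(rows) == 0L) {
    data.frame(node_id = character(), n_sink_tips = integer(),
               state = character(), stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  out[order(-out$n_sink_tips, out$node_id), , drop = FALSE]
}

#' Founder report table
#'
#' Runs [founder_age()] for several designated nodes and assembles the
#' report (node, sink lineages, rho, sigma, age, CI).
#'
#' @param tree phylo_node root.
#' @param founder_nodes character vector of node ids.
#' @param sink_region sink region label.
#' @param clk clock object.
#' @param regions named sample-to-region vector.
#' @param path optional TSV output path.
#' @return data.frame of founder results.
#' @export
founder_report <- function(tree, founder_nodes, sink_region, clk, regions,
                           path = NULL) {
  out <- do.call(rbind, lapply(founder_nodes, function(fn) {
    founder_age(tree, fn, sink_region, clk, regions)
  }))
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
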