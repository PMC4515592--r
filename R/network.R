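#' Binary haplotype matrix for network construction
#'
#' Encodes haplotypes as a 0/1 matrix over their variants (0 = reference
#' state, 1 = derived). Invariant columns (carried by none or by every
#' haplotype) are dropped, identical haplotypes are collapsed with their
#' sample ids kept as multiplicity, and each column gets a weight equal to
#' the inverse of the variant's relative frequency across input haplotypes,
#' binned to the integers 1-99 (rare mutations weigh more, fast/frequent
#' mutations weigh less).
#'
#' @param haplotypes list of [haplotype()] objects.
#' @param add_reference append an all-zero (ancestral/reference) row when no
#'   observed haplotype equals the reference state; it becomes the natural
#'   root for [extract_tree()].
#' @return object of class `haplo_matrix` with elements `mat`, `variants`
#'   (one row per column), `weights`, `samples` (list per row), `observed`.
#' @export
haplotype_matrix <- function(haplotypes, add_reference = TRUE) {
  stopifnot(length(haplotypes) >= 1L)
  keysets <- lapply(haplotypes, function(h) variant_keys(h$variants))
  all_keys <- sort(unique(unlist(keysets)))
  n <- length(haplotypes)
  mat <- matrix(0L, nrow = n, ncol = length(all_keys),
                dimnames = list(NULL, all_keys))
  for (i in seq_len(n)) mat[i, keysets[[i]]] <- 1L
  freq <- colMeans(mat)
  keep <- freq > 0 & freq < 1
  mat <- mat[, keep, drop = FALSE]
  freq <- freq[keep]
  weights <- pmin(99L, pmax(1L, as.integer(round(1 / freq))))
  vall <- do.call(rbind, lapply(haplotypes, function(h) h$variants))
  vall <- vall[!duplicated(variant_keys(vall)), , drop = FALSE]
  rownames(vall) <- variant_keys(vall)
  variants <- vall[colnames(mat), , drop = FALSE]
  # collapse identical rows, keep sample multiplicity
  pat <- apply(mat, 1, paste, collapse = "")
  ids <- vapply(haplotypes, `[[`, character(1), "sample_id")
  upat <- unique(pat)
  umat <- mat[match(upat, pat), , drop = FALSE]
  samples <- lapply(upat, function(p) ids[pat == p])
  observed <- rep(TRUE, length(upat))
  if (add_reference && !any(rowSums(umat) == 0L)) {
    umat <- rbind(umat, 0L)
    samples <- c(samples, list(character()))
    observed <- c(observed, FALSE)
  }
  rownames(umat) <- ifelse(rowSums(umat) == 0L, "reference",
                           paste0("H", cumsum(rowSums(umat) > 0L)))
  structure(list(mat = umat, variants = variants, weights = weights,
                 samples = stats::setNames(samples, rownames(umat)),
                 observed = stats::setNames(observed, rownames(umat))),
            class = "haplo_matrix")
}

# group identical column patterns into character classes; a class is a set
# of variants that always co-occur and therefore share one network edge
.character_classes <- function(mat, weights) {
  pat <- apply(mat, 2, paste, collapse = "")
  cls_of <- match(pat, unique(pat))
  lapply(seq_along(unique(pat)), function(k) {
    cols <- which(cls_of == k)
    list(columns = colnames(mat)[cols],
         pattern = mat[, cols[1]],
         weight = weights[cols[1]],
         recurrent = FALSE)
  })
}

.incompatible <- function(a, b) {
  g <- unique(paste0(a, b))
  all(c("00", "01", "10", "11") %in% g)
}

#' Build a reduced-median network
#'
#' Implements reduced-median construction for binary haplotype data. First,
#' character conflicts between columns of very unequal weight are resolved:
#' whenever two characters are incompatible (all four gametes present) and
#' their weight ratio reaches `reduction_threshold`, the lower-weight
#' (more frequently mutating) character is split into two independent
#' single-origin copies — i.e. it is declared recurrent — which removes the
#' conflict. Remaining conflicts are resolved by median (majority-of-three)
#' closure, which adds inferred median vectors; the network then links every
#' pair of nodes with no third node metrically between them, so
#' pairwise-compatible data yield exactly the unique perfect phylogeny and
#' an unresolved two-character conflict yields the classic four-cycle.
#'
#' @param hm [haplotype_matrix()] object.
#' @param reduction_threshold weight ratio at which a conflict is resolved
#'   by declaring the lower-weight character recurrent (default 2).
#' @param max_nodes safety cap on the median closure.
#' @return object of class `haplo_network`: `nodes` (pattern matrix over
#'   character classes), `node_ids`, `observed`, `samples`, `edges`
#'   (data.frame from, to, n_variants), `edge_classes` (list of class
#'   indices per edge), `classes` (list with `columns`, `weight`,
#'   `recurrent`), `variants` (per-column variant table), `n_median`.
#' @export
build_reduced_median <- function(hm, reduction_threshold = 2,
                                 max_nodes = 4096L) {
  stopifnot(inherits(hm, "haplo_matrix"))
  classes <- .character_classes(hm$mat, hm$weights)
  # --- reduction: split recurrent low-weight characters -------------------
  repeat {
    n_c <- length(classes)
    if (n_c < 2L) break
    best <- NULL
    for (i in seq_len(n_c - 1L)) for (j in (i + 1L):n_c) {
      if (!.incompatible(classes[[i]]$pattern, classes[[j]]$pattern)) next
      wi <- classes[[i]]$weight; wj <- classes[[j]]$weight
      ratio <- max(wi, wj) / min(wi, wj)
      if (ratio >= reduction_threshold &&
          (is.null(best) || ratio > best$ratio)) {
        best <- list(i = i, j = j, ratio = ratio)
      }
    }
    if (is.null(best)) break
    lo <- if (classes[[best$i]]$weight <= classes[[best$j]]$weight) {
      best$i
    } else best$j
    hi <- setdiff(c(best$i, best$j), lo)
    p_lo <- classes[[lo]]$pattern
    p_hi <- classes[[hi]]$pattern
    split1 <- as.integer(p_lo & p_hi)
    split2 <- as.integer(p_lo & !p_hi)
    base <- classes[[lo]]
    classes[[lo]] <- NULL
    classes <- c(classes,
                 list(modifyList(base, list(pattern = split1,
                                            recurrent = TRUE)),
                      modifyList(base, list(pattern = split2,
                                            recurrent = TRUE))))
  }
  cmat <- if (length(classes) > 0L) {
    do.call(cbind, lapply(classes, `[[`, "pattern"))
  } else {
    matrix(0L, nrow = nrow(hm$mat), ncol = 0L)
  }
  rownames(cmat) <- rownames(hm$mat)

  # --- median closure -----------------------------------------------------
  nodes <- if (ncol(cmat) == 0L) cmat[1L, , drop = FALSE] else unique(cmat)
  repeat {
    n <- nrow(nodes)
    if (n > max_nodes) stop("median closure exceeded max_nodes")
    added <- FALSE
    if (n >= 3L) {
      existing <- new.env(hash = TRUE)
      for (i in seq_len(n)) {
        assign(paste(nodes[i, ], collapse = ""), TRUE, envir = existing)
      }
      for (i in seq_len(n - 2L)) for (j in (i + 1L):(n - 1L)) {
        for (k in (j + 1L):n) {
          med <- as.integer(nodes[i, ] + nodes[j, ] + nodes[k, ] >= 2L)
          key <- paste(med, collapse = "")
          if (!exists(key, envir = existing, inherits = FALSE)) {
            nodes <- rbind(nodes, med)
            assign(key, TRUE, envir = existing)
            added <- TRUE
          }
        }
      }
    }
    if (!added) break
  }

  # --- node bookkeeping ----------------------------------------------------
  obs_pat <- apply(cmat, 1, paste, collapse = "")
  node_pat <- apply(nodes, 1, paste, collapse = "")
  node_ids <- character(nrow(nodes))
  observed <- node_pat %in% obs_pat
  node_ids[observed] <- rownames(cmat)[match(node_pat[observed], obs_pat)]
  node_ids[!observed] <- paste0("M", seq_len(sum(!observed)))
  rownames(nodes) <- node_ids
  samples <- stats::setNames(vector("list", length(node_ids)), node_ids)
  for (id in node_ids) {
    samples[[id]] <- if (id %in% names(hm$samples)) hm$samples[[id]]
    else character()
  }

  # --- geodesic adjacency ---------------------------------------------------
  D <- as.matrix(stats::dist(nodes, method = "manhattan"))
  nn <- nrow(nodes)
  edges <- list()
  edge_classes <- list()
  if (nn > 1L) {
    for (i in seq_len(nn - 1L)) for (j in (i + 1L):nn) {
      d <- D[i, j]
      between <- any(D[i, -c(i, j)] + D[-c(i, j), j] == d)
      if (nn == 2L) between <- FALSE
      if (!between) {
        cls <- which(nodes[i, ] != nodes[j, ])
        edges[[length(edges) + 1L]] <- data.frame(
          from = node_ids[i], to = node_ids[j],
          n_variants = sum(vapply(classes[cls], function(cl) {
            length(cl$columns)
          }, integer(1))),
          stringsAsFactors = FALSE)
        edge_classes[[length(edges)]] <- cls
      }
    }
  }
  edges <- if (length(edges) > 0L) do.call(rbind, edges) else {
    data.frame(from = character(), to = character(),
               n_variants = integer())
  }
  structure(list(nodes = nodes, node_ids = node_ids, observed =
                   stats::setNames(observed, node_ids),
                 samples = samples, edges = edges,
                 edge_classes = edge_classes, classes = classes,
                 variants = hm$variants, n_median = sum(!observed)),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("<haplo_network>", nrow(x$nodes), "node(s) (", x$n_median,
      "median vector(s) ),", nrow(x$edges), "edge(s),",
      length(x$classes), "character class(es)\n")
  invisible(x)
}

# variants data.frame carried by a set of character classes, with a
# recurrent flag per row
.class_variants <- function(net, cls_idx) {
  out <- list()
  for (k in cls_idx) {
    cl <- net$classes[[k]]
    v <- net$variants[cl$columns, , drop = FALSE]
    v$recurrent <- cl$recurrent
    out[[length(out) + 1L]] <- v
  }
  v <- do.call(rbind, out)
  rownames(v) <- NULL
  v[order(v$position, v$subindex, v$alt), , drop = FALSE]
}

#' Extract a rooted, frequency-guided tree from a network
#'
#' Chooses one spanning tree of the network, rooted at an ancestral
#' haplotype. Edges are added Prim-style from the root with a deterministic
#' multi-key preference: fewest mutations first (so the extracted tree
#' attains minimum parsimony among spanning trees of the network), then the
#' smallest summed character weight — which places higher-frequency
#' (lower-weight) mutations deeper in the tree, mirroring frequency-guided
#' manual branching — then lexicographically by (position, derived base) and
#' node id. Samples are attached as zero-mutation tip children of their
#' haplotype node, and any position occurring more than once on a
#' root-to-tip path is flagged recurrent.
#'
#' @param net [build_reduced_median()] network.
#' @param root node id of the root haplotype (default "reference" when the
#'   ancestral row is part of the network).
#' @return [phylo_node()] rooted tree.
#' @export
extract_tree <- function(net, root = "reference") {
  ids <- net$node_ids
  if (!root %in% ids) stop("root haplotype '", root, "' is not in the network")
  ne <- nrow(net$edges)
  edge_weight <- vapply(seq_len(ne), function(e) {
    sum(vapply(net$classes[net$edge_classes[[e]]], `[[`, numeric(1),
               "weight"))
  }, numeric(1))
  edge_lab <- vapply(seq_len(ne), function(e) {
    v <- .class_variants(net, net$edge_classes[[e]])
    sprintf("%05d%s", v$position[1], v$alt[1])
  }, character(1))

  in_tree <- stats::setNames(rep(FALSE, length(ids)), ids)
  in_tree[root] <- TRUE
  children <- stats::setNames(vector("list", length(ids)), ids)
  edge_of <- stats::setNames(vector("list", length(ids)), ids)
  used <- rep(FALSE, ne)
  while (any(!in_tree)) {
    cand <- which(!used &
                    xor(in_tree[net$edges$from], in_tree[net$edges$to]))
    if (length(cand) == 0L) stop("network is not connected")
    new_node <- ifelse(in_tree[net$edges$from[cand]],
                       net$edges$to[cand], net$edges$from[cand])
    ord <- order(net$edges$n_variants[cand], edge_weight[cand],
                 edge_lab[cand], new_node)
    e <- cand[ord[1]]
    child <- unname(new_node[ord[1]])
    parent <- if (in_tree[net$edges$from[e]]) net$edges$from[e] else {
      net$edges$to[e]
    }
    parent <- unname(parent)
    in_tree[child] <- TRUE
    used[e] <- TRUE
    children[[parent]] <- c(children[[parent]], child)
    edge_of[[child]] <- net$edge_classes[[e]]
  }

  build <- function(id, edge_cls) {
    ev <- if (is.null(edge_cls)) empty_variants() else {
      .class_variants(net, edge_cls)
    }
    kids <- lapply(children[[id]], function(cid) build(cid, edge_of[[cid]]))
    for (s in sort(net$samples[[id]])) {
      kids[[length(kids) + 1L]] <- phylo_node(s, tip_samples = s)
    }
    phylo_node(id, edge_variants = ev, children = kids)
  }
  tree <- build(root, NULL)
  .flag_recurrent(tree, integer())
}

.flag_recurrent <- function(node, seen_positions) {
  ev <- node$edge_variants
  if (nrow(ev) > 0L) {
    if (!"recurrent" %in% names(ev)) ev$recurrent <- FALSE
    rec <- ev$position %in% seen_positions
    ev$recurrent <- ev$recurrent | rec
    node$edge_variants <- ev
    seen_positions <- c(seen_positions, ev$position)
  }
  node$children <- lapply(node$children, .flag_recurrent, seen_positions)
  node
}

#' Label clades of a mutation-labelled tree
#'
#' Each node whose accumulated root-to-node variant labels contain all of a
#' definition's labels receives that clade label; when several definitions
#' match, the most specific (largest) one wins, ties broken alphabetically.
#' Definitions that match no node raise a warning.
#'
#' @param tree [phylo_node()] root.
#' @param clade_definitions named list; each element a character vector of
#'   variant labels (as in [variant_labels()]) defining the clade.
#' @return the tree with `clade_label` set on matching nodes.
#' @export
annotate_clades <- function(tree, clade_definitions) {
  stopifnot(is.list(clade_definitions),
            !is.null(names(clade_definitions)))
  matched <- stats::setNames(rep(FALSE, length(clade_definitions)),
                             names(clade_definitions))
  walk <- function(node, acc) {
    acc <- c(acc, variant_labels(node$edge_variants))
    hits <- names(clade_definitions)[vapply(clade_definitions, function(d) {
      all(d %in% acc)
    }, logical(1))]
    if (length(hits) > 0L) {
      sizes <- lengths(clade_definitions[hits])
      hits <- hits[order(-sizes, hits)]
      node$clade_label <- hits[1]
      matched[hits] <<- TRUE
    }
    node$children <- lapply(node$children, walk, acc)
    node
  }
  tree <- walk(tree, character())
  if (any(!matched)) {
    warning("clade definition(s) matched no node: ",
            paste(names(matched)[!matched], collapse = ", "))
  }
  tree
}

#' Topmost node carrying a clade label
#'
#' @param tree annotated tree from [annotate_clades()].
#' @param label clade label.
#' @return node id, or NULL when the label is absent.
#' @export
clade_root <- function(tree, label) {
  if (identical(tree$clade_label, label)) return(tree$node_id)
  for (ch in tree$children) {
    hit <- clade_root(ch, label)
    if (!is.null(hit)) return(hit)
  }
  NULL
}
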