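# shared fixtures and independent oracles used across the suite

REF <- synthetic_reference()
REFV <- strsplit(REF, "")[[1]]

# substitutions at given positions, derived base = first non-reference base
mkvar <- function(pos) {
  if (length(pos) == 0L) return(empty_variants())
  pos <- as.integer(pos)
  variant_table(pos, ref = REFV[pos],
                alt = vapply(pos, function(q) {
                  setdiff(c("A", "C", "G", "T"), REFV[q])[1]
                }, character(1)))
}

mkhap <- function(id, pos, pop = "P", region = "other",
                  covered = c(1L, MT_GENOME_LENGTH)) {
  haplotype(id, mkvar(pos), population = pop, region = region,
            covered_range = covered)
}

# ---- rho / sigma oracles: explicit path enumeration --------------------

# mutation counts per root-to-tip path below a node, by walking every path
oracle_tip_paths <- function(node, counting = "all",
                             fragment_range = NULL) {
  count <- function(v) {
    v <- v[v$class == "substitution", , drop = FALSE]
    if (counting == "synonymous") {
      v <- v[!is.na(v$synonymous) & v$synonymous == "yes", , drop = FALSE]
    } else if (counting == "fragment") {
      v <- v[v$position >= fragment_range[1] &
               v$position <= fragment_range[2], , drop = FALSE]
    }
    nrow(v)
  }
  rec <- function(nd, acc) {
    if (length(nd$children) == 0L) {
      return(stats::setNames(acc, nd$tip_samples))
    }
    unlist(lapply(nd$children, function(ch) {
      rec(ch, acc + count(ch$edge_variants))
    }))
  }
  rec(node, 0)
}

oracle_rho <- function(node, ...) mean(oracle_tip_paths(node, ...))

# sigma by direct edge enumeration: sqrt( sum (n_e/n)^2 m_e )
oracle_sigma <- function(node, counting = "all", fragment_range = NULL) {
  count <- function(v) {
    v <- v[v$class == "substitution", , drop = FALSE]
    if (counting == "synonymous") {
      v <- v[!is.na(v$synonymous) & v$synonymous == "yes", , drop = FALSE]
    } else if (counting == "fragment") {
      v <- v[v$position >= fragment_range[1] &
               v$position <= fragment_range[2], , drop = FALSE]
    }
    nrow(v)
  }
  n <- length(tips_below(node))
  acc <- 0
  walk <- function(nd) {
    for (ch in nd$children) {
      acc <<- acc + (length(tips_below(ch)) / n)^2 * count(ch$edge_variants)
      walk(ch)
    }
  }
  walk(node)
  sqrt(acc)
}

# random mutation-labelled tree (recursive splitting), <= max_tips tips;
# positions unique within the tree (infinite sites)
random_tree <- function(max_tips = 50L, p_split = 0.6) {
  pool <- sample(MT_GENOME_LENGTH, 1200L)
  used <- 0L
  tip_i <- 0L
  node_i <- 0L
  take <- function(k) {
    out <- pool[(used + 1L):(used + k)]
    used <<- used + k
    out
  }
  build <- function(depth, budget) {
    m <- sample(0:3, 1L)
    ev <- if (m > 0L) mkvar(take(m)) else empty_variants()
    if (budget <= 1L || depth > 5L || stats::runif(1) > p_split) {
      tip_i <<- tip_i + 1L
      return(phylo_node(paste0("T", tip_i), edge_variants = ev,
                        tip_samples = paste0("T", tip_i)))
    }
    k <- sample(2:min(3L, budget), 1L)
    shares <- as.integer(stats::rmultinom(1, budget - k, rep(1, k))) + 1L
    node_i <<- node_i + 1L
    phylo_node(paste0("N", node_i), edge_variants = ev,
               children = lapply(shares, function(b) build(depth + 1L, b)))
  }
  node_i <- node_i + 1L
  phylo_node("root", children = lapply(1:2, function(i) {
    build(1L, sample.int(max(1L, max_tips %/% 2L), 1L))
  }))
}

# ---- brute-force AMOVA oracle (explicit double loops) -------------------

oracle_fst <- function(popA, popB, distance_mode = "haplotype_identity") {
  haps <- c(popA$members, popB$members)
  grp <- rep(c(1L, 2L), c(length(popA$members), length(popB$members)))
  n <- length(haps)
  d2 <- function(i, j) {
    ki <- variant_keys(haps[[i]]$variants)
    kj <- variant_keys(haps[[j]]$variants)
    if (distance_mode == "haplotype_identity") {
      as.numeric(!setequal(ki, kj))
    } else {
      length(setdiff(ki, kj)) + length(setdiff(kj, ki))
    }
  }
  ssd_total <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) ssd_total <- ssd_total + d2(i, j)
  ssd_total <- ssd_total / n
  ssd_within <- 0
  for (g in 1:2) {
    idx <- which(grp == g)
    ng <- length(idx)
    s <- 0
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (a < b) s <- s + d2(idx[a], idx[b])
    }
    ssd_within <- ssd_within + s / ng
  }
  msd_among <- (ssd_total - ssd_within) / 1
  msd_within <- ssd_within / (n - 2)
  n_prime <- (n - (length(popA$members)^2 + length(popB$members)^2) / n) / 1
  sigma_a <- (msd_among - msd_within) / n_prime
  sigma_a / (sigma_a + msd_within)
}

# ---- misc ---------------------------------------------------------------

procrustes_rmse <- function(Y, X) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(t(Yc) %*% Xc)
  R <- s$u %*% t(s$v)
  sqrt(mean((Yc %*% R - Xc)^2))
}

# root-to-node variant labels of a node (sorted), by path search
state_of <- function(tree, id) {
  rec <- function(node, acc) {
    acc <- c(acc, variant_labels(node$edge_variants))
    if (node$node_id == id) return(list(acc))
    out <- list()
    for (ch in node$children) out <- c(out, rec(ch, acc))
    out
  }
  r <- rec(tree, character())
  sort(r[[1]])
}

# exhaustive spanning-tree enumeration on a network's edge list; returns the
# minimum total n_variants over all spanning trees
oracle_min_parsimony <- function(net) {
  ids <- net$node_ids
  nn <- length(ids)
  ne <- nrow(net$edges)
  stopifnot(ne <= 20L)
  combos <- utils::combn(ne, nn - 1L)
  best <- Inf
  for (c_i in seq_len(ncol(combos))) {
    sel <- combos[, c_i]
    # connectivity check by union-find
    parent <- stats::setNames(ids, ids)
    find <- function(x) {
      while (parent[[x]] != x) x <- parent[[x]]
      x
    }
    acyclic <- TRUE
    for (e in sel) {
      a <- find(net$edges$from[e])
      b <- find(net$edges$to[e])
      if (a == b) {
        acyclic <- FALSE
        break
      }
      parent[[a]] <- b
    }
    if (acyclic) best <- min(best, sum(net$edges$n_variants[sel]))
  }
  best
}

# parsimony score of an extracted tree = total variants over its edges
tree_parsimony <- function(tree) {
  s <- nrow(tree$edge_variants)
  for (ch in tree$children) s <- s + tree_parsimony(ch)
  s
}
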