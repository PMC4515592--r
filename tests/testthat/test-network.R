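test_that("single haplotype gives a single-node, edgeless network", {
  hm <- haplotype_matrix(list(mkhap("s1", c(100, 200))))
  net <- build_reduced_median(hm)
  expect_equal(nrow(net$nodes), 1L)
  expect_equal(nrow(net$edges), 0L)
  expect_equal(net$n_median, 0L)
})

test_that("pairwise-compatible characters give the unique perfect phylogeny", {
  # 4 haplotypes, 3 mutually compatible characters, internal states observed
  haps <- list(mkhap("s1", integer()), mkhap("s2", 100),
               mkhap("s3", c(100, 200)), mkhap("s4", c(100, 300)))
  net <- build_reduced_median(haplotype_matrix(haps))
  expect_equal(net$n_median, 0L)
  expect_equal(nrow(net$edges), 3L)          # #edges = #characters
  expect_equal(nrow(net$nodes), 4L)
  tree <- extract_tree(net)
  # network already a tree: extraction keeps it, rooted at the reference
  expect_equal(tree$node_id, "reference")
  expect_equal(sort(tips_below(tree)), c("s1", "s2", "s3", "s4"))
  el <- tree_edge_list(tree)
  expect_equal(sum(el$n_variants), 3L)
})

test_that("the classic two-character incompatibility keeps a 4-cycle", {
  haps <- list(mkhap("s1", integer()), mkhap("s2", 100),
               mkhap("s3", 200), mkhap("s4", c(100, 200)))
  net <- build_reduced_median(haplotype_matrix(haps))
  # equal weights: conflict unresolved, 4 nodes, 4 edges, one cycle
  expect_equal(nrow(net$nodes), 4L)
  expect_equal(nrow(net$edges), 4L)
  expect_equal(net$n_median, 0L)
  deg <- table(c(net$edges$from, net$edges$to))
  expect_true(all(deg == 2L))
})

test_that("frequency-guided extraction resolves cycles against hotspots", {
  # character at 100 carried by 6 of 8 samples (weight 1), at 200 by 3
  # (weight 3); threshold 10 keeps the 4-cycle in the network, and the
  # extraction resolves it by duplicating the frequent (low-weight, hotspot)
  # character: position 100 appears on two edges, 200 on one, and the
  # frequent character defines the basal split
  haps <- c(lapply(1:4, function(i) mkhap(paste0("a", i), 100)),
            list(mkhap("b1", 200)),
            lapply(1:2, function(i) mkhap(paste0("c", i), c(100, 200))),
            list(mkhap("r", integer())))
  net <- build_reduced_median(haplotype_matrix(haps),
                              reduction_threshold = 10)
  expect_equal(nrow(net$edges), 4L)  # cycle retained in the network
  tree <- extract_tree(net)
  el <- tree_edge_list(tree)
  n100 <- sum(grepl("100[ACGT]", el$variants))
  n200 <- sum(grepl("200[ACGT]", el$variants))
  expect_equal(n100, 2L)
  expect_equal(n200, 1L)
  root_child_pos <- unlist(lapply(tree$children, function(ch) {
    ch$edge_variants$position
  }))
  expect_true(100L %in% root_child_pos)
  expect_equal(sort(tips_below(tree)),
               sort(vapply(haps, `[[`, character(1), "sample_id")))
})

test_that("strong weight imbalance resolves the conflict by splitting", {
  # same incompatibility, threshold 2, frequencies 6/8 vs 2/8:
  # weights ~1 vs 4, ratio >= 2 -> low-weight character declared recurrent
  haps <- c(lapply(1:4, function(i) mkhap(paste0("a", i), 100)),
            list(mkhap("b1", 200)),
            lapply(1:2, function(i) mkhap(paste0("c", i), c(100, 200))),
            list(mkhap("r", integer())))
  net <- build_reduced_median(haplotype_matrix(haps))
  expect_true(any(vapply(net$classes, `[[`, logical(1), "recurrent")))
  # the split removes the cycle: the network is a tree over its nodes
  expect_equal(nrow(net$edges), nrow(net$nodes) - 1L)
  tree <- extract_tree(net)
  # the recurrent position appears on two edges and is flagged
  el <- tree_edge_list(tree)
  rec_edges <- sum(vapply(strsplit(el$variants, " "), function(v) {
    any(grepl("100", v))
  }, logical(1)))
  expect_equal(rec_edges, 2L)
  flag <- c()
  walk <- function(nd) {
    if (nrow(nd$edge_variants) > 0L) {
      flag <<- c(flag, nd$edge_variants$recurrent[
        nd$edge_variants$position == 100L])
    }
    lapply(nd$children, walk)
  }
  walk(tree)
  expect_true(all(flag))
})

test_that("extraction is a minimum-parsimony spanning tree (exhaustive check)", {
  set.seed(41)
  for (rep in 1:8) {
    n <- sample(4:8, 1)
    npos <- sample(3:6, 1)
    pos <- sample(seq(100, 4000, by = 7), npos)
    haps <- lapply(seq_len(n), function(i) {
      mkhap(paste0("s", i), sort(sample(pos, sample(0:npos, 1))))
    })
    hm <- haplotype_matrix(haps)
    net <- build_reduced_median(hm, reduction_threshold = 100)
    if (nrow(net$edges) > 18L) next
    tree <- extract_tree(net)
    # spanning: every observed haplotype reachable, #edges = #nodes - 1
    expect_setequal(tips_below(tree),
                    vapply(haps, `[[`, character(1), "sample_id"))
    expect_equal(tree_parsimony(tree), oracle_min_parsimony(net))
  }
})

test_that("extract_tree reproduces a planted perfect phylogeny", {
  set.seed(43)
  for (rep in 1:5) {
    cfg <- sim_config(n_samples = 12, effective_size = 700,
                      seed = 600 + rep)
    sim <- simulate_panmictic(cfg)
    net <- build_reduced_median(haplotype_matrix(sim$haplotypes))
    tree <- extract_tree(net)
    # infinite-sites data is compatible: no cycles possible
    expect_equal(nrow(net$edges), nrow(net$nodes) - 1L)
    # rho from the extracted tree equals rho from the true tree: mutation
    # path lengths to every tip are preserved by the perfect phylogeny
    true_paths <- sort(oracle_tip_paths(sim$tree))
    got_paths <- sort(oracle_tip_paths(tree))
    expect_equal(got_paths, true_paths[names(got_paths)])
  }
})

test_that("root must be a network node", {
  net <- build_reduced_median(haplotype_matrix(list(mkhap("s1", 100),
                                                    mkhap("s2", 200))))
  expect_error(extract_tree(net, root = "nope"), "not in the network")
})

test_that("clade annotation labels subtrees, most specific label wins", {
  haps <- list(mkhap("s1", integer()), mkhap("s2", 100),
               mkhap("s3", c(100, 200)), mkhap("s4", c(100, 200, 300)))
  net <- build_reduced_median(haplotype_matrix(haps))
  tree <- extract_tree(net)
  defs <- list(L2 = variant_labels(mkvar(100)),
               L2a = variant_labels(mkvar(c(100, 200))))
  tree <- annotate_clades(tree, defs)
  l2 <- find_node(tree, clade_root(tree, "L2"))
  l2a <- find_node(tree, clade_root(tree, "L2a"))
  expect_setequal(tips_below(l2), c("s2", "s3", "s4"))
  expect_setequal(tips_below(l2a), c("s3", "s4"))
  expect_equal(l2a$clade_label, "L2a")  # nested: child more specific
  expect_warning(annotate_clades(tree, list(zzz = "A9999G")),
                 "matched no node")
})
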