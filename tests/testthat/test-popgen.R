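frag_hap <- function(id, pos, pop) {
  mkhap(id, pos, pop = pop, covered = HVS1_RANGE)
}
fixed_pop <- function(name, pos, n = 5) {
  population_sample(name, lapply(seq_len(n), function(i) {
    frag_hap(paste0(name, i), pos, name)
  }))
}

test_that("FST endpoints and brute-force AMOVA agreement", {
  A <- fixed_pop("A", 16100)
  B <- fixed_pop("B", 16200)
  A2 <- fixed_pop("A2", 16100)
  expect_equal(pairwise_fst(A, A2), 0)   # same haplotype fixed in both
  expect_equal(pairwise_fst(A, B), 1)    # different haplotypes fixed

  # 3:1 vs 1:3 mixture, against the explicit sum-of-squares oracle
  mixA <- population_sample("mA", c(
    lapply(1:3, function(i) frag_hap(paste0("a", i), 16100, "mA")),
    list(frag_hap("a4", 16200, "mA"))))
  mixB <- population_sample("mB", c(
    list(frag_hap("b1", 16100, "mB")),
    lapply(2:4, function(i) frag_hap(paste0("b", i), 16200, "mB"))))
  for (mode in c("haplotype_identity", "pairwise_differences")) {
    expect_equal(pairwise_fst(mixA, mixB, mode),
                 oracle_fst(mixA, mixB, mode), tolerance = 1e-12)
  }
  # symmetry
  expect_equal(pairwise_fst(mixA, mixB), pairwise_fst(mixB, mixA))

  # fragment mismatch is an error
  other <- population_sample("o", list(mkhap("o1", 100, pop = "o")))
  expect_error(pairwise_fst(A, other), "different fragments")
})

test_that("permutation test is deterministic, correct at the extremes", {
  A <- fixed_pop("A", 16100, n = 10)
  B <- fixed_pop("B", 16200, n = 10)
  same <- fixed_pop("C", 16100, n = 10)

  # identical single-haplotype populations: every permutation ties, p = 1
  expect_equal(permutation_pvalue(A, same, 99, seed = 5)$p_value, 1)

  # completely fixed different haplotypes: p below 0.05 at 999 permutations
  p <- permutation_pvalue(A, B, 999, seed = 5)$p_value
  expect_lt(p, 0.05)

  # determinism contract
  expect_identical(permutation_pvalue(A, B, 199, seed = 7),
                   permutation_pvalue(A, B, 199, seed = 7))
})

test_that("Bonferroni flags and Slatkin linearization", {
  expect_identical(bonferroni_significant(0.04, 0.05), TRUE)
  expect_identical(bonferroni_significant(c(0.01, rep(0.5, 9)), 0.05)[1],
                   FALSE)  # 0.01 > 0.05/10
  expect_identical(bonferroni_significant(c(0.004, rep(0.5, 9)), 0.05)[1],
                   TRUE)
  expect_equal(slatkin_linearize(c(0, 0.5, 0.2)), c(0, 1, 0.25))
  expect_equal(slatkin_linearize(-0.03), 0)  # negative estimates floored
  expect_error(slatkin_linearize(1), "undefined")
})

test_that("matrix builder returns symmetric matrices with unit diagonals", {
  pops <- list(fixed_pop("A", 16100, 8), fixed_pop("B", 16200, 8),
               fixed_pop("C", c(16100, 16300), 8))
  dm <- fst_matrix(pops, n_permutations = 99, seed = 2)
  expect_equal(dm$fst, t(dm$fst))
  expect_equal(diag(dm$fst), c(A = 0, B = 0, C = 0))
  expect_equal(dm$p_values, t(dm$p_values))
  off <- dm$linearized[1, 2]
  expect_equal(off, slatkin_linearize(min(dm$fst[1, 2], 1 - 1e-12)))
})

test_that("merging pools only populations the test cannot distinguish", {
  set.seed(71)
  cfg <- sim_config(seed = 81, scenario = "island_pair",
                    effective_size = 500, divergence = 0,
                    n_per_population = 30)
  ip <- simulate_island_pair(cfg)
  sameA <- population_sample("X1", ip$pop1$members)
  sameB <- population_sample("X2", ip$pop2$members)
  diffC <- fixed_pop("Y", 16345, n = 30)
  pops <- list(sameA, sameB, diffC)
  merged <- merge_nonsignificant(pops, list(c("X1", "X2"), c("X1", "Y")),
                                 alpha = 0.05, n_permutations = 499,
                                 seed = 4)
  nm <- vapply(merged, `[[`, character(1), "name")
  expect_true("X1+X2" %in% nm)       # same source population: pooled
  expect_true("Y" %in% nm)           # fixed different haplotype: kept
  # empty candidate list: identity
  expect_identical(merge_nonsignificant(pops, list()), pops)
})

test_that("null permutation p-values are super-uniform", {
  reps <- 120
  rej <- 0L
  for (i in seq_len(reps)) {
    cfg <- sim_config(seed = 9200 + i, scenario = "island_pair",
                      effective_size = 500, divergence = 0,
                      n_per_population = 30)
    ip <- simulate_island_pair(cfg)
    p <- permutation_pvalue(ip$pop1, ip$pop2, 199, seed = i)$p_value
    rej <- rej + (p <= 0.05)
  }
  expect_lte(rej / reps, 0.075)
})

test_that("S-stress MDS recovers a planted configuration", {
  set.seed(61)
  X <- matrix(stats::rnorm(12), 6, 2)
  D <- as.matrix(stats::dist(X))
  fit <- mds_sstress(D, k = 2)
  expect_lt(fit$s_stress, 1e-8)
  expect_lt(procrustes_rmse(fit$coordinates, X), 1e-6)
  expect_equal(colMeans(fit$coordinates), c(0, 0))  # centered

  # coincident points stay coincident
  D0 <- matrix(0, 3, 3)
  fit0 <- mds_sstress(D0, k = 1)
  expect_equal(as.numeric(fit0$coordinates), c(0, 0, 0))

  # two points in one dimension sit at exactly their distance
  D2 <- matrix(c(0, 3, 3, 0), 2, 2)
  fit2 <- mds_sstress(D2, k = 1)
  expect_equal(abs(diff(as.numeric(fit2$coordinates))), 3,
               tolerance = 1e-6)

  expect_error(mds_sstress(D2, k = 2), "smaller")

  # k = n - 1 on a Euclidean-embeddable matrix: near-zero stress
  X5 <- matrix(stats::rnorm(15), 5, 3)
  fit5 <- mds_sstress(as.matrix(stats::dist(X5)), k = 4)
  expect_lt(fit5$s_stress, 1e-6)
})

test_that("haplogroup composition: planted mixes, star fallback, errors", {
  cls <- list(L2 = variant_labels(mkvar(16100)),
              L2a = variant_labels(mkvar(c(16100, 16200))),
              L0 = variant_labels(mkvar(16300)))
  # 30/70 planted mixture of L2a and L0
  p1 <- population_sample("P1", c(
    lapply(1:3, function(i) frag_hap(paste0("x", i), c(16100, 16200), "P1")),
    lapply(4:10, function(i) frag_hap(paste0("x", i), 16300, "P1"))))
  tab <- haplogroup_composition(list(p1), cls)
  expect_equal(tab$L2a, 0.3)
  expect_equal(tab$L0, 0.7)
  expect_equal(sum(tab[, -1]), 1, tolerance = 1e-12)

  # an L2 lineage lacking any subclade motif is reported as L2*
  p2 <- population_sample("P2", list(frag_hap("y1", 16100, "P2")))
  tab2 <- haplogroup_composition(list(p2), cls)
  expect_equal(tab2[["L2*"]], 1)

  # all samples carrying one label's motif: frequency 1
  p3 <- population_sample("P3", lapply(1:4, function(i) {
    frag_hap(paste0("z", i), 16300, "P3")
  }))
  expect_equal(haplogroup_composition(list(p3), cls)$L0, 1)

  # contradictory classifier: disjoint top-level labels both match
  bad <- list(L2 = variant_labels(mkvar(16100)),
              L0 = variant_labels(mkvar(16100)))
  expect_error(haplogroup_composition(list(p2), bad), "disjoint top-level")

  # rows sum to one across several populations
  tab3 <- haplogroup_composition(list(p1, p2, p3), cls)
  expect_equal(rowSums(tab3[, -1]), rep(1, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
})
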