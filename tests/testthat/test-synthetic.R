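test_that("config validation and determinism under a fixed seed", {
  expect_error(sim_config(n_samples = 5), "seed")
  expect_error(sim_config(seed = 1, scenario = "source_sink",
                          founder_time_years = NULL), "founder_time")
  expect_error(sim_config(seed = 1, scenario = "source_sink",
                          founder_time_years = 5000, n_sink = 0),
               "sink samples")

  cfg <- sim_config(n_samples = 8, effective_size = 500, seed = 77)
  g1 <- simulate_genealogy(cfg)
  g2 <- simulate_genealogy(cfg)
  expect_identical(g1, g2)
  s1 <- drop_mutations(simulate_genealogy(cfg), cfg)
  s2 <- drop_mutations(simulate_genealogy(cfg), cfg)
  expect_identical(lapply(s1$haplotypes, `[[`, "variants"),
                   lapply(s2$haplotypes, `[[`, "variants"))
})

test_that("genealogies are clock-like: equal root-to-tip path years", {
  cfg <- sim_config(n_samples = 10, effective_size = 800, seed = 55)
  gen <- simulate_genealogy(cfg)
  nodes <- gen$nodes
  depth <- function(id) {
    d <- 0
    while (!is.na(nodes$parent[match(id, nodes$id)])) {
      p <- nodes$parent[match(id, nodes$id)]
      d <- d + nodes$time_years[match(p, nodes$id)] -
        nodes$time_years[match(id, nodes$id)]
      id <- p
    }
    d
  }
  tips <- nodes$id[!is.na(nodes$sample_id)]
  depths <- vapply(tips, depth, numeric(1))
  expect_equal(unname(depths), rep(gen$tmrca_years, length(tips)))
})

test_that("pairwise TMRCA matches the coalescent expectation E[T2] = 2Ne", {
  ne <- 500
  reps <- 800
  tm <- numeric(reps)
  for (i in seq_len(reps)) {
    cfg <- sim_config(n_samples = 2, effective_size = ne, seed = 10000 + i)
    tm[i] <- simulate_genealogy(cfg)$tmrca_years
  }
  gens <- mean(tm) / 25
  expect_lt(abs(gens - 2 * ne) / (2 * ne), 0.05)
})

test_that("mutations are infinite-sites, Poisson-dispersed, respect masks", {
  cfg <- sim_config(n_samples = 12, effective_size = 900, seed = 88,
                    masked_positions = 1:8000)
  sim <- simulate_panmictic(cfg)
  pos <- unlist(lapply(sim$haplotypes, function(h) h$variants$position))
  # no masked position is ever hit
  expect_true(all(pos > 8000))
  # infinite sites: a position is reused only through shared ancestry, so
  # the per-edge planted positions are globally unique
  edge_pos <- c()
  walk <- function(nd) {
    edge_pos <<- c(edge_pos, nd$edge_variants$position)
    lapply(nd$children, walk)
  }
  walk(sim$tree)
  expect_false(any(duplicated(edge_pos)))

  # rate 0: all haplotypes identical to the reference
  cfg0 <- sim_config(n_samples = 5, effective_size = 500, seed = 3,
                     substitution_rate = 0)
  sim0 <- simulate_panmictic(cfg0)
  expect_true(all(vapply(sim0$haplotypes, function(h) {
    nrow(h$variants) == 0L
  }, logical(1))))

  # Poisson dispersion of the total mutation count at fixed tree length
  cfgp <- sim_config(n_samples = 6, effective_size = 700, seed = 4)
  gen <- rescale_genealogy(simulate_genealogy(cfgp), 20000)
  counts <- vapply(1:300, function(i) {
    set.seed(20000 + i)
    sim <- drop_mutations(gen, cfgp, classify = FALSE)
    tot <- 0
    walk2 <- function(nd) {
      tot <<- tot + nrow(nd$edge_variants)
      lapply(nd$children, walk2)
    }
    walk2(sim$tree)
    tot
  }, numeric(1))
  ratio <- stats::var(counts) / mean(counts)
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.2)
})

test_that("rho is unbiased for a fixed TMRCA under the clock", {
  reps <- 120
  tm <- 25000
  rhos <- numeric(reps)
  for (i in seq_len(reps)) {
    cfg <- sim_config(n_samples = 20, effective_size = 1000,
                      seed = 11000 + i)
    gen <- rescale_genealogy(simulate_genealogy(cfg), tm)
    sim <- drop_mutations(gen, cfg, classify = FALSE)
    rhos[i] <- compute_rho(sim$tree)$rho
  }
  ages <- rhos * 3624
  se <- stats::sd(ages) / sqrt(reps)
  expect_lt(abs(mean(ages) - tm), 2 * se + 1e-9)
})

test_that("source-sink scenario plants a recoverable founder", {
  sc <- sim_config(n_samples = 25, effective_size = 2000, seed = 1234,
                   scenario = "source_sink", founder_time_years = 8000,
                   n_source = 15, n_sink = 10, sink_effective_size = 80)
  ss <- simulate_source_sink(sc)
  expect_equal(ss$founder_time_years, 8000)
  f <- find_node(ss$tree, ss$founder_node)
  expect_false(is.null(f))
  regs <- ss$regions[tips_below(f)]
  expect_true(all(c("Eastern", "Central") %in% regs))
  expect_equal(sum(ss$regions == "Eastern"), 10L)
  # an impossible founder time errors out after bounded retries
  bad <- sim_config(n_samples = 25, effective_size = 2000, seed = 5,
                    scenario = "source_sink", founder_time_years = 10,
                    n_source = 5, n_sink = 10,
                    sink_effective_size = 5000)
  expect_error(simulate_source_sink(bad, max_retries = 3), "founder time")
})

test_that("island pair: fst increases with divergence, 1 at d = 1", {
  fst <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(d) {
    cfg <- sim_config(seed = 99, scenario = "island_pair",
                      effective_size = 500, divergence = d,
                      n_per_population = 200)
    ip <- simulate_island_pair(cfg)
    pairwise_fst(ip$pop1, ip$pop2)
  }, numeric(1))
  expect_true(all(diff(fst) > 0))
  expect_equal(fst[5], 1)
})

test_that("simulation files round-trip through the pipeline readers", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_samples = 5, effective_size = 500, seed = 21,
                    scenario = "source_sink", founder_time_years = 6000,
                    n_source = 5, n_sink = 5, sink_effective_size = 60)
  ss <- simulate_source_sink(cfg)
  paths <- write_simulation(ss, dir)
  expect_true(all(file.exists(file.path(
    dir, c("samples.fasta", "samples.tsv", "true_tree.nwk",
           "truth.json")))))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$founder_time_years, 6000)
  nwk <- ape::read.tree(file.path(dir, "true_tree.nwk"))
  expect_equal(ape::Ntip(nwk), 10L)
})
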