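#' Simulation configuration
#'
#' Study conditions for the matrilineal (haploid) coalescent simulator.
#' Defaults mirror the analysis assumptions: a 25-year generation time and a
#' whole-molecule substitution rate of one substitution every 3,624 years per
#' lineage over 16,569 sites; mutations follow the infinite-sites model
#' (every mutation strikes a new, unmasked site).
#'
#' @param n_samples number of sampled lineages (>= 2).
#' @param effective_size female effective population size (haploid Ne, in
#'   individuals).
#' @param generation_years years per generation (default 25).
#' @param growth_rate exponential growth rate per generation, backwards in
#'   time the population shrinks at this rate (default 0: constant size).
#' @param substitution_rate substitutions per lineage per year over the
#'   simulated stretch (default 1/3,624).
#' @param genome_length number of sites (default 16,569).
#' @param site_range closed interval positions mutations may hit (defaults to
#'   the whole molecule; set to `HVS1_RANGE` for HVS-I simulations).
#' @param masked_positions sites mutations must avoid.
#' @param seed mandatory RNG seed.
#' @param scenario "panmictic", "source_sink" or "island_pair".
#' @param founder_time_years,n_founders,n_source,n_sink source_sink scenario:
#'   migration time, number of founding lineages, sample sizes per region.
#'   `effective_size` is the source Ne; `sink_effective_size` the sink deme's.
#' @param sink_effective_size sink deme Ne (default `effective_size / 10`).
#' @param source_region,sink_region region labels for the scenario.
#' @param divergence island_pair scenario knob in `[0, 1]`: probability an
#'   individual carries its population-private haplotype.
#' @param n_per_population island_pair sample size per population.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 20L, effective_size = 1000,
                       generation_years = 25, growth_rate = 0,
                       substitution_rate = 1 / 3624,
                       genome_length = MT_GENOME_LENGTH,
                       site_range = c(1L, genome_length),
                       masked_positions = integer(), seed,
                       scenario = c("panmictic", "source_sink",
                                    "island_pair"),
                       founder_time_years = NULL, n_founders = 1L,
                       n_source = 15L, n_sink = 10L,
                       sink_effective_size = effective_size / 10,
                       source_region = "Central", sink_region = "Eastern",
                       divergence = 0, n_per_population = 30L) {
  scenario <- match.arg(scenario)
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_samples >= 2L, effective_size > 0, generation_years > 0,
            substitution_rate >= 0, genome_length > 0,
            divergence >= 0, divergence <= 1)
  if (scenario == "source_sink") {
    if (is.null(founder_time_years) || founder_time_years <= 0) {
      stop("source_sink scenario needs a positive founder_time_years")
    }
    if (n_sink < 1L) stop("source_sink scenario needs sink samples")
    stopifnot(n_source >= 1L, n_founders >= 1L, sink_effective_size > 0)
  }
  structure(list(n_samples = as.integer(n_samples),
                 effective_size = effective_size,
                 generation_years = generation_years,
                 growth_rate = growth_rate,
                 substitution_rate = substitution_rate,
                 genome_length = as.integer(genome_length),
                 site_range = as.integer(site_range),
                 masked_positions = as.integer(masked_positions),
                 seed = as.integer(seed), scenario = scenario,
                 founder_time_years = founder_time_years,
                 n_founders = as.integer(n_founders),
                 n_source = as.integer(n_source),
                 n_sink = as.integer(n_sink),
                 sink_effective_size = sink_effective_size,
                 source_region = source_region, sink_region = sink_region,
                 divergence = divergence,
                 n_per_population = as.integer(n_per_population)),
            class = "sim_config")
}

# coalescent waiting time (in generations) for k lineages, starting at time
# t0 generations before present, under Ne(t) = Ne * exp(-growth * t)
# (backwards in time); solves the time-inhomogeneous exponential. The pair
# coalescence rate is 1 / (2 Ne), i.e. E[T2] = 2 Ne generations.
.coal_wait <- function(k, ne, growth, t0) {
  rate <- choose(k, 2) / (2 * ne)
  e <- stats::rexp(1)
  if (growth == 0) return(e / rate)
  # integral of rate * exp(growth * t) dt from t0 to t0 + w equals e
  log(exp(growth * t0) + e * growth / rate) / growth - t0
}

# genealogy container: data.frame of nodes (id, parent, time_years,
# sample_id, region) + tmrca; tips have time 0
.genealogy <- function(nodes, config) {
  structure(list(nodes = nodes,
                 tmrca_years = max(nodes$time_years),
                 config = config),
            class = "genealogy")
}

#' @export
print.genealogy <- function(x, ...) {
  cat("<genealogy>", sum(!is.na(x$nodes$sample_id)), "tips, TMRCA",
      round(x$tmrca_years), "years\n")
  invisible(x)
}

#' Simulate a clock-like coalescent genealogy
#'
#' Standard Kingman coalescent for a matrilineal locus: with k lineages the
#' waiting time to the next coalescence is exponential with rate
#' `choose(k,2) / (2 Ne)` per generation — so a pair coalesces after
#' 2 Ne generations on average — time-rescaled under exponential
#' growth, times are converted to years with the generation time, and all
#' tips sit at the present so every root-to-tip path length equals the TMRCA
#' (clock-like by construction). Deterministic given the config seed.
#'
#' @param config [sim_config()].
#' @return object of class `genealogy`.
#' @export
simulate_genealogy <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  .simulate_genealogy_impl(config)
}

.simulate_genealogy_impl <- function(config, n = config$n_samples,
                                     region = "other",
                                     sample_prefix = "S") {
  nodes <- data.frame(
    id = paste0(sample_prefix, seq_len(n)),
    parent = NA_character_, time_years = 0,
    sample_id = paste0(sample_prefix, seq_len(n)),
    region = region, stringsAsFactors = FALSE)
  active <- nodes$id
  t_gen <- 0
  next_internal <- 1L
  while (length(active) > 1L) {
    t_gen <- t_gen + .coal_wait(length(active), config$effective_size,
                                config$growth_rate, t_gen)
    pair <- sample(active, 2L)
    new_id <- paste0(sample_prefix, "N", next_internal)
    next_internal <- next_internal + 1L
    nodes <- rbind(nodes, data.frame(
      id = new_id, parent = NA_character_,
      time_years = t_gen * config$generation_years,
      sample_id = NA_character_, region = NA_character_,
      stringsAsFactors = FALSE))
    nodes$parent[match(pair, nodes$id)] <- new_id
    active <- c(setdiff(active, pair), new_id)
  }
  .genealogy(nodes, config)
}

#' Rescale a genealogy to a fixed TMRCA
#'
#' Multiplies all node times by `tmrca_years / current TMRCA`; used to
#' condition simulations on a known true age.
#'
#' @param gen genealogy.
#' @param tmrca_years target TMRCA in years.
#' @return rescaled genealogy.
#' @export
rescale_genealogy <- function(gen, tmrca_years) {
  stopifnot(inherits(gen, "genealogy"), gen$tmrca_years > 0)
  f <- tmrca_years / gen$tmrca_years
  gen$nodes$time_years <- gen$nodes$time_years * f
  gen$tmrca_years <- tmrca_years
  gen
}

#' Drop infinite-sites mutations on a genealogy
#'
#' Each branch receives a Poisson number of substitutions with mean
#' `substitution_rate x branch length in years`; positions are drawn without
#' replacement from the unmasked sites of `site_range` (infinite sites:
#' no position is reused within a replicate), and the derived base always
#' differs from the reference base. Synonymous status is classified against
#' the reference with the packaged annotation so synonymous-clock dating is
#' testable on simulated data.
#'
#' @param gen [simulate_genealogy()] result.
#' @param config the [sim_config()] used (defaults to the one in `gen`).
#' @param reference reference sequence string (default
#'   [synthetic_reference()]).
#' @param classify classify synonymy of the planted substitutions.
#' @return list of class `sim_result`: `tree` (mutation-labelled
#'   [phylo_node()], root id "root"), `haplotypes` (list of [haplotype()]),
#'   `genealogy`, `tmrca_years`, `regions` (named vector), plus any truth
#'   fields already present on the genealogy (e.g. founder node).
#' @export
drop_mutations <- function(gen, config = gen$config,
                           reference = synthetic_reference(),
                           classify = TRUE) {
  stopifnot(inherits(gen, "genealogy"))
  nodes <- gen$nodes
  refv <- strsplit(toupper(reference), "")[[1]]
  available <- setdiff(seq.int(config$site_range[1], config$site_range[2]),
                       config$masked_positions)
  root_id <- nodes$id[is.na(nodes$parent)]
  stopifnot(length(root_id) == 1L)
  branch_years <- gen$nodes$time_years[match(nodes$parent, nodes$id)] -
    nodes$time_years
  branch_years[is.na(branch_years)] <- 0
  counts <- stats::rpois(nrow(nodes), config$substitution_rate * branch_years)
  total <- sum(counts)
  if (total > length(available)) {
    stop("more mutations (", total, ") than available sites (",
         length(available), "); infinite-sites model violated")
  }
  pos <- if (total > 0L) sample(available, total) else integer()
  alts <- vapply(pos, function(p) {
    sample(setdiff(c("A", "C", "G", "T"), refv[p]), 1L)
  }, character(1))
  idx <- rep(seq_len(nrow(nodes)), counts)
  edge_variants <- lapply(seq_len(nrow(nodes)), function(i) {
    sel <- idx == i
    if (!any(sel)) return(empty_variants())
    v <- variant_table(pos[sel], ref = refv[pos[sel]], alt = alts[sel],
                       class = "substitution")
    if (classify) v <- classify_synonymous(v, reference) else v
  })
  names(edge_variants) <- nodes$id

  build <- function(id) {
    ch_ids <- nodes$id[!is.na(nodes$parent) & nodes$parent == id]
    kids <- lapply(ch_ids, build)
    sid <- nodes$sample_id[match(id, nodes$id)]
    phylo_node(if (id == root_id) "root" else id,
               edge_variants = edge_variants[[id]],
               children = kids,
               tip_samples = if (is.na(sid)) character() else sid)
  }
  tree <- build(root_id)

  # per-sample haplotypes: accumulate variants root -> tip
  haps <- list()
  regions <- character()
  acc <- function(node, vars) {
    vars <- rbind(vars, node$edge_variants)
    if (is_tip(node)) {
      sid <- node$tip_samples
      reg <- nodes$region[match(sid, nodes$sample_id)]
      haps[[sid]] <<- haplotype(sid, vars[order(vars$position), ,
                                          drop = FALSE],
                                population = reg, region = reg)
      regions[sid] <<- reg
    }
    for (ch in node$children) acc(ch, vars)
  }
  acc(tree, empty_variants())

  out <- list(tree = tree, haplotypes = unname(haps),
              genealogy = gen, tmrca_years = gen$tmrca_years,
              regions = regions, config = config)
  for (extra in c("founder_node", "founder_time_years")) {
    if (!is.null(gen[[extra]])) out[[extra]] <- gen[[extra]]
  }
  class(out) <- "sim_result"
  out
}

#' Simulate a panmictic sample with mutations
#'
#' @param config [sim_config()] (scenario "panmictic").
#' @param reference reference string.
#' @return `sim_result`, see [drop_mutations()].
#' @export
simulate_panmictic <- function(config, reference = synthetic_reference()) {
  gen <- simulate_genealogy(config)
  drop_mutations(gen, config, reference)
}

#' Simulate a single source-to-sink colonization
#'
#' Sink-region lineages coalesce inside a sink deme of size
#' `sink_effective_size`; the simulation requires that at
#' `founder_time_years` at most `n_founders` sink lineages remain (the
#' genealogy is redrawn a bounded number of times otherwise, then errors).
#' At the founder time each remaining sink lineage coalesces with a random
#' source lineage alive then — the migrant carries a source haplotype of
#' that moment — and the merged set continues as a source-deme coalescent.
#' The attachment node (for a single founder) is recorded as the planted
#' founder node: its expected rho age over sink tips equals the migration
#' time, and its haplotype state is ancestral to source tips.
#'
#' @param config [sim_config()] with scenario "source_sink".
#' @param reference reference string.
#' @param max_retries resimulation attempts for the sink genealogy.
#' @return `sim_result` with `founder_node` and `founder_time_years` truth.
#' @export
simulate_source_sink <- function(config, reference = synthetic_reference(),
                                 max_retries = 100L) {
  stopifnot(inherits(config, "sim_config"),
            config$scenario == "source_sink")
  set.seed(config$seed)
  ft_gen <- config$founder_time_years / config$generation_years

  sink_nodes <- NULL
  for (try in seq_len(max_retries)) {
    nodes <- data.frame(
      id = paste0("K", seq_len(config$n_sink)), parent = NA_character_,
      time_years = 0, sample_id = paste0("K", seq_len(config$n_sink)),
      region = config$sink_region, stringsAsFactors = FALSE)
    active <- nodes$id
    t_gen <- 0
    ni <- 1L
    while (length(active) > config$n_founders) {
      w <- .coal_wait(length(active), config$sink_effective_size,
                      config$growth_rate, t_gen)
      if (t_gen + w >= ft_gen) break
      t_gen <- t_gen + w
      pair <- sample(active, 2L)
      nid <- paste0("KN", ni)
      ni <- ni + 1L
      nodes <- rbind(nodes, data.frame(
        id = nid, parent = NA_character_,
        time_years = t_gen * config$generation_years,
        sample_id = NA_character_, region = NA_character_,
        stringsAsFactors = FALSE))
      nodes$parent[match(pair, nodes$id)] <- nid
      active <- c(setdiff(active, pair), nid)
    }
    if (length(active) <= config$n_founders) {
      sink_nodes <- list(nodes = nodes, active = active)
      break
    }
  }
  if (is.null(sink_nodes)) {
    stop("sink sample did not reduce to ", config$n_founders,
         " lineage(s) by founder_time_years after ", max_retries,
         " attempts; the founder time exceeds the simulated TMRCA support")
  }

  # source deme coalescent up to the founder time
  src <- data.frame(
    id = paste0("C", seq_len(config$n_source)), parent = NA_character_,
    time_years = 0, sample_id = paste0("C", seq_len(config$n_source)),
    region = config$source_region, stringsAsFactors = FALSE)
  active_src <- src$id
  t_gen <- 0
  ni <- 1L
  while (length(active_src) > 1L) {
    w <- .coal_wait(length(active_src), config$effective_size,
                    config$growth_rate, t_gen)
    if (t_gen + w >= ft_gen) break
    t_gen <- t_gen + w
    pair <- sample(active_src, 2L)
    nid <- paste0("CN", ni)
    ni <- ni + 1L
    src <- rbind(src, data.frame(
      id = nid, parent = NA_character_,
      time_years = t_gen * config$generation_years,
      sample_id = NA_character_, region = NA_character_,
      stringsAsFactors = FALSE))
    src$parent[match(pair, src$id)] <- nid
    active_src <- c(setdiff(active_src, pair), nid)
  }

  # founder event(s): each surviving sink lineage attaches to a random
  # source lineage at exactly the founder time
  nodes <- rbind(sink_nodes$nodes, src)
  founder_ids <- character()
  fi <- 1L
  for (lin in sink_nodes$active) {
    host <- sample(active_src, 1L)
    fid <- paste0("F", fi)
    fi <- fi + 1L
    nodes <- rbind(nodes, data.frame(
      id = fid, parent = NA_character_,
      time_years = config$founder_time_years,
      sample_id = NA_character_, region = NA_character_,
      stringsAsFactors = FALSE))
    nodes$parent[match(c(lin, host), nodes$id)] <- fid
    active_src <- c(setdiff(active_src, host), fid)
    founder_ids <- c(founder_ids, fid)
  }

  # continue the source coalescent above the founder time
  t_gen <- ft_gen
  ni <- ni + 1000L
  while (length(active_src) > 1L) {
    t_gen <- t_gen + .coal_wait(length(active_src), config$effective_size,
                                config$growth_rate, t_gen)
    pair <- sample(active_src, 2L)
    nid <- paste0("CN", ni)
    ni <- ni + 1L
    nodes <- rbind(nodes, data.frame(
      id = nid, parent = NA_character_,
      time_years = t_gen * config$generation_years,
      sample_id = NA_character_, region = NA_character_,
      stringsAsFactors = FALSE))
    nodes$parent[match(pair, nodes$id)] <- nid
    active_src <- c(setdiff(active_src, pair), nid)
  }

  gen <- .genealogy(nodes, config)
  gen$founder_node <- founder_ids
  gen$founder_time_years <- config$founder_time_years
  drop_mutations(gen, config, reference)
}

#' Simulate two island populations with controllable divergence
#'
#' With divergence `d = 0` both populations draw their fragment haplotypes
#' from one shared panmictic pool, the exact exchangeable null of the FST
#' permutation test. With `d > 0` each individual carries, with probability
#' `d`, its population's private haplotype (a fixed haplotype with private
#' marker variants), so `d = 1` gives two populations fixed for different
#' haplotypes and FST 1. Haplotypes are restricted to the HVS-I fragment.
#'
#' @param config [sim_config()] with scenario "island_pair"; the simulator's
#'   HVS-I fragment substitution rate defaults to one substitution every
#'   20,180 years when `site_range` equals the HVS-I fragment.
#' @param reference reference string.
#' @param pool_size size of the shared panmictic pool sample.
#' @return list of two [population_sample()] objects ("pop1", "pop2") plus
#'   the divergence used, as class `island_pair`.
#' @export
simulate_island_pair <- function(config, reference = synthetic_reference(),
                                 pool_size = 40L) {
  stopifnot(inherits(config, "sim_config"),
            config$scenario == "island_pair")
  frag <- HVS1_RANGE
  pool_cfg <- sim_config(
    n_samples = pool_size, effective_size = config$effective_size,
    generation_years = config$generation_years,
    substitution_rate = if (identical(config$site_range,
                                      as.integer(c(1, config$genome_length))))
      1 / 20180 else config$substitution_rate,
    genome_length = config$genome_length,
    site_range = frag, masked_positions = config$masked_positions,
    seed = config$seed, scenario = "panmictic")
  pool <- simulate_panmictic(pool_cfg, reference)
  pool_haps <- lapply(pool$haplotypes, extract_fragment,
                      start = frag[1], end = frag[2])
  used <- unlist(lapply(pool_haps, function(h) h$variants$position))
  free <- setdiff(setdiff(frag[1]:frag[2], config$masked_positions), used)
  stopifnot(length(free) >= 6L)
  refv <- strsplit(toupper(reference), "")[[1]]
  private <- lapply(1:2, function(k) {
    p <- free[(3 * k - 2):(3 * k)]
    variant_table(p, ref = refv[p],
                  alt = vapply(p, function(q) {
                    setdiff(c("A", "C", "G", "T"), refv[q])[1]
                  }, character(1)),
                  class = "substitution")
  })

  n <- config$n_per_population
  draw_pop <- function(pop_idx) {
    members <- lapply(seq_len(n), function(i) {
      use_private <- stats::runif(1) < config$divergence
      v <- if (use_private) private[[pop_idx]] else {
        pool_haps[[sample.int(length(pool_haps), 1L)]]$variants
      }
      haplotype(paste0("P", pop_idx, "_", i), v,
                population = paste0("pop", pop_idx),
                covered_range = frag)
    })
    population_sample(paste0("pop", pop_idx), members)
  }
  out <- list(pop1 = draw_pop(1L), pop2 = draw_pop(2L),
              divergence = config$divergence)
  class(out) <- "island_pair"
  out
}

#' Write a simulation to disk in the pipeline's input dialects
#'
#' FASTA + metadata TSV (the pipeline inputs), the true mutation-labelled
#' tree as newick, and a truth JSON (TMRCA, founder node/time when present,
#' seed).
#'
#' @param sim `sim_result` from [drop_mutations()].
#' @param dir output directory (created if needed).
#' @param reference reference string used for the FASTA.
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir, reference = synthetic_reference()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, "samples.fasta")
  meta <- file.path(dir, "samples.tsv")
  write_haplotype_fasta(sim$haplotypes, reference, fasta, meta)
  nwk <- file.path(dir, "true_tree.nwk")
  writeLines(to_newick(sim$tree), nwk)
  truth <- list(tmrca_years = sim$tmrca_years, seed = sim$config$seed)
  if (!is.null(sim$founder_node)) {
    truth$founder_node <- sim$founder_node
    truth$founder_time_years <- sim$founder_time_years
  }
  tj <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta, meta, nwk, tj))
}
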