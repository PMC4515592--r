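#' Read and validate a pipeline configuration
#'
#' YAML or JSON file with the stage settings. Required fields: `seed`,
#' `output_dir` and either an `input` block (`fasta`, `metadata`,
#' `reference`, optional `fragment_start`) or a `simulate` block (passed to
#' [sim_config()]). Optional blocks: `mask` (positions, drop_indels),
#' `clocks` (list of clock specs), `clades` (label -> variant labels),
#' `founder` (nodes, sink_region, source_region, clock), `popgen`
#' (fragment, n_permutations, alpha, distance_mode, min_population_size,
#' mds_k, classifier). Referenced input files must exist at validation time.
#'
#' @param path configuration file path.
#' @return validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg configuration list.
#' @export
validate_run_config <- function(cfg) {
  if (is.null(cfg$seed)) stop("config validation: seed is required")
  if (is.null(cfg$output_dir)) {
    stop("config validation: output_dir is required")
  }
  if (is.null(cfg$input) && is.null(cfg$simulate)) {
    stop("config validation: either an input or a simulate block is required")
  }
  if (!is.null(cfg$input)) {
    for (f in c("fasta", "metadata", "reference")) {
      if (is.null(cfg$input[[f]])) {
        stop("config validation: input$", f, " is required")
      }
      if (!file.exists(cfg$input[[f]])) {
        stop("config validation: input file not found: ", cfg$input[[f]])
      }
    }
  }
  if (!is.null(cfg$clocks)) {
    for (cl in cfg$clocks) {
      if (is.null(cl$preset) && is.null(cl$years_per_substitution)) {
        stop("config validation: every clock needs a preset or a ",
             "years_per_substitution")
      }
    }
  }
  class(cfg) <- c("run_config", class(cfg))
  cfg
}

.build_clock <- function(spec) {
  if (!is.null(spec$preset)) {
    return(switch(spec$preset,
                  whole_mtdna = clock_whole_mtdna(),
                  synonymous = clock_synonymous(),
                  stop("unknown clock preset: ", spec$preset)))
  }
  clock(name = if (is.null(spec$name)) "custom" else spec$name,
        years_per_substitution = spec$years_per_substitution,
        counting = if (is.null(spec$counting)) "all" else spec$counting,
        fragment_range = if (is.null(spec$fragment_range)) NULL else {
          as.integer(unlist(spec$fragment_range))
        },
        scaling_base_length = spec$scaling_base_length)
}

#' Run the full pipeline
#'
#' Executes the configured stages in order — haplotype conversion, network +
#' tree extraction, clade dating, founder analysis, population comparison —
#' writing each stage's TSV/newick outputs and a manifest (inputs, seed,
#' parameter hash, per-stage record counts) into `output_dir`. Stages
#' communicate only through their outputs and never mutate inputs; the same
#' config and seed reproduce byte-identical tables. A stage failure aborts
#' with an error naming the stage.
#'
#' @param cfg configuration list or path (see [read_run_config()]).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (!inherits(cfg, "run_config")) cfg <- validate_run_config(cfg)
  out_dir <- cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed,
                   parameter_hash = digest_config(cfg),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- haplotype stage -----------------------------------------------------
  haps <- stage("haplotype", {
    if (!is.null(cfg$simulate)) {
      sc <- do.call(sim_config, c(cfg$simulate, list(seed = cfg$seed)))
      sim <- if (sc$scenario == "source_sink") {
        simulate_source_sink(sc)
      } else simulate_panmictic(sc)
      write_simulation(sim, file.path(out_dir, "simulated_input"))
      reference <- synthetic_reference()
      sim$haplotypes
    } else {
      reference <- as.character(
        Biostrings::readDNAStringSet(cfg$input$reference)[[1]])
      recs <- read_fasta_with_metadata(cfg$input$fasta, cfg$input$metadata,
                                       cfg$input$fragment_start)
      haplotypes_from_records(recs, reference)
    }
  })
  masked_n <- 0L
  if (!is.null(cfg$mask)) {
    pos <- as.integer(unlist(cfg$mask$positions))
    drop_ind <- isTRUE(cfg$mask$drop_indels)
    before <- sum(vapply(haps, function(h) nrow(h$variants), integer(1)))
    haps <- lapply(haps, mask_haplotype, masked_positions = pos,
                   drop_indels = drop_ind)
    after <- sum(vapply(haps, function(h) nrow(h$variants), integer(1)))
    masked_n <- before - after
  }
  write_haplotype_table(haps, file.path(out_dir, "haplotypes.tsv"))
  manifest$stages$haplotype <- list(n_samples = length(haps),
                                    variants_removed = masked_n)
  regions <- stats::setNames(
    vapply(haps, `[[`, character(1), "region"),
    vapply(haps, `[[`, character(1), "sample_id"))

  # --- network stage -------------------------------------------------------
  tree <- stage("network", {
    hm <- haplotype_matrix(haps)
    net <- build_reduced_median(hm)
    tr <- extract_tree(net)
    writeLines(to_newick(tr), file.path(out_dir, "tree.nwk"))
    tree_edge_list(tr, file.path(out_dir, "edges.tsv"))
    manifest$stages$network <- list(n_nodes = nrow(net$nodes),
                                     n_median = net$n_median,
                                     n_edges = nrow(net$edges))
    tr
  })

  # --- dating stage --------------------------------------------------------
  if (!is.null(cfg$clades)) {
    stage("date", {
      if (is.null(cfg$clocks)) stop("no clocks configured")
      clocks <- lapply(cfg$clocks, .build_clock)
      defs <- lapply(cfg$clades, function(d) as.character(unlist(d)))
      tree <- annotate_clades(tree, defs)
      ages <- date_clades(tree, names(defs), clocks,
                          path = file.path(out_dir, "clade_ages.tsv"))
      manifest$stages$date <- list(n_rows = nrow(ages))
    })
  }

  # --- founder stage -------------------------------------------------------
  if (!is.null(cfg$founder)) {
    stage("founder", {
      fc <- cfg$founder
      clk <- .build_clock(fc$clock)
      nodes <- if (!is.null(fc$nodes)) as.character(unlist(fc$nodes)) else {
        scan_founder_candidates(tree, regions, fc$source_region,
                                fc$sink_region,
                                min_sink_tips =
                                  if (is.null(fc$min_sink_tips)) 3L else {
                                    fc$min_sink_tips
                                  })$node_id
      }
      rep <- founder_report(tree, nodes, fc$sink_region, clk, regions,
                            path = file.path(out_dir, "founder_ages.tsv"))
      manifest$stages$founder <- list(n_nodes = length(nodes))
    })
  }

  # --- popgen stage --------------------------------------------------------
  if (!is.null(cfg$popgen)) {
    stage("popgen", {
      pg <- cfg$popgen
      frag <- if (is.null(pg$fragment)) HVS1_RANGE else {
        as.integer(unlist(pg$fragment))
      }
      min_n <- if (is.null(pg$min_population_size)) 30L else {
        pg$min_population_size
      }
      frag_haps <- lapply(haps, extract_fragment, start = frag[1],
                          end = frag[2])
      pops_names <- vapply(frag_haps, `[[`, character(1), "population")
      keep <- names(which(table(pops_names) > min_n))
      pops <- lapply(keep, function(nm) {
        population_sample(nm, frag_haps[pops_names == nm])
      })
      if (length(pops) < 2L) stop("fewer than two populations of size > ",
                                  min_n)
      nperm <- if (is.null(pg$n_permutations)) 10000L else pg$n_permutations
      dm <- fst_matrix(pops, n_permutations = nperm, seed = cfg$seed)
      utils::write.table(dm$fst, file.path(out_dir, "fst.tsv"), sep = "\t",
                         quote = FALSE, col.names = NA)
      utils::write.table(dm$p_values, file.path(out_dir, "fst_pvalues.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
      utils::write.table(dm$linearized,
                         file.path(out_dir, "fst_linearized.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
      k <- if (is.null(pg$mds_k)) min(2L, length(pops) - 1L) else pg$mds_k
      mds <- mds_sstress(dm$linearized, k = k)
      coords <- data.frame(population = rownames(mds$coordinates),
                           mds$coordinates)
      utils::write.table(coords, file.path(out_dir, "mds_coordinates.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(pg$classifier)) {
        comp <- haplogroup_composition(
          pops, lapply(pg$classifier, function(d) as.character(unlist(d))))
        utils::write.table(comp, file.path(out_dir, "composition.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      manifest$stages$popgen <- list(n_populations = length(pops),
                                      s_stress = mds$s_stress)
    })
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Stable hash of a configuration
#' @param cfg configuration list.
#' @return md5 string of the serialized config.
#' @keywords internal
digest_config <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
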