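#' Molecular clocks for rho dating
#'
#' A clock converts a rho statistic (mean mutational steps from a node to its
#' tips) into years. Three counting rules are supported: all substitutions on
#' the whole molecule, synonymous substitutions only, or substitutions inside
#' a fragment. Indels are never counted. For fragment clocks the effective
#' rate is rescaled by the fragment size:
#' `years_per_substitution * scaling_base_length / fragment_length`,
#' so a clock calibrated on a longer stretch slows down proportionally when
#' only a sub-fragment is scored.
#'
#' @param name clock name used in reports.
#' @param years_per_substitution calibrated years per counted substitution.
#' @param counting one of "all", "synonymous", "fragment".
#' @param fragment_range length-2 closed interval (required for "fragment").
#' @param scaling_base_length length (bp) the rate was calibrated on
#'   (required for "fragment").
#' @return object of class `clock`.
#' @export
clock <- function(name, years_per_substitution,
                  counting = c("all", "synonymous", "fragment"),
                  fragment_range = NULL, scaling_base_length = NULL) {
  counting <- match.arg(counting)
  if (!is.numeric(years_per_substitution) || years_per_substitution <= 0) {
    stop("years_per_substitution must be positive")
  }
  if (counting == "fragment") {
    if (is.null(fragment_range) || is.null(scaling_base_length)) {
      stop("fragment clocks need both fragment_range and scaling_base_length")
    }
    stopifnot(length(fragment_range) == 2L,
              fragment_range[1] <= fragment_range[2],
              scaling_base_length > 0)
  }
  structure(list(name = name,
                 years_per_substitution = years_per_substitution,
                 counting = counting,
                 fragment_range = fragment_range,
                 scaling_base_length = scaling_base_length),
            class = "clock")
}

#' Whole-mtDNA corrected clock: one substitution every 3,624 years
#' @return clock object.
#' @export
clock_whole_mtdna <- function() {
  clock("whole_mtDNA", 3624, counting = "all")
}

#' Synonymous clock: one synonymous substitution every 7,884 years
#' @return clock object.
#' @export
clock_synonymous <- function() {
  clock("synonymous", 7884, counting = "synonymous")
}

#' HVS-I fragment clock
#'
#' Scales a base HVS-I rate to the analysed fragment (default the 276-bp
#' stretch 16090-16365). The base rate and the length it was calibrated on
#' must be supplied: published base rates vary and none is assumed.
#'
#' @param years_per_substitution base rate, years per substitution over
#'   `scaling_base_length` bp.
#' @param scaling_base_length bp length the base rate refers to.
#' @param fragment_range scored fragment (closed interval).
#' @return clock object.
#' @export
clock_hvs1 <- function(years_per_substitution, scaling_base_length,
                       fragment_range = HVS1_RANGE) {
  clock("HVS-I", years_per_substitution, counting = "fragment",
        fragment_range = fragment_range,
        scaling_base_length = scaling_base_length)
}

#' Effective years per counted substitution of a clock
#' @param clk clock object.
#' @return numeric rate in years per substitution.
#' @export
effective_rate <- function(clk) {
  stopifnot(inherits(clk, "clock"))
  if (clk$counting == "fragment") {
    frag_len <- diff(clk$fragment_range) + 1
    clk$years_per_substitution * clk$scaling_base_length / frag_len
  } else {
    clk$years_per_substitution
  }
}

# counted mutations on one edge under a counting rule; indels never count
count_edge <- function(variants, counting = "all", fragment_range = NULL) {
  v <- variants[variants$class == "substitution", , drop = FALSE]
  switch(counting,
         all = nrow(v),
         synonymous = sum(!is.na(v$synonymous) & v$synonymous == "yes"),
         fragment = {
           stopifnot(!is.null(fragment_range))
           sum(v$position >= fragment_range[1] &
                 v$position <= fragment_range[2])
         },
         stop("unknown counting rule: ", counting))
}

# edge-sum accumulation below a node: for every edge e below the node,
# record (counted mutations m_e, number of contributing tips n_e). The tip
# filter restricts which tips contribute (founder analysis uses it to score
# sink-region tips only).
.edge_stats <- function(node, counting, fragment_range, tip_filter) {
  stats <- list()
  rec <- function(nd) {
    if (is_tip(nd)) {
      return(sum(vapply(nd$tip_samples, tip_filter, logical(1))))
    }
    n_here <- 0L
    for (ch in nd$children) {
      n_ch <- rec(ch)
      if (n_ch > 0L) {
        m <- count_edge(ch$edge_variants, counting, fragment_range)
        stats[[length(stats) + 1L]] <<- c(m = m, n = n_ch)
      }
      n_here <- n_here + n_ch
    }
    n_here
  }
  n_total <- rec(node)
  list(n = n_total,
       edges = if (length(stats) > 0L) do.call(rbind, stats) else {
         matrix(numeric(), ncol = 2, dimnames = list(NULL, c("m", "n")))
       })
}

#' Rho statistic of a node
#'
#' The average number of counted mutational steps from the node to the tips
#' below it: `rho = sum over tips of path mutations / n`, computed by the
#' equivalent edge sum `rho = sum_e m_e * n_e / n` with `m_e` counted
#' mutations on edge `e` and `n_e` tips below it.
#'
#' @param tree [phylo_node()] root.
#' @param node_id node to date (default: the root).
#' @param counting "all", "synonymous" or "fragment".
#' @param fragment_range closed interval for the "fragment" rule.
#' @param tip_filter predicate on sample ids selecting contributing tips.
#' @return list with `rho` and `n_tips`.
#' @export
compute_rho <- function(tree, node_id = NULL, counting = "all",
                        fragment_range = NULL,
                        tip_filter = function(s) TRUE) {
  node <- if (is.null(node_id)) tree else find_node(tree, node_id)
  if (is.null(node)) stop("node '", node_id, "' not in tree")
  es <- .edge_stats(node, counting, fragment_range, tip_filter)
  if (es$n == 0L) stop("no contributing tips below node")
  list(rho = sum(es$edges[, "m"] * es$edges[, "n"]) / es$n, n_tips = es$n)
}

#' Genealogy-aware (Saillard) standard error of rho
#'
#' `sigma = sqrt( sum_e (n_e / n)^2 * m_e )` over the edges below the node:
#' mutations on edges subtending many tips are shared by all their
#' descendants and therefore contribute more error than private mutations.
#'
#' @inheritParams compute_rho
#' @return numeric sigma (in mutation units).
#' @export
compute_sigma <- function(tree, node_id = NULL, counting = "all",
                          fragment_range = NULL,
                          tip_filter = function(s) TRUE) {
  node <- if (is.null(node_id)) tree else find_node(tree, node_id)
  if (is.null(node)) stop("node '", node_id, "' not in tree")
  es <- .edge_stats(node, counting, fragment_range, tip_filter)
  if (es$n == 0L) stop("no contributing tips below node")
  sqrt(sum((es$edges[, "n"] / es$n)^2 * es$edges[, "m"]))
}

#' Convert rho and sigma into an age with a 95% interval
#'
#' `age = rho * rate`, with the normal-approximation interval
#' `age +/- 1.96 * sigma * rate`, lower bound clamped at zero (ages cannot
#' be negative, hence the `[0-...]` intervals in clade-age tables).
#'
#' @param rho rho statistic.
#' @param sigma Saillard standard error of rho.
#' @param clk [clock()] object.
#' @param n_tips number of tips used.
#' @param node_id optional node label carried into the result.
#' @return one-row data.frame of class `rho_estimate`: node_id, clock,
#'   n_tips, rho, sigma, age_years, ci_low, ci_high.
#' @export
age_estimate <- function(rho, sigma, clk, n_tips, node_id = NA_character_) {
  stopifnot(rho >= 0, sigma >= 0)
  rate <- effective_rate(clk)
  age <- rho * rate
  half <- 1.96 * sigma * rate
  out <- data.frame(node_id = node_id, clock = clk$name,
                    n_tips = as.integer(n_tips), rho = rho, sigma = sigma,
                    age_years = age,
                    ci_low = max(0, age - half), ci_high = age + half,
                    stringsAsFactors = FALSE)
  class(out) <- c("rho_estimate", class(out))
  out
}

#' Date a node of a tree under a clock
#'
#' Convenience wrapper running [compute_rho()], [compute_sigma()] and
#' [age_estimate()] with the clock's own counting rule.
#'
#' @param tree phylo_node root.
#' @param clk clock object.
#' @param node_id node to date (default root).
#' @param tip_filter predicate on sample ids.
#' @return `rho_estimate` row.
#' @export
date_node <- function(tree, clk, node_id = NULL,
                      tip_filter = function(s) TRUE) {
  r <- compute_rho(tree, node_id, clk$counting, clk$fragment_range,
                   tip_filter)
  s <- compute_sigma(tree, node_id, clk$counting, clk$fragment_range,
                     tip_filter)
  age_estimate(r$rho, s, clk, r$n_tips,
               node_id = if (is.null(node_id)) tree$node_id else node_id)
}

#' Clade-age table
#'
#' One row per (clade, clock), ordered by clade then clock — the layout of
#' published clade-age tables (clade, n, rho, sigma, age, 95% CI).
#'
#' @param tree tree annotated with [annotate_clades()].
#' @param clade_labels clade labels to date.
#' @param clocks list of [clock()] objects.
#' @param path optional TSV output path.
#' @return data.frame with one `rho_estimate` row per clade x clock.
#' @export
date_clades <- function(tree, clade_labels, clocks, path = NULL) {
  stopifnot(is.list(clocks))
  clade_labels <- sort(unique(as.character(clade_labels)))
  rows <- list()
  for (lab in clade_labels) {
    nid <- clade_root(tree, lab)
    if (is.null(nid)) stop("unknown clade label: ", lab)
    ord <- order(vapply(clocks, `[[`, character(1), "name"))
    for (clk in clocks[ord]) {
      est <- date_node(tree, clk, node_id = nid)
      est$clade <- lab
      rows[[length(rows) + 1L]] <- est
    }
  }
  out <- if (length(rows) == 0L) {
    data.frame(clade = character(), node_id = character(),
               clock = character(), n_tips = integer(), rho = numeric(),
               sigma = numeric(), age_years = numeric(), ci_low = numeric(),
               ci_high = numeric())
  } else {
    tab <- do.call(rbind, rows)
    tab[, c("clade", setdiff(names(tab), "clade"))]
  }
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
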