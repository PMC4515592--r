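#' Population sample of fragment-restricted haplotypes
#'
#' @param name population name.
#' @param members list of [haplotype()] objects, all sharing one covered
#'   range (typically the HVS-I fragment 16090-16365).
#' @param country,language optional metadata.
#' @return object of class `population_sample`.
#' @export
population_sample <- function(name, members, country = NA_character_,
                              language = NA_character_) {
  stopifnot(length(members) >= 1L)
  covered <- members[[1]]$covered_range
  same <- vapply(members, function(h) identical(h$covered_range, covered),
                 logical(1))
  if (!all(same)) stop("members of '", name, "' cover different fragments")
  structure(list(name = name, members = members, country = country,
                 language = language, covered_range = covered),
            class = "population_sample")
}

#' @export
print.population_sample <- function(x, ...) {
  cat("<population_sample>", x$name, "- n =", length(x$members),
      "covering", x$covered_range[1], "-", x$covered_range[2], "\n")
  invisible(x)
}

# squared inter-individual distances for AMOVA: haplotype_identity scores
# 0/1 on variant-set equality; pairwise_differences uses the size of the
# symmetric difference of the variant sets (used directly as the squared
# distance, the convention for pairwise-difference AMOVA)
.sq_dist_matrix <- function(haps, distance_mode) {
  keys <- lapply(haps, function(h) variant_keys(h$variants))
  n <- length(keys)
  D <- matrix(0, n, n)
  if (distance_mode == "haplotype_identity") {
    sig <- vapply(keys, paste, character(1), collapse = "|")
    D[] <- as.numeric(outer(sig, sig, `!=`))
  } else {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d <- length(setdiff(keys[[i]], keys[[j]])) +
        length(setdiff(keys[[j]], keys[[i]]))
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

# AMOVA fixation index from a squared-distance matrix and group sizes;
# groups is an integer vector of group labels per individual
.fst_from_distances <- function(D, groups) {
  n <- length(groups)
  tab <- table(groups)
  p <- length(tab)
  ssd_total <- sum(D) / (2 * n)
  ssd_within <- 0
  for (g in names(tab)) {
    idx <- which(groups == g)
    ssd_within <- ssd_within + sum(D[idx, idx]) / (2 * length(idx))
  }
  ssd_among <- ssd_total - ssd_within
  df_among <- p - 1L
  df_within <- n - p
  if (df_within == 0L) return(NA_real_)
  msd_among <- ssd_among / df_among
  msd_within <- ssd_within / df_within
  n_prime <- (n - sum(tab^2) / n) / df_among
  sigma_a <- (msd_among - msd_within) / n_prime
  denom <- sigma_a + msd_within
  if (denom == 0) return(0)
  sigma_a / denom
}

#' Pairwise FST between two populations
#'
#' AMOVA-based fixation index: the between-population variance component
#' over the total. `haplotype_identity` (the default) scores individuals 0/1
#' on sharing the same fragment haplotype; `pairwise_differences` uses the
#' number of differing positions (a Phi-ST-like distance). Slightly negative
#' estimates are possible (unbiased variance components) and are reported as
#' computed.
#'
#' @param popA,popB [population_sample()] objects on the same fragment.
#' @param distance_mode "haplotype_identity" or "pairwise_differences".
#' @return numeric FST.
#' @export
pairwise_fst <- function(popA, popB,
                         distance_mode = c("haplotype_identity",
                                           "pairwise_differences")) {
  distance_mode <- match.arg(distance_mode)
  if (!identical(popA$covered_range, popB$covered_range)) {
    stop("populations cover different fragments")
  }
  haps <- c(popA$members, popB$members)
  groups <- rep(c(1L, 2L), c(length(popA$members), length(popB$members)))
  D <- .sq_dist_matrix(haps, distance_mode)
  .fst_from_distances(D, groups)
}

#' Permutation p-value for pairwise FST
#'
#' Individuals are randomly reassigned to the two populations (sizes
#' preserved) and the FST recomputed; the p-value is
#' `(1 + #{permuted FST >= observed}) / (n_permutations + 1)`.
#'
#' @inheritParams pairwise_fst
#' @param n_permutations number of label permutations (default 10,000).
#' @param seed RNG seed; the same seed reproduces the same p-value.
#' @return list with `fst`, `p_value`, `n_permutations`.
#' @export
permutation_pvalue <- function(popA, popB, n_permutations = 10000L,
                               seed = 1L,
                               distance_mode = c("haplotype_identity",
                                                 "pairwise_differences")) {
  distance_mode <- match.arg(distance_mode)
  stopifnot(n_permutations >= 1L)
  if (!identical(popA$covered_range, popB$covered_range)) {
    stop("populations cover different fragments")
  }
  nA <- length(popA$members)
  haps <- c(popA$members, popB$members)
  n <- length(haps)
  groups <- rep(c(1L, 2L), c(nA, n - nA))
  D <- .sq_dist_matrix(haps, distance_mode)
  obs <- .fst_from_distances(D, groups)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_permutations)) {
    perm <- groups[sample.int(n)]
    if (.fst_from_distances(D, perm) >= obs - 1e-12) hits <- hits + 1L
  }
  list(fst = obs, p_value = (1 + hits) / (n_permutations + 1),
       n_permutations = as.integer(n_permutations))
}

#' Bonferroni significance flags
#'
#' Flag `i` is significant iff `p[i] <= alpha / m` with `m = length(p)`.
#'
#' @param p_values numeric vector of p-values.
#' @param alpha family-wise error rate (default 0.05).
#' @return logical vector.
#' @export
bonferroni_significant <- function(p_values, alpha = 0.05) {
  stopifnot(length(p_values) >= 1L)
  p_values <= alpha / length(p_values)
}

#' Slatkin linearization of FST
#'
#' `fst / (1 - fst)`, approximately linear in divergence time; negative
#' estimates are floored at zero first. Undefined at `fst = 1`.
#'
#' @param fst numeric vector of FST values (< 1).
#' @return numeric vector of linearized distances.
#' @export
slatkin_linearize <- function(fst) {
  if (any(fst >= 1)) stop("Slatkin linearization undefined at fst = 1")
  fst <- pmax(0, fst)
  fst / (1 - fst)
}

#' Pairwise FST / p-value / linearized distance matrices
#'
#' @param populations list of [population_sample()] objects.
#' @param n_permutations permutations per pair.
#' @param seed base RNG seed; pair (i, j) uses `seed + i * 1009 + j`.
#' @param distance_mode see [pairwise_fst()].
#' @return object of class `pop_distance_matrix` with symmetric `fst`,
#'   `p_values` and `linearized` matrices (diagonals 0, 1, 0).
#' @export
fst_matrix <- function(populations, n_permutations = 10000L, seed = 1L,
                       distance_mode = c("haplotype_identity",
                                         "pairwise_differences")) {
  distance_mode <- match.arg(distance_mode)
  k <- length(populations)
  nm <- vapply(populations, `[[`, character(1), "name")
  fst <- matrix(0, k, k, dimnames = list(nm, nm))
  p <- matrix(1, k, k, dimnames = list(nm, nm))
  for (i in seq_len(max(0L, k - 1L))) for (j in (i + 1L):k) {
    res <- permutation_pvalue(populations[[i]], populations[[j]],
                              n_permutations,
                              seed = seed + i * 1009L + j,
                              distance_mode = distance_mode)
    fst[i, j] <- fst[j, i] <- res$fst
    p[i, j] <- p[j, i] <- res$p_value
  }
  lin <- matrix(slatkin_linearize(pmin(fst, 1 - 1e-12)), k, k,
                dimnames = list(nm, nm))
  diag(lin) <- 0
  stopifnot(isTRUE(all.equal(fst, t(fst))))
  structure(list(populations = nm, fst = fst, p_values = p,
                 linearized = lin), class = "pop_distance_matrix")
}

#' Pool populations whose differentiation is non-significant
#'
#' Within each candidate group (e.g. the same ethnic group sampled in two
#' countries, or several samples from one country), pairwise FST permutation
#' tests are run, Bonferroni-corrected over all tests performed in the call,
#' and populations connected by non-significant pairs are pooled into one
#' sample; all other populations are left intact.
#'
#' @param populations list of [population_sample()] objects.
#' @param merge_candidates list of character vectors of population names
#'   eligible for merging.
#' @param alpha family-wise error rate.
#' @param n_permutations,seed,distance_mode see [permutation_pvalue()].
#' @return list of population samples after pooling; pooled samples are
#'   named "A+B".
#' @export
merge_nonsignificant <- function(populations, merge_candidates,
                                 alpha = 0.05, n_permutations = 10000L,
                                 seed = 1L,
                                 distance_mode = c("haplotype_identity",
                                                   "pairwise_differences")) {
  distance_mode <- match.arg(distance_mode)
  if (length(merge_candidates) == 0L) return(populations)
  nm <- vapply(populations, `[[`, character(1), "name")
  tests <- list()
  for (g in seq_along(merge_candidates)) {
    grp <- merge_candidates[[g]]
    stopifnot(all(grp %in% nm))
    if (length(grp) < 2L) next
    for (i in seq_len(length(grp) - 1L)) for (j in (i + 1L):length(grp)) {
      tests[[length(tests) + 1L]] <- list(a = grp[i], b = grp[j])
    }
  }
  if (length(tests) == 0L) return(populations)
  p <- vapply(seq_along(tests), function(t) {
    permutation_pvalue(populations[[match(tests[[t]]$a, nm)]],
                       populations[[match(tests[[t]]$b, nm)]],
                       n_permutations, seed = seed + t,
                       distance_mode = distance_mode)$p_value
  }, numeric(1))
  ok <- !bonferroni_significant(p, alpha)
  # union-find over non-significant pairs
  parent <- stats::setNames(nm, nm)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (t in seq_along(tests)) {
    if (ok[t]) parent[[find(tests[[t]]$a)]] <- find(tests[[t]]$b)
  }
  roots <- vapply(nm, find, character(1))
  out <- list()
  for (r in unique(roots)) {
    members_idx <- which(roots == r)
    if (length(members_idx) == 1L) {
      out[[length(out) + 1L]] <- populations[[members_idx]]
    } else {
      pooled <- unlist(lapply(populations[members_idx], `[[`, "members"),
                       recursive = FALSE)
      out[[length(out) + 1L]] <- population_sample(
        paste(sort(nm[members_idx]), collapse = "+"), pooled)
    }
  }
  out
}

# Young's S-stress (formula 1): sqrt( sum (d^2 - delta^2)^2 / sum delta^4 )
.s_stress <- function(coords, delta) {
  d2 <- as.matrix(stats::dist(coords))^2
  delta2 <- delta^2
  num <- sum((d2[upper.tri(d2)] - delta2[upper.tri(delta2)])^2)
  den <- sum(delta2[upper.tri(delta2)]^2)
  if (den == 0) return(0)
  sqrt(num / den)
}

#' Multidimensional scaling minimizing Young's S-stress
#'
#' Finds a k-dimensional configuration for a symmetric zero-diagonal
#' distance matrix by minimizing the squared-distance stress
#' `sqrt( sum (d_ij^2 - delta_ij^2)^2 / sum delta_ij^4 )`, starting from the
#' classical (eigen-decomposition) solution and refining it with BFGS
#' gradient descent. Deterministic: no random restarts.
#'
#' @param delta symmetric distance matrix (e.g. Slatkin-linearized FST).
#' @param k target dimension (must be < number of points).
#' @param maxit optimizer iteration cap.
#' @return list with `coordinates` (centered n x k matrix) and `s_stress`.
#' @export
mds_sstress <- function(delta, k = 2L, maxit = 1000L) {
  delta <- as.matrix(delta)
  n <- nrow(delta)
  if (k >= n) stop("k must be smaller than the number of populations")
  stopifnot(isTRUE(all.equal(delta, t(delta))), all(diag(delta) == 0))
  # cmdscale warns when the input supports fewer than k positive
  # eigenvalues; collapsed dimensions are padded with zeros below
  x0 <- suppressWarnings(stats::cmdscale(delta, k = k))
  if (is.null(dim(x0))) x0 <- matrix(x0, nrow = n)
  if (ncol(x0) < k) {  # degenerate input: pad collapsed dimensions
    x0 <- cbind(x0, matrix(0, n, k - ncol(x0)))
  }
  obj <- function(par) .s_stress(matrix(par, n, k), delta)
  fit <- stats::optim(as.vector(x0), obj, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  coords <- matrix(fit$par, n, k)
  coords <- sweep(coords, 2, colMeans(coords))
  rownames(coords) <- rownames(delta)
  list(coordinates = coords, s_stress = .s_stress(coords, delta))
}

#' Haplogroup composition of populations
#'
#' Classifies each member haplotype by motif: a classifier maps haplogroup
#' labels to the variant labels (see [variant_labels()]) that define them,
#' and the most specific matching label wins. A haplotype matching a label
#' that has sub-labels in the classifier but none of them is reported with a
#' "*" suffix (e.g. an L2 lineage with no subclade motif counts as "L2*", the
#' convention when subclades are not distinguishable from the fragment).
#' Unmatched haplotypes count as "other". Matching two disjoint top-level
#' labels is an error (contradictory classifier).
#'
#' @param populations list of [population_sample()] objects.
#' @param classifier named list: label -> character vector of variant labels.
#' @return data.frame, one row per population, one column per label;
#'   rows sum to 1.
#' @export
haplogroup_composition <- function(populations, classifier) {
  stopifnot(is.list(classifier), !is.null(names(classifier)))
  labs <- names(classifier)
  is_prefix <- function(a, b) a != b && startsWith(b, a)
  top <- labs[!vapply(labs, function(l) {
    any(vapply(labs, is_prefix, logical(1), b = l))
  }, logical(1))]
  classify_one <- function(h) {
    have <- variant_labels(h$variants)
    hit <- labs[vapply(classifier, function(m) all(m %in% have), logical(1))]
    if (length(hit) == 0L) return("other")
    tops <- unique(vapply(hit, function(l) {
      anc <- top[vapply(top, function(t) t == l || is_prefix(t, l),
                        logical(1))]
      anc[1]
    }, character(1)))
    if (length(tops) > 1L) {
      stop("haplotype ", h$sample_id, " matches disjoint top-level labels: ",
           paste(tops, collapse = ", "))
    }
    best <- hit[order(-nchar(hit), hit)][1]
    has_children <- any(vapply(labs, function(l) is_prefix(best, l),
                               logical(1)))
    child_hit <- any(vapply(hit, function(l) is_prefix(best, l), logical(1)))
    if (has_children && !child_hit) paste0(best, "*") else best
  }
  all_labels <- sort(unique(c(
    unlist(lapply(populations, function(p) {
      vapply(p$members, classify_one, character(1))
    })))))
  tab <- t(vapply(populations, function(p) {
    cls <- vapply(p$members, classify_one, character(1))
    counts <- table(factor(cls, levels = all_labels))
    as.numeric(counts) / length(cls)
  }, numeric(length(all_labels))))
  out <- as.data.frame(tab)
  names(out) <- all_labels
  out <- cbind(population = vapply(populations, `[[`, character(1), "name"),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
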