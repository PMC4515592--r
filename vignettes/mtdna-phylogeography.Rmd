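---
title: "Rho-statistic dating and phylogeography of mtDNA haplogroups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rho-statistic dating and phylogeography of mtDNA haplogroups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhophylo)
```

## The problem

Human mitochondrial DNA is maternally inherited, non-recombining and fast
mutating, which makes it a natural marker for lineage-based phylogeography:
the geography of a haplogroup's internal clades, together with molecular
dates for those clades, reconstructs when maternal lineages moved between
regions. `rhophylo` implements the full analysis chain used in this
tradition: aligned sequences are converted into haplotypes (sets of
differences from the rCRS coordinate reference), a reduced-median network
summarizes the haplotypes and a mutation-labelled tree is extracted from it,
clades are dated with the rho statistic under calibrated molecular clocks,
migrations are dated by founder analysis, and populations are compared on
the HVS-I hypervariable fragment. A coalescent simulator with known truth
generates every input the test-suite needs.

## Haplotype conversion

Input sequences must already sit in rCRS coordinates — the package
deliberately does not align, because alignment choices (and their manual
curation) are upstream of everything this package models. `call_variants()`
reports substitutions, deletions (gap in the sample) and insertions
(anchored to the preceding reference position with sub-indices, in the
PhyloTree naming style, e.g. `573.1C`). Ambiguity codes (`N`) never produce
variants. Coordinates are 1-based and intervals closed, so the HVS-I
analysis fragment 16090–16365 spans exactly 276 positions.

Substitutions are classified as synonymous / non-synonymous / non-coding
against a packaged table of the 13 protein-coding genes at their canonical
human mtDNA coordinates and the vertebrate mitochondrial genetic code
(table 2: `AGA`/`AGG` stop, `ATA` Met, `TGA` Trp). Three details matter:

* Overlapping gene ends (ATP8/ATP6, ATP6/COX3, ND4L/ND4) are trimmed so
  each position belongs to at most one gene; the true translation start is
  retained so reading frames stay correct. Positions in the trimmed overlap
  are classified in the downstream gene's frame.
* ND6 lies on the light strand and is translated from the reverse
  complement.
* Positions in a gene's incomplete terminal codon (completed by transcript
  polyadenylation in vivo) are reported `not_coding`: synonymy is not
  defined for them at the DNA level.

The package does not ship the real rCRS sequence; analyses of real data
must supply the genuine reference FASTA. For simulation and testing,
`synthetic_reference()` provides a fixed, clearly-labelled synthetic
16,569-bp stand-in, so synonymous classification in simulations is exercised
through exactly the same code path as real data would use.

## Reduced-median network and tree extraction

Haplotypes are encoded as a 0/1 matrix (reference vs derived state);
invariant columns are dropped, identical haplotypes collapse with their
multiplicity, and each character receives a weight equal to the inverse of
its relative frequency, binned to 1–99. Under this convention a mutation
seen many times across the data set — a hypervariable site — gets a *low*
weight, expressing low confidence that all its occurrences share one origin.

`build_reduced_median()` resolves character conflicts in two stages:

1. **Reduction.** When two characters are incompatible (all four gamete
   patterns present) and their weight ratio reaches the
   `reduction_threshold` (default 2), the lower-weight character is split
   into two independent single-origin copies — it is declared recurrent.
   This removes the conflict and marks both copies, which the extracted
   tree flags and which dating counts once per occurrence.
2. **Median closure.** Remaining conflicts (between characters of similar
   weight) are kept: majority-of-three median vectors are added until
   closure, and the network links every pair of nodes with no third node
   metrically between them. Pairwise-compatible data therefore yield
   exactly the unique perfect phylogeny, and the classic unresolved
   two-character conflict yields a four-cycle.

Characters with identical split patterns (variants that always co-occur)
share a single network edge carrying all of them.

`extract_tree()` picks one spanning tree, Prim-style from a designated root
haplotype (by default the all-ancestral "reference" node), preferring at
each step: fewest mutations, then smallest summed character weight, then
lexicographic (position, derived base), then node id. The first key makes
the result a minimum-parsimony spanning tree of the network (verified
exhaustively in the tests on small instances); the second implements
frequency-guided branching — where a cycle admits alternatives, the
resolution that duplicates the frequent (hotspot) character and keeps the
rare character single-origin is chosen, so the high-frequency mutation
defines the basal split. Samples attach to their haplotype node as
zero-mutation tips, which is exactly what the rho statistic needs: a sampled
ancestral haplotype contributes a zero-length path.

## Rho dating

For a node `v` with `n` tips below it, `rho` is the mean number of counted
mutations on the `v`-to-tip paths, computed by the equivalent edge sum
`sum_e m_e n_e / n`. The genealogy-aware standard error is
`sigma = sqrt( sum_e (n_e/n)^2 m_e )`: a mutation shared by many tips moves
rho by more than a private one, and the error estimate weights it
accordingly. Ages are `rho x years-per-substitution` with a normal 95%
interval `+/- 1.96 sigma` on the same scale, clamped below at zero — the
`[0–…]` rows of published clade-age tables.

Three clock families are built in:

| clock | rate | counts |
|---|---|---|
| `clock_whole_mtdna()` | 1 substitution / 3,624 yr | all substitutions |
| `clock_synonymous()` | 1 synonymous substitution / 7,884 yr | synonymous only |
| `clock_hvs1(rate, base_length)` | user-supplied | fragment 16090–16365 |

The two fixed rates are the published purifying-selection-corrected linear
calibrations for the whole molecule and for synonymous positions; the
package applies them as linear rates and does not reproduce the underlying
time-dependent correction curve (clocks are pluggable if a user wants to
supply one). Indels are never counted under any rule — age-estimation
models do not cover them — and `not_coding` counts as non-synonymous
(excluded) under the synonymous rule. Fragment clocks rescale the base rate
by `scaling_base_length / fragment_length`; because published base HVS-I
rates differ, `clock_hvs1()` deliberately has no default rate.

## Founder analysis

`founder_age()` dates the arrival of lineages in a sink region: rho and
sigma are computed from a designated founder node exactly as above, but only
tips whose region label equals the sink region contribute mutations and
counts. On a node whose descendants are all sink tips this reduces to the
plain clade age (asserted on random trees in the tests).

The original practice picks founder nodes by inspection.
`scan_founder_candidates()` automates a heuristic version: a candidate
subtends at least `min_sink_tips` (default 3) sink tips and its own
haplotype state is observed in, or ancestral to, a source-region tip. Every
ancestor of such a node also satisfies the definition, so only *minimal*
qualifying nodes are returned by default; in a tree with no source tips only
the root can qualify. The heuristic is exact under infinite sites (a
sink-private mutation can never appear in a source lineage) but on real
data, where recurrent mutations blur ancestry, it is a proposal list, not an
oracle — hence user-designated founder nodes remain the primary interface.

## Population comparison on HVS-I

`pairwise_fst()` is the AMOVA-based fixation index: the between-population
variance component over the total, from squared inter-individual distances.
Two distance modes are provided; the default `haplotype_identity` scores
0/1 on sharing a fragment haplotype (conventional frequency-based FST),
`pairwise_differences` uses the count of differing positions (a
Phi-ST-like measure). Significance comes from `permutation_pvalue()`:
individuals are reassigned to the two samples (sizes preserved) and
`p = (1 + #{permuted FST >= observed}) / (n_permutations + 1)`, 10,000
permutations by default. Slightly negative FST estimates (a known property
of unbiased variance components) are reported as computed, but floored at
zero before Slatkin linearization `fst / (1 - fst)`, keeping ordination
distances non-negative. Bonferroni correction is applied wherever families
of tests are run, and `merge_nonsignificant()` pools populations (same
ethnic group across countries, or same country) that the corrected
permutation test cannot distinguish.

`mds_sstress()` ordinates the linearized matrix by minimizing Young's
S-stress (formula 1),
`sqrt( sum (d_ij^2 - delta_ij^2)^2 / sum delta_ij^4 )`, from a classical
(eigen-decomposition) start refined by BFGS descent — deterministic, no
random restarts; the terminal S-stress is reported with the centered
coordinates. This is the package's own documented criterion; no numeric
equality with any particular commercial MDS implementation is claimed.

`haplogroup_composition()` classifies each haplotype by motif against a
user-supplied classifier (label → required variant labels); the most
specific matching label wins, and a lineage matching a label whose
subclades are defined but absent is reported with a `*` suffix — e.g. an L2
lineage with no subclade motif counts as `L2*`, the convention when a
subclade (such as L2c) is not distinguishable from HVS-I alone. Matching
two disjoint top-level labels is an error, because it means the classifier
is contradictory. Composition rows always sum to 1.

## The simulator: what it emulates, and what it does not

`simulate_genealogy()` draws a matrilineal Kingman coalescent: with `k`
lineages the waiting time is exponential at rate `choose(k,2) / (2 Ne)` per
generation (so a pair coalesces after `2 Ne` generations on average),
optionally time-rescaled under exponential growth, with 25-year generations
by default. All tips sit at the present, so genealogies are exactly
clock-like. `drop_mutations()` adds Poisson substitutions per branch at a
default rate of one per 3,624 years over 16,569 sites, infinite-sites
(positions drawn without replacement, masked sites excluded), with derived
bases differing from the reference; synonymous status is classified through
the standard annotation path so the synonymous clock is testable.

`simulate_source_sink()` plants a colonization: sink samples coalesce in a
small sink deme, and at the founder time each surviving sink lineage (one,
for the default single-founder scenario) coalesces with a random source
lineage alive at that moment — the migrant carries a source haplotype of
that time. The attachment node is the recorded truth: its expected rho age
over sink tips equals the migration time, and its haplotype state is
ancestral to source tips, so both the dating and the candidate scan can be
validated against it. If the sink sample still has more lineages than
founders at the founder time, the sink genealogy is redrawn (bounded
retries, then an error), i.e. the scenario conditions on the founder
bottleneck.

`simulate_island_pair()` produces the null and alternative for the FST
machinery: at divergence 0 both samples draw from one shared pool (the
exact exchangeable null of the permutation test); at divergence `d` each
individual carries a population-private haplotype with probability `d`, so
`d = 1` gives two fixed, distinct populations and FST exactly 1. The
shared pool is itself a coalescent sample over the HVS-I fragment, by
default at one substitution per 20,180 years — the classic calibration for
this 276-bp stretch.

What the simulator does **not** emulate: recombination (absent in mtDNA),
selection, heteroplasmy, rate heterogeneity across sites (real HVS-I
hotspots violate infinite sites), sequencing error, and time-dependent
rates. Passing tests therefore demonstrate the estimators' correctness
under their own model assumptions, not robustness to the homoplasy of real
control-region data — the recurrent-mutation flagging exists precisely
because real data violate infinite sites.

## Numerical choices and problem sizes

* Ties everywhere are broken lexicographically by (position, derived base),
  then node id — determinism over elegance.
* The reduction threshold defaults to 2, the conventional value for
  reduced-median analysis; the median closure carries a safety cap
  (`max_nodes`, default 4096).
* Permutation p-values use the add-one estimator, so `p` is never 0 and the
  same seed reproduces the same value exactly.
* `mds_sstress()` converges when BFGS stalls (relative tolerance 1e-12,
  default 1000 iterations); the classical start makes the planted-recovery
  case essentially exact before refinement.
* The validation suite runs at deliberately modest sizes chosen to keep the
  whole suite under a few minutes while leaving Monte-Carlo error well
  inside the asserted bands: 2,000 pairwise-TMRCA replicates, 300
  unbiasedness replicates at n = 20, 200 end-to-end coverage replicates,
  500 null permutation pairs at n = 30 with 199 permutations each (the
  package default stays at 10,000), and 200 founder-recovery replicates.

## Known limitations

* The candidate-scan heuristic assumes infinite sites; on real data it
  over-proposes around hypervariable positions.
* The reduced-median implementation targets the data sizes of haplogroup
  studies (hundreds of haplotypes, conflicts local to a few characters);
  it makes no Steiner-optimality claims and is not a replacement for
  dedicated network software on pathological inputs.
* FST assumes the two samples cover the identical fragment; there is no
  missing-data model within the fragment.
* Clocks are linear; users who need time-dependent corrections can supply
  their own `clock()` per analysis but the package does not model the
  correction curve itself.

## A worked example

```{r example, eval = FALSE}
library(rhophylo)

# simulate a colonization with known truth
cfg <- sim_config(n_samples = 25, effective_size = 2000, seed = 7,
                  scenario = "source_sink", founder_time_years = 8000,
                  n_source = 15, n_sink = 10, sink_effective_size = 80)
sim <- simulate_source_sink(cfg)

# rebuild the phylogeny from the haplotypes alone
net  <- build_reduced_median(haplotype_matrix(sim$haplotypes))
tree <- extract_tree(net)
date_node(tree, clock_whole_mtdna())

# date the migration from the planted founder node on the true tree
founder_age(sim$tree, sim$founder_node, "Eastern",
            clock_whole_mtdna(), sim$regions)
```
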