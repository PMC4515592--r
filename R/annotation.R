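#' Mitochondrial genome constants
#'
#' The package works in 1-based, closed-interval rCRS coordinates over a
#' 16,569-bp circular genome. `MT_GENOME_LENGTH` is exported because fragment
#' clocks and the simulator scale by it.
#'
#' @export
MT_GENOME_LENGTH <- 16569L

#' HVS-I analysis fragment (positions 16090 to 16365, 276 bp)
#' @export
HVS1_RANGE <- c(16090L, 16365L)

#' Protein-coding gene annotation of the human mitochondrial genome
#'
#' Returns the 13 protein-coding genes with their canonical rCRS coordinates.
#' Because ATP8/ATP6, ATP6/COX3 and ND4L/ND4 overlap, the intervals used to
#' assign a position to a gene (`start`, `end`) are trimmed to be
#' non-overlapping (first gene keeps the shared positions assigned to the
#' later gene's frame are dropped from the earlier one); `coding_start` keeps
#' the true translation start so reading frames stay correct. `strand` is
#' "H" (heavy) except ND6, which is encoded on the light strand and is
#' translated from the reverse complement read 3'->5' in rCRS coordinates.
#'
#' Positions outside every interval (control region, rRNAs, tRNAs) are
#' treated as non-coding by [classify_synonymous()].
#'
#' @return data.frame with columns `gene`, `start`, `end`, `coding_start`,
#'   `coding_end`, `strand`.
#' @export
mt_annotation <- function() {
  ann <- data.frame(
    gene = c("ND1", "ND2", "COX1", "COX2", "ATP8", "ATP6", "COX3",
             "ND3", "ND4L", "ND4", "ND5", "ND6", "CYTB"),
    coding_start = c(3307L, 4470L, 5904L, 7586L, 8366L, 8527L, 9207L,
                     10059L, 10470L, 10760L, 12337L, 14149L, 14747L),
    coding_end = c(4262L, 5511L, 7445L, 8269L, 8572L, 9206L, 9990L,
                   10404L, 10766L, 12137L, 14148L, 14673L, 15887L),
    strand = c("H", "H", "H", "H", "H", "H", "H",
               "H", "H", "H", "H", "L", "H"),
    stringsAsFactors = FALSE
  )
  # non-overlapping assignment intervals: later gene wins the shared stretch
  ann$start <- ann$coding_start
  ann$end <- ann$coding_end
  ann$end[ann$gene == "ATP8"] <- 8526L   # 8527-8572 assigned to ATP6
  ann$end[ann$gene == "ND4L"] <- 10759L  # 10760-10766 assigned to ND4
  stopifnot(all(ann$start[-1] > ann$end[-nrow(ann)]))
  ann
}

#' Vertebrate mitochondrial genetic code
#'
#' Codon -> amino-acid map (translation table 2): AGA/AGG are stops,
#' ATA codes Met and TGA codes Trp.
#'
#' @return named character vector of length 64 (DNA codons).
#' @export
mt_genetic_code <- function() {
  bases <- c("T", "C", "A", "G")
  # amino acids in TCAG order, first base slowest, third fastest
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CCWW",   # T..
    "LLLLPPPPHHQQRRRR",   # C..
    "IIMMTTTTNNKKSS**",   # A.. (ATA=M, AGA/AGG=*)
    "VVVVAAAADDEEGGGG"    # G.. (TGA=W handled in the T row)
  ), "")[[1]]
  codons <- character(64)
  i <- 0L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    i <- i + 1L
    codons[i] <- paste0(b1, b2, b3)
  }
  stats::setNames(aa, codons)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "-" = "-")

#' Reverse complement of a base vector
#' @keywords internal
rev_comp <- function(bases) rev(unname(COMPLEMENT[bases]))

#' Deterministic synthetic stand-in for the rCRS reference sequence
#'
#' A fixed pseudo-random 16,569-bp nucleotide sequence used by the simulator
#' and the test-suite wherever a full-length reference is needed. It is a
#' synthetic stand-in, not the real revised Cambridge Reference Sequence:
#' analyses of real data must pass the genuine reference FASTA. The sequence
#' is identical on every call and in every session.
#'
#' @param length genome length (default 16,569).
#' @return single character string of A/C/G/T.
#' @export
synthetic_reference <- function(length = MT_GENOME_LENGTH) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(16569L)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
               prob = c(0.31, 0.31, 0.13, 0.25)), collapse = "")
}

#' Coding positions under the packaged annotation
#' @param annotation gene table from [mt_annotation()].
#' @return integer vector of all positions inside protein-coding genes.
#' @export
coding_positions <- function(annotation = mt_annotation()) {
  unlist(Map(seq.int, annotation$start, annotation$end), use.names = FALSE)
}
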