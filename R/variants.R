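#' Empty variant table
#'
#' Variants are stored as a data.frame with one row per difference from the
#' reference: `position` (1-based rCRS coordinate), `subindex` (0 for
#' substitutions/deletions; 1,2,... for insertions anchored to the preceding
#' reference position), `ref`, `alt` (gap token "-" for deletions),
#' `class` (substitution / insertion / deletion) and `synonymous`
#' (yes / no / not_coding; NA until classified).
#'
#' @return zero-row variant data.frame.
#' @export
empty_variants <- function() {
  data.frame(position = integer(), subindex = integer(),
             ref = character(), alt = character(), class = character(),
             synonymous = character(), stringsAsFactors = FALSE)
}

#' Construct a variant table
#'
#' @param position integer vector of 1-based reference positions.
#' @param ref,alt reference and derived bases ("-" marks a deletion's alt).
#' @param class variant classes; inferred from `alt`/`subindex` if missing.
#' @param subindex insertion sub-index (0 for non-insertions).
#' @param synonymous optional tri-state "yes"/"no"/"not_coding".
#' @return variant data.frame, ordered by (position, subindex, alt).
#' @export
variant_table <- function(position, ref, alt, class = NULL,
                          subindex = 0L, synonymous = NA_character_) {
  n <- length(position)
  if (n == 0L) return(empty_variants())
  subindex <- rep_len(as.integer(subindex), n)
  if (is.null(class)) {
    class <- ifelse(subindex > 0L, "insertion",
                    ifelse(alt == "-", "deletion", "substitution"))
  }
  v <- data.frame(position = as.integer(position),
                  subindex = subindex,
                  ref = as.character(ref), alt = as.character(alt),
                  class = as.character(class),
                  synonymous = rep_len(as.character(synonymous), n),
                  stringsAsFactors = FALSE)
  bad <- v$position < 1L | v$position > MT_GENOME_LENGTH
  if (any(bad)) stop("variant position outside [1, ", MT_GENOME_LENGTH, "]")
  if (any(v$class == "substitution" & v$ref == v$alt)) {
    stop("substitution with derived base equal to the reference base")
  }
  v[order(v$position, v$subindex, v$alt), , drop = FALSE]
}

#' PhyloTree-style variant labels
#'
#' Substitutions are written refPOSalt (e.g. "A750G"), deletions "A750d",
#' insertions "750.1C".
#'
#' @param variants variant data.frame.
#' @return character vector of labels.
#' @export
variant_labels <- function(variants) {
  if (nrow(variants) == 0L) return(character())
  ifelse(variants$class == "insertion",
         paste0(variants$position, ".", variants$subindex, variants$alt),
         ifelse(variants$class == "deletion",
                paste0(variants$ref, variants$position, "d"),
                paste0(variants$ref, variants$position, variants$alt)))
}

variant_keys <- function(variants) {
  if (nrow(variants) == 0L) return(character())
  paste(variants$position, variants$subindex, variants$alt, variants$class,
        sep = ":")
}

#' Construct a haplotype
#'
#' A haplotype is one sample's set of differences from the reference plus its
#' population metadata and the reference interval its sequence covers.
#'
#' @param sample_id sample identifier.
#' @param variants variant data.frame (see [variant_table()]).
#' @param population population name.
#' @param region one of "Western", "Central", "Eastern", "Southern", "other".
#' @param covered_range length-2 integer vector, closed interval of covered
#'   rCRS positions.
#' @return object of class `haplotype`.
#' @export
haplotype <- function(sample_id, variants = empty_variants(),
                      population = NA_character_, region = "other",
                      covered_range = c(1L, MT_GENOME_LENGTH)) {
  region <- match.arg(region,
                      c("Western", "Central", "Eastern", "Southern", "other"))
  covered_range <- as.integer(covered_range)
  stopifnot(length(covered_range) == 2L,
            covered_range[1] <= covered_range[2])
  out <- variants$position < covered_range[1] |
    variants$position > covered_range[2]
  if (any(out)) {
    stop("variant position outside covered_range for sample ", sample_id)
  }
  key <- paste(variants$position, variants$subindex)
  if (anyDuplicated(key)) {
    stop("duplicate variant positions in haplotype of sample ", sample_id)
  }
  structure(list(sample_id = as.character(sample_id), variants = variants,
                 population = population, region = region,
                 covered_range = covered_range),
            class = "haplotype")
}

#' @export
print.haplotype <- function(x, ...) {
  cat("<haplotype>", x$sample_id, " (", x$population, ", ", x$region, ")\n",
      "  covers ", x$covered_range[1], "-", x$covered_range[2], "; ",
      nrow(x$variants), " variant(s): ",
      paste(variant_labels(x$variants), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Call variants of an aligned sequence against a reference
#'
#' The sequence must be positionally aligned to the reference: either the
#' full molecule (equal length once alignment gaps are counted) or a fragment
#' whose first base sits at reference position `offset`. Gaps ("-") in the
#' sample produce deletions; gaps in the reference produce insertions
#' anchored to the preceding reference position with sub-indices 1,2,...;
#' ambiguity code N never yields a variant.
#'
#' @param sequence sample sequence (character string, may contain "-"/"N").
#' @param reference reference sequence aligned to the sample ("-" where the
#'   sample carries an insertion).
#' @param offset reference coordinate of the first reference base of the
#'   alignment (1 for whole-molecule input; e.g. 16090 for an HVS-I fragment).
#' @return variant data.frame.
#' @export
call_variants <- function(sequence, reference, offset = 1L) {
  s <- strsplit(toupper(sequence), "")[[1]]
  r <- strsplit(toupper(reference), "")[[1]]
  if (length(s) != length(r)) {
    stop("sequence and reference have different aligned lengths (",
         length(s), " vs ", length(r),
         "); input must be positionally aligned")
  }
  ok <- c("A", "C", "G", "T", "N", "-")
  bad <- setdiff(unique(c(s, r)), ok)
  if (length(bad) > 0L) {
    stop("non-nucleotide character(s) in input: ",
         paste(bad, collapse = ", "))
  }
  pos <- offset - 1L + cumsum(r != "-")  # reference coordinate per column
  diffs <- which(s != r & s != "N")
  if (length(diffs) == 0L) return(empty_variants())
  res <- lapply(diffs, function(i) {
    if (r[i] == "-") {           # insertion, anchored to preceding position
      list(position = max(pos[i], offset), sub = NA_integer_,
           ref = "-", alt = s[i], class = "insertion")
    } else if (s[i] == "-") {
      list(position = pos[i], sub = 0L, ref = r[i], alt = "-",
           class = "deletion")
    } else {
      list(position = pos[i], sub = 0L, ref = r[i], alt = s[i],
           class = "substitution")
    }
  })
  position <- vapply(res, `[[`, integer(1), "position")
  sub <- vapply(res, `[[`, integer(1), "sub")
  # number insertions at the same anchor 1,2,... in alignment order
  ins <- which(is.na(sub))
  if (length(ins) > 0L) sub[ins] <- stats::ave(ins, position[ins],
                                               FUN = seq_along)
  variant_table(position,
                ref = vapply(res, `[[`, character(1), "ref"),
                alt = vapply(res, `[[`, character(1), "alt"),
                class = vapply(res, `[[`, character(1), "class"),
                subindex = sub)
}

#' Apply substitutions to a reference sequence
#'
#' Inverse of [call_variants()] for substitution-only variant sets; used for
#' round-trip checks and to materialize simulated sequences.
#'
#' @param reference reference string.
#' @param variants variant data.frame (substitutions only).
#' @param offset reference coordinate of the first base of `reference`.
#' @return derived sequence string.
#' @export
apply_variants <- function(reference, variants, offset = 1L) {
  if (any(variants$class != "substitution")) {
    stop("apply_variants handles substitutions only")
  }
  s <- strsplit(toupper(reference), "")[[1]]
  idx <- variants$position - offset + 1L
  stopifnot(all(idx >= 1L & idx <= length(s)))
  s[idx] <- variants$alt
  paste(s, collapse = "")
}

#' Classify substitutions as synonymous, non-synonymous or non-coding
#'
#' A substitution is synonymous iff the codon containing it translates to the
#' same amino acid before and after the change, under the packaged
#' protein-coding annotation and the vertebrate mitochondrial code. Positions
#' outside every protein-coding gene (control region, rRNAs, tRNAs) are
#' "not_coding", as are positions in a gene's incomplete terminal codon
#' (those codons are completed by polyadenylation of the transcript, so
#' synonymy is undefined at the DNA level). Indels are rejected: synonymy is
#' undefined for them.
#'
#' @param variants variant data.frame of substitutions.
#' @param reference full-length reference string the positions refer to.
#' @param annotation gene table, see [mt_annotation()].
#' @return the variant data.frame with its `synonymous` column filled.
#' @export
classify_synonymous <- function(variants, reference,
                                annotation = mt_annotation()) {
  if (nrow(variants) == 0L) return(variants)
  if (any(variants$class != "substitution")) {
    stop("synonymy is undefined for indels; classify substitutions only")
  }
  refv <- strsplit(toupper(reference), "")[[1]]
  if (length(refv) < max(annotation$end)) {
    stop("reference shorter than the packaged annotation span")
  }
  code <- mt_genetic_code()
  variants$synonymous <- vapply(seq_len(nrow(variants)), function(i) {
    p <- variants$position[i]
    g <- which(annotation$start <= p & annotation$end >= p)
    if (length(g) == 0L) return("not_coding")
    g <- annotation[g, ]
    gene_len <- g$coding_end - g$coding_start + 1L
    if (g$strand == "H") {
      off <- p - g$coding_start
      # incomplete terminal codon (completed by polyadenylation in vivo):
      # synonymy is undefined there, treat as non-coding
      if (off %/% 3L >= gene_len %/% 3L) return("not_coding")
      cod_pos <- g$coding_start + (off %/% 3L) * 3L + 0:2
      before <- refv[cod_pos]
      after <- before
      after[off %% 3L + 1L] <- variants$alt[i]
    } else {  # light strand: read 3'->5' in rCRS coordinates, complemented
      off <- g$coding_end - p
      if (off %/% 3L >= gene_len %/% 3L) return("not_coding")
      cod_pos <- g$coding_end - ((off %/% 3L) * 3L + 0:2)
      before <- unname(COMPLEMENT[refv[cod_pos]])
      after <- before
      after[off %% 3L + 1L] <- unname(COMPLEMENT[variants$alt[i]])
    }
    if (identical(code[[paste(before, collapse = "")]],
                  code[[paste(after, collapse = "")]])) "yes" else "no"
  }, character(1))
  variants
}

#' Remove masked positions and (optionally) indels from a haplotype
#'
#' Mirrors the exclusion step applied before dating: positions removed for
#' phylogenetic reconstruction are dropped, and indels can be dropped because
#' age estimation does not model them. The input is not modified.
#'
#' @param h haplotype.
#' @param masked_positions integer vector of positions to drop.
#' @param drop_indels also drop insertions and deletions.
#' @return new haplotype.
#' @export
mask_haplotype <- function(h, masked_positions = integer(),
                           drop_indels = FALSE) {
  stopifnot(inherits(h, "haplotype"))
  v <- h$variants
  keep <- !(v$position %in% masked_positions)
  if (drop_indels) keep <- keep & v$class == "substitution"
  h$variants <- v[keep, , drop = FALSE]
  h
}

#' Restrict a haplotype to a reference fragment
#'
#' Keeps only variants inside the closed interval `[start, end]` and narrows
#' `covered_range` accordingly; the HVS-I analysis fragment 16090-16365 spans
#' 276 positions.
#'
#' @param h haplotype.
#' @param start,end 1-based closed fragment bounds.
#' @return new haplotype covering `[start, end]`.
#' @export
extract_fragment <- function(h, start, end) {
  stopifnot(inherits(h, "haplotype"), start <= end)
  if (start < h$covered_range[1] || end > h$covered_range[2]) {
    stop("fragment [", start, ", ", end, "] outside covered range [",
         h$covered_range[1], ", ", h$covered_range[2], "] of sample ",
         h$sample_id)
  }
  v <- h$variants
  h$variants <- v[v$position >= start & v$position <= end, , drop = FALSE]
  h$covered_range <- c(as.integer(start), as.integer(end))
  h
}

#' Fragment length of a haplotype's covered range
#' @param h haplotype.
#' @return integer number of covered reference positions.
#' @export
fragment_length <- function(h) {
  diff(h$covered_range) + 1L
}
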