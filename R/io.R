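#' Read aligned sequences and per-sample metadata
#'
#' Sequences must already be aligned to reference coordinates (this package
#' never aligns). Whole-molecule input must match the reference's aligned
#' length; fragment input (e.g. HVS-I) must declare the reference coordinate
#' of its first base via `fragment_start`. Metadata is a TSV with at least
#' `sample_id`, `population`, `region` columns (`country` and `language` are
#' carried through when present) and is joined on the FASTA names.
#'
#' @param fasta_path path to a FASTA file.
#' @param metadata_path path to a tab-separated metadata file.
#' @param fragment_start reference position of the first column, or NULL for
#'   whole-molecule input.
#' @return list of records, each with `sample_id`, `sequence`, `population`,
#'   `region`, `country`, `language`, `offset`.
#' @export
read_fasta_with_metadata <- function(fasta_path, metadata_path,
                                     fragment_start = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "population", "region")
  if (!all(need %in% names(meta))) {
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  }
  ids <- names(seqs)
  missing <- setdiff(ids, meta$sample_id)
  if (length(missing) > 0L) {
    stop("no metadata row for sample(s): ", paste(missing, collapse = ", "))
  }
  offset <- if (is.null(fragment_start)) 1L else as.integer(fragment_start)
  lapply(seq_along(seqs), function(i) {
    m <- meta[match(ids[i], meta$sample_id), ]
    list(sample_id = ids[i], sequence = as.character(seqs[[i]]),
         population = m$population, region = m$region,
         country = if ("country" %in% names(m)) m$country else NA_character_,
         language = if ("language" %in% names(m)) m$language else NA_character_,
         offset = offset)
  })
}

#' Convert sequence records into haplotypes
#'
#' Calls variants for each record of [read_fasta_with_metadata()] against the
#' matching stretch of the reference and optionally classifies substitutions
#' as synonymous.
#'
#' @param records list from [read_fasta_with_metadata()].
#' @param reference full-length reference sequence string.
#' @param classify classify substitution synonymy with the packaged
#'   annotation (whole-molecule records only make this meaningful).
#' @param annotation gene table for classification.
#' @return list of [haplotype()] objects.
#' @export
haplotypes_from_records <- function(records, reference, classify = TRUE,
                                    annotation = mt_annotation()) {
  refv <- strsplit(toupper(reference), "")[[1]]
  lapply(records, function(rec) {
    s <- rec$sequence
    if (rec$offset == 1L && nchar(s) == length(refv)) {
      ref_window <- reference
    } else {
      ref_window <- paste(refv[rec$offset:(rec$offset + nchar(s) - 1L)],
                          collapse = "")
    }
    v <- call_variants(s, ref_window, offset = rec$offset)
    if (classify && any(v$class == "substitution")) {
      sub <- v$class == "substitution"
      v[sub, ] <- classify_synonymous(v[sub, , drop = FALSE], reference,
                                      annotation)
    }
    covered <- c(rec$offset,
                 rec$offset + sum(strsplit(ref_window, "")[[1]] != "-") - 1L)
    haplotype(rec$sample_id, v, population = rec$population,
              region = rec$region, covered_range = covered)
  })
}

#' Write haplotypes as FASTA plus metadata TSV
#'
#' Materializes each haplotype's sequence by applying its substitutions to
#' the reference over its covered range (indels are not materialized) and
#' writes the two files the pipeline reads back.
#'
#' @param haplotypes list of haplotypes sharing one covered range.
#' @param reference full-length reference string.
#' @param fasta_path,metadata_path output paths.
#' @return invisibly, the two paths.
#' @export
write_haplotype_fasta <- function(haplotypes, reference, fasta_path,
                                  metadata_path) {
  covered <- haplotypes[[1]]$covered_range
  refv <- strsplit(toupper(reference), "")[[1]]
  window <- paste(refv[covered[1]:covered[2]], collapse = "")
  seqs <- vapply(haplotypes, function(h) {
    stopifnot(identical(h$covered_range, covered))
    v <- h$variants[h$variants$class == "substitution", , drop = FALSE]
    apply_variants(window, v, offset = covered[1])
  }, character(1))
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- vapply(haplotypes, `[[`, character(1), "sample_id")
  Biostrings::writeXStringSet(dna, fasta_path)
  meta <- data.frame(
    sample_id = names(dna),
    population = vapply(haplotypes, `[[`, character(1), "population"),
    region = vapply(haplotypes, `[[`, character(1), "region"),
    stringsAsFactors = FALSE)
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta_path, metadata_path))
}

#' Export haplotypes as a variant-string table
#'
#' One row per sample with PhyloTree-style variant labels, the dialect used
#' for published haplotype tables.
#'
#' @param haplotypes list of haplotypes.
#' @param path output TSV path (NULL returns the data.frame).
#' @return data.frame with columns sample_id, population, region,
#'   covered_start, covered_end, variants.
#' @export
write_haplotype_table <- function(haplotypes, path = NULL) {
  tab <- data.frame(
    sample_id = vapply(haplotypes, `[[`, character(1), "sample_id"),
    population = vapply(haplotypes, `[[`, character(1), "population"),
    region = vapply(haplotypes, `[[`, character(1), "region"),
    covered_start = vapply(haplotypes, function(h) h$covered_range[1],
                           integer(1)),
    covered_end = vapply(haplotypes, function(h) h$covered_range[2],
                         integer(1)),
    variants = vapply(haplotypes, function(h) {
      paste(variant_labels(h$variants), collapse = " ")
    }, character(1)),
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tab
}
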