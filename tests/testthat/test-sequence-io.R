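test_that("variant calling finds exactly the planted differences", {
  expect_identical(call_variants(REF, REF), empty_variants())

  s <- REFV
  s[100] <- setdiff(c("A", "C", "G", "T"), REFV[100])[1]
  v <- call_variants(paste(s, collapse = ""), REF)
  expect_equal(nrow(v), 1L)
  expect_equal(v$position, 100L)
  expect_equal(v$class, "substitution")

  set.seed(11)
  pos <- sort(sample(MT_GENOME_LENGTH, 5))
  planted <- mkvar(pos)
  seq5 <- apply_variants(REF, planted)
  called <- call_variants(seq5, REF)
  expect_equal(called$position, planted$position)
  expect_equal(called$alt, planted$alt)
  # round trip: re-applying the called variants reconstructs the input
  expect_identical(apply_variants(REF, called), seq5)
})

test_that("gaps become indels, N is silent, junk characters error", {
  s <- REFV
  s[50] <- "-"                 # deletion
  s[60] <- "N"                 # ambiguity: never a variant
  v <- call_variants(paste(s, collapse = ""), REF)
  expect_equal(v$class, "deletion")
  expect_equal(v$position, 50L)

  # insertion: gap in the reference, anchored to the preceding position
  samp <- paste0(substr(REF, 1, 100), "A", substr(REF, 101, nchar(REF)))
  refg <- paste0(substr(REF, 1, 100), "-", substr(REF, 101, nchar(REF)))
  v <- call_variants(samp, refg)
  expect_equal(v$class, "insertion")
  expect_equal(v$position, 100L)
  expect_equal(v$subindex, 1L)
  expect_equal(variant_labels(v), "100.1A")

  s[70] <- "X"
  expect_error(call_variants(paste(s, collapse = ""), REF),
               "non-nucleotide")
  expect_error(call_variants("ACGT", REF), "aligned")
})

test_that("fragment records are called in reference coordinates", {
  frag <- substr(REF, 16090, 16365)
  fv <- strsplit(frag, "")[[1]]
  fv[16189 - 16090 + 1] <- setdiff(c("A", "C", "G", "T"),
                                   fv[16189 - 16090 + 1])[1]
  v <- call_variants(paste(fv, collapse = ""), frag, offset = 16090L)
  expect_equal(v$position, 16189L)
})

test_that("synonymous classification matches an independent translation oracle", {
  ann <- mt_annotation()
  # control region is outside all coding genes
  v <- classify_synonymous(mkvar(16189L), REF)
  expect_equal(v$synonymous, "not_coding")

  # oracle: translate the whole gene before and after the change with
  # seqinr's vertebrate-mitochondrial translator (NCBI code 2)
  oracle <- function(pos, alt) {
    g <- ann[ann$start <= pos & ann$end >= pos, ]
    if (nrow(g) == 0L) return("not_coding")
    gene_len <- g$coding_end - g$coding_start + 1L
    off <- if (g$strand == "H") pos - g$coding_start else g$coding_end - pos
    if (off %/% 3 >= gene_len %/% 3) return("not_coding")
    span <- g$coding_start:g$coding_end
    tr <- function(basev) {
      if (g$strand == "L") {
        basev <- rev(chartr("ACGT", "TGCA", basev))
      }
      basev <- basev[seq_len(3 * (length(basev) %/% 3))]
      paste(seqinr::translate(tolower(basev), numcode = 2), collapse = "")
    }
    afterv <- REFV
    afterv[pos] <- alt
    if (tr(REFV[span]) == tr(afterv[span])) "yes" else "no"
  }
  set.seed(21)
  pos <- sample(coding_positions(ann), 1000L)
  v <- classify_synonymous(mkvar(pos), REF)
  expected <- vapply(seq_along(pos), function(i) {
    oracle(v$position[i], v$alt[i])
  }, character(1))
  expect_identical(v$synonymous, expected)
  expect_true(any(v$synonymous == "yes") && any(v$synonymous == "no"))

  # indels have no synonymy
  del <- variant_table(4000L, REFV[4000], "-", class = "deletion")
  expect_error(classify_synonymous(del, REF), "indel")
})

test_that("masking drops positions and indels without touching the input", {
  v <- rbind(mkvar(c(100, 200)),
             variant_table(300L, REFV[300], "-", class = "deletion"))
  h <- haplotype("s1", v)
  m <- mask_haplotype(h, drop_indels = TRUE)
  expect_equal(nrow(m$variants), 2L)
  expect_equal(nrow(h$variants), 3L)  # input unchanged
  expect_identical(mask_haplotype(h), h)  # empty mask, flag off: identity
  m2 <- mask_haplotype(h, masked_positions = c(100L, 200L, 300L))
  expect_equal(nrow(m2$variants), 0L)
  # idempotence
  expect_identical(mask_haplotype(m, drop_indels = TRUE), m)
})

test_that("fragment extraction uses closed intervals and is idempotent", {
  h <- mkhap("s1", c(16089, 16090, 16200, 16365, 16366))
  f <- extract_fragment(h, 16090, 16365)
  expect_equal(fragment_length(f), 276L)
  expect_equal(f$variants$position, c(16090L, 16200L, 16365L))
  expect_identical(extract_fragment(f, 16090, 16365), f)
  expect_identical(extract_fragment(h, 1, MT_GENOME_LENGTH), h)
  expect_error(extract_fragment(f, 16000, 16100), "outside covered range")
})

test_that("FASTA + metadata read/write round-trips simulated data", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_samples = 6, effective_size = 600, seed = 31)
  sim <- simulate_panmictic(cfg)
  write_simulation(sim, dir)
  recs <- read_fasta_with_metadata(file.path(dir, "samples.fasta"),
                                   file.path(dir, "samples.tsv"))
  expect_length(recs, 6L)
  haps <- haplotypes_from_records(recs, REF)
  got <- lapply(haps, function(h) variant_keys(h$variants))
  names(got) <- vapply(haps, `[[`, character(1), "sample_id")
  want <- lapply(sim$haplotypes, function(h) variant_keys(h$variants))
  names(want) <- vapply(sim$haplotypes, `[[`, character(1), "sample_id")
  expect_identical(got[sort(names(got))], want[sort(names(want))])

  # a sample missing from the metadata is an error naming it
  meta <- utils::read.delim(file.path(dir, "samples.tsv"))
  utils::write.table(meta[-1, ], file.path(dir, "short.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_fasta_with_metadata(file.path(dir, "samples.fasta"),
                                        file.path(dir, "short.tsv")),
               meta$sample_id[1])
})
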