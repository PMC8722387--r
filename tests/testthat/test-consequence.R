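# Codon-level consequence calls and residue conservation.

toy_transcript <- function(codon, utr5 = "AAAA", utr3 = "TTTT") {
  cdna <- paste0(utr5, "ATG", codon, "TAA", utr3)
  data.frame(transcript_id = "toy", cdna = cdna,
             cds_start = nchar(utr5) + 1L,
             cds_end = nchar(utr5) + 9L,
             stringsAsFactors = FALSE)
}

toy_variant <- function(tx, codon_pos, alt) {
  pos <- tx$cds_start + 3L + (codon_pos - 1L)
  row <- row_with_counts()
  row$transcript_id <- "toy"
  row$position <- pos
  row$ref <- substr(tx$cdna, pos, pos)
  row$alt <- alt
  row
}

test_that("classic substitution types are called correctly", {
  # CGC -> TGC: Arg -> Cys missense (C>T transition at codon position 1)
  tx <- toy_transcript("CGC")
  call <- call_consequence(toy_variant(tx, 1, "T"), tx)
  expect_identical(call$ref_codon, "CGC")
  expect_identical(call$alt_codon, "TGC")
  expect_identical(call$ref_aa, "R")
  expect_identical(call$alt_aa, "C")
  expect_identical(call$consequence_class, "missense")
  expect_identical(call$codon_index, 2L)

  # ATT -> AAT: Ile -> Asn missense (T>A at codon position 2)
  tx <- toy_transcript("ATT")
  call <- call_consequence(toy_variant(tx, 2, "A"), tx)
  expect_identical(call$ref_aa, "I")
  expect_identical(call$alt_aa, "N")
  expect_identical(call$consequence_class, "missense")

  # GCT -> GCC: wobble-position synonymous
  tx <- toy_transcript("GCT")
  call <- call_consequence(toy_variant(tx, 3, "C"), tx)
  expect_identical(call$consequence_class, "synonymous")

  # TGG -> TGA: nonsense; and stop loss on the terminal codon
  tx <- toy_transcript("TGG")
  call <- call_consequence(toy_variant(tx, 3, "A"), tx)
  expect_identical(call$consequence_class, "nonsense")

  tx <- toy_transcript("GGG")
  row <- row_with_counts()
  row$transcript_id <- "toy"
  row$position <- tx$cds_end - 1L  # TAA -> TCA
  row$ref <- "A"; row$alt <- "C"
  call <- call_consequence(row, tx)
  expect_identical(call$consequence_class, "stop_loss")
})

test_that("all 64 codons translate by the standard genetic code", {
  codons <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                  paste0), c("T", "C", "A", "G"), paste0))
  # independent oracle: seqinr's own translation table
  expected <- vapply(codons, function(cd) {
    seqinr::translate(strsplit(cd, "")[[1]])
  }, character(1))
  for (i in seq_along(codons)) {
    tx <- toy_transcript(codons[i])
    # mutate the third base to itself-adjacent base; we only check ref_aa
    alt <- setdiff(c("A", "C", "G", "T"), substr(codons[i], 1, 1))[1]
    call <- call_consequence(toy_variant(tx, 1, alt), tx)
    expect_identical(call$ref_aa, unname(expected[i]),
                     label = sprintf("codon %s", codons[i]))
  }
})

test_that("calls agree with a whole-ORF retranslate-and-diff oracle", {
  set.seed(33)
  tx_all <- simulate_transcripts(50, c(10, 40), c(5, 8))
  for (i in seq_len(nrow(tx_all))) {
    tx <- tx_all[i, ]
    v <- random_variant_on(tx)
    call <- call_consequences(v, tx)
    oracle <- oracle_consequence(v, tx)
    expect_identical(call$consequence_class, oracle$consequence_class)
    if (call$consequence_class %in% c("missense", "nonsense", "stop_loss")) {
      expect_identical(call$codon_index, as.integer(oracle$codon_index))
      expect_identical(call$ref_aa, oracle$ref_aa)
      expect_identical(call$alt_aa, oracle$alt_aa)
    }
    if (!is.na(call$codon_index)) {
      expect_identical(call$codon_index,
                       as.integer(ceiling((v$position - tx$cds_start + 1) / 3)))
    }
  }
})

test_that("UTR variants are noncoding and integrity errors are raised", {
  tx <- toy_transcript("CGC")
  row <- row_with_counts(); row$transcript_id <- "toy"
  row$position <- 2L; row$ref <- "A"; row$alt <- "G"
  expect_identical(call_consequence(row, tx)$consequence_class, "noncoding")

  # ref allele must match the cDNA
  bad <- toy_variant(tx, 1, "T")
  bad$ref <- "G"
  expect_error(call_consequence(bad, tx), "v1",
               class = "poolscreen_data_error")

  # unknown transcript
  bad <- toy_variant(tx, 1, "T")
  bad$transcript_id <- "ghost"
  expect_error(call_consequence(bad, tx), "ghost",
               class = "poolscreen_data_error")
})

test_that("conservation scoring follows the stated gap policy", {
  aln <- c(km = "MAR-KD", human = "MARCKD", mouse = "MARCKD",
           frog = "MAKCKD", fish = "MARCKD")
  cc <- conservation_at(aln, "km", 3)
  expect_equal(cc$conserved_fraction, 0.8)  # 4 R, 1 K
  expect_false(cc$is_conserved)

  # unanimity
  cc <- conservation_at(aln, "km", 2)
  expect_equal(cc$conserved_fraction, 1)
  expect_true(cc$is_conserved)

  # reference gap skipped: residue 4 of km maps past the gap column
  cc <- conservation_at(aln, "km", 4)
  expect_identical(cc$alignment_column, 5L)
  expect_identical(cc$reference_residue, "K")

  # gaps excluded from the denominator
  aln2 <- c(a = "R", b = "R", c = "R", d = "R", e = "-")
  cc <- conservation_at(aln2, "a", 1)
  expect_equal(cc$conserved_fraction, 1)
  expect_identical(cc$n_used, 4L)

  # 3 R + 2 K
  aln3 <- c(a = "R", b = "R", c = "R", d = "K", e = "K")
  expect_equal(conservation_at(aln3, "a", 1)$conserved_fraction, 0.6)

  expect_error(conservation_at(aln, "km", 99),
               class = "poolscreen_range_error")
  expect_error(conservation_at(aln, "ghost", 1),
               class = "poolscreen_config_error")
})
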