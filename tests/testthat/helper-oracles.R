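# Shared fixtures and independent oracles, built in code at test time.

# One variant-table row from explicit pool counts.
row_with_counts <- function(wt = c(20L, 0L), mut = c(0L, 25L),
                            sib = c(12L, 7L), id = "v1") {
  data.frame(variant_id = id, transcript_id = "tx1", position = 5L,
             ref = "C", alt = "T",
             wt_ref = wt[1], wt_alt = wt[2],
             mut_ref = mut[1], mut_alt = mut[2],
             sib_ref = sib[1], sib_alt = sib[2],
             stringsAsFactors = FALSE)
}

# Random variant table biased toward threshold-adjacent and fixed counts so
# every screen's boundary is exercised.
random_variant_table <- function(n) {
  draw <- function() {
    pool <- c(0:12, 0L, 0L, sample(0:200, 5L, replace = TRUE))
    sample(pool, n, replace = TRUE)
  }
  alleles <- t(replicate(n, sample(c("A", "C", "G", "T"), 2L)))
  data.frame(variant_id = sprintf("v%06d", seq_len(n)),
             transcript_id = sprintf("tx%03d", sample.int(20L, n, TRUE)),
             position = sample.int(500L, n, TRUE),
             ref = alleles[, 1], alt = alleles[, 2],
             wt_ref = draw(), wt_alt = draw(),
             mut_ref = draw(), mut_alt = draw(),
             sib_ref = draw(), sib_alt = draw(),
             stringsAsFactors = FALSE)
}

# Brute-force per-row conjunction of the six screen predicates, coded
# independently of the cascade implementation.
oracle_final_set <- function(tab, th = screen_thresholds()) {
  frac <- function(r, a) if (r + a == 0) NA_real_ else a / (r + a)
  h <- th$screen1_hom_fraction
  keep <- vapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    fwt <- frac(r$wt_ref, r$wt_alt)
    fmut <- frac(r$mut_ref, r$mut_alt)
    s1 <- isTRUE(fwt >= h && fmut <= 1 - h) ||
      isTRUE(fwt <= 1 - h && fmut >= h)
    s2 <- isTRUE(fmut == th$mut_alt_fraction_required &&
                   fwt == th$wt_alt_fraction_max)
    s3 <- r$wt_ref + r$wt_alt > th$wt_min_total
    s4 <- r$mut_ref + r$mut_alt > th$mut_min_total
    s5 <- r$sib_ref > th$sib_min_each_allele &&
      r$sib_alt > th$sib_min_each_allele
    s6 <- r$sib_ref > r$sib_alt
    s1 && s2 && s3 && s4 && s5 && s6
  }, logical(1))
  sort(tab$variant_id[keep])
}

# Whole-ORF retranslate-and-diff consequence oracle: mutate the cDNA,
# translate both ORFs with Biostrings, and diff the proteins.
oracle_consequence <- function(variant, transcript) {
  pos <- variant$position
  if (pos < transcript$cds_start || pos > transcript$cds_end) {
    return(list(consequence_class = "noncoding"))
  }
  mutated <- transcript$cdna
  substr(mutated, pos, pos) <- variant$alt
  cds <- function(x) substr(x, transcript$cds_start, transcript$cds_end)
  tr <- function(x) {
    as.character(Biostrings::translate(Biostrings::DNAString(cds(x)),
                                       no.init.codon = TRUE))
  }
  p_ref <- strsplit(tr(transcript$cdna), "")[[1]]
  p_alt <- strsplit(tr(mutated), "")[[1]]
  diff <- which(p_ref != p_alt)
  if (length(diff) == 0L) {
    ci <- ceiling((pos - transcript$cds_start + 1) / 3)
    return(list(consequence_class = "synonymous", codon_index = ci,
                ref_aa = p_ref[ci], alt_aa = p_ref[ci]))
  }
  ci <- diff[1]
  cls <- if (p_alt[ci] == "*") "nonsense"
  else if (p_ref[ci] == "*") "stop_loss"
  else "missense"
  list(consequence_class = cls, codon_index = ci,
       ref_aa = p_ref[ci], alt_aa = p_alt[ci])
}

# A random single-base substitution inside a simulated transcript.
random_variant_on <- function(transcript, id = "v1") {
  pos <- sample.int(nchar(transcript$cdna), 1L)
  ref <- substr(transcript$cdna, pos, pos)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
  data.frame(variant_id = id, transcript_id = transcript$transcript_id,
             position = pos, ref = ref, alt = alt,
             wt_ref = 20L, wt_alt = 0L, mut_ref = 0L, mut_alt = 20L,
             sib_ref = 10L, sib_alt = 8L, stringsAsFactors = FALSE)
}

# Compare two run directories byte-wise, ignoring VCF date stamps.
expect_same_run_dir <- function(dir_a, dir_b) {
  fa <- sort(list.files(dir_a))
  fb <- sort(list.files(dir_b))
  expect_identical(fa, fb)
  for (f in fa) {
    la <- readLines(file.path(dir_a, f), warn = FALSE)
    lb <- readLines(file.path(dir_b, f), warn = FALSE)
    drop <- function(x) x[!startsWith(x, "##fileDate")]
    expect_identical(drop(la), drop(lb), label = f)
  }
}
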