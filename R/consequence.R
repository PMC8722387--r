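# Codon-level consequence annotation of transcript variants, and
# cross-species conservation of the affected residue.

GAP_CHARS <- c("-", ".")

# codon -> amino acid, standard nuclear genetic code ('*' = stop).
translate_codons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  bad <- is.na(aa)
  if (any(bad)) {
    ps_stop("poolscreen_data_error", "cannot translate codon '%s'",
            codons[bad][1])
  }
  unname(aa)
}

classify_consequence <- function(ref_aa, alt_aa) {
  ifelse(ref_aa == alt_aa, "synonymous",
         ifelse(alt_aa == "*", "nonsense",
                ifelse(ref_aa == "*", "stop_loss", "missense")))
}

#' Annotate codon-level consequences of transcript variants
#'
#' Maps each variant position to its codon in the transcript's CDS (forward
#' frame anchored at `cds_start`), translates the reference and mutated
#' codons by the standard genetic code and classifies the change as
#' `synonymous`, `missense`, `nonsense`, `stop_loss`, or `noncoding` when
#' the position lies outside the CDS. The codon index is
#' `ceil((position - cds_start + 1) / 3)`. The variant's reference allele is
#' checked against the cDNA; a mismatch is a data-integrity error naming the
#' variant.
#'
#' @param variants Variant count table (see [read_variant_table()]); only
#'   the identity columns are used.
#' @param transcripts Transcript model data frame; every referenced
#'   transcript must be present.
#' @return Data frame with one row per variant: `variant_id`,
#'   `transcript_id`, `position`, `codon_index`, `ref_codon`, `alt_codon`,
#'   `ref_aa`, `alt_aa`, `consequence_class` (codon fields `NA` for
#'   noncoding variants).
#' @examples
#' tx <- data.frame(transcript_id = "tx1",
#'                  cdna = "AAAATGCGCTGATTT", cds_start = 4, cds_end = 12)
#' v <- data.frame(variant_id = "v1", transcript_id = "tx1", position = 7L,
#'                 ref = "C", alt = "T", wt_ref = 10L, wt_alt = 0L,
#'                 mut_ref = 0L, mut_alt = 10L, sib_ref = 6L, sib_alt = 5L)
#' call_consequences(v, tx)[, c("ref_aa", "alt_aa", "consequence_class")]
#' @export
call_consequences <- function(variants, transcripts) {
  variants <- validate_variant_table(variants)
  transcripts <- validate_transcripts(transcripts, require_orf = FALSE)
  idx <- match(variants$transcript_id, transcripts$transcript_id)
  if (anyNA(idx)) {
    ps_stop("poolscreen_data_error",
            "variant(s) reference missing transcript(s): %s",
            paste(unique(variants$transcript_id[is.na(idx)]), collapse = ", "))
  }
  cdna <- transcripts$cdna[idx]
  cds_start <- transcripts$cds_start[idx]
  cds_end <- transcripts$cds_end[idx]
  pos <- variants$position

  too_far <- pos > nchar(cdna)
  if (any(too_far)) {
    ps_stop("poolscreen_data_error",
            "variant '%s': position %d beyond transcript '%s' length %d",
            variants$variant_id[too_far][1], pos[too_far][1],
            variants$transcript_id[too_far][1], nchar(cdna)[too_far][1])
  }
  base <- substring(cdna, pos, pos)
  mism <- base != variants$ref
  if (any(mism)) {
    ps_stop("poolscreen_data_error",
            "variant '%s': ref allele '%s' does not match cDNA base '%s' at %s:%d",
            variants$variant_id[mism][1], variants$ref[mism][1],
            base[mism][1], variants$transcript_id[mism][1], pos[mism][1])
  }

  coding <- pos >= cds_start & pos <= cds_end
  n <- nrow(variants)
  out <- data.frame(variant_id = variants$variant_id,
                    transcript_id = variants$transcript_id,
                    position = pos,
                    codon_index = NA_integer_,
                    ref_codon = NA_character_,
                    alt_codon = NA_character_,
                    ref_aa = NA_character_,
                    alt_aa = NA_character_,
                    consequence_class = rep("noncoding", n),
                    stringsAsFactors = FALSE)
  if (any(coding)) {
    ci <- (pos[coding] - cds_start[coding]) %/% 3L + 1L
    offset <- (pos[coding] - cds_start[coding]) %% 3L + 1L
    cstart <- cds_start[coding] + 3L * (ci - 1L)
    ref_codon <- substring(cdna[coding], cstart, cstart + 2L)
    alt_codon <- ref_codon
    substr(alt_codon, offset, offset) <- variants$alt[coding]
    ref_aa <- translate_codons(ref_codon)
    alt_aa <- translate_codons(alt_codon)
    out$codon_index[coding] <- ci
    out$ref_codon[coding] <- ref_codon
    out$alt_codon[coding] <- alt_codon
    out$ref_aa[coding] <- ref_aa
    out$alt_aa[coding] <- alt_aa
    out$consequence_class[coding] <- classify_consequence(ref_aa, alt_aa)
  }
  out
}

#' Annotate a single variant
#'
#' Convenience wrapper around [call_consequences()] for one variant row and
#' one transcript model.
#'
#' @param variant One-row variant count table.
#' @param transcript One-row transcript model data frame.
#' @return One-row consequence data frame.
#' @export
call_consequence <- function(variant, transcript) {
  if (!is.data.frame(variant) || nrow(variant) != 1L) {
    ps_stop("poolscreen_config_error", "'variant' must be a single table row")
  }
  call_consequences(variant, transcript)
}

#' Read an aligned orthologue FASTA
#'
#' @param path Aligned FASTA of orthologous protein sequences (equal
#'   lengths, gaps as `-` or `.`).
#' @return Named character vector of aligned sequences.
#' @export
read_alignment <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    ps_stop("poolscreen_validation_error",
            "duplicate sequence name in alignment %s", path)
  }
  x <- as.character(seqs)
  if (length(unique(nchar(x))) > 1L) {
    ps_stop("poolscreen_validation_error",
            "alignment %s has unequal sequence lengths", path)
  }
  x
}

#' Conservation of one residue across an orthologue alignment
#'
#' Maps residue `position` of the (ungapped) reference sequence to its
#' alignment column and reports the column residues and the fraction of
#' sequences carrying the reference residue. Gap characters are excluded
#' from the denominator by default.
#'
#' @param alignment Named character vector of aligned sequences (see
#'   [read_alignment()]) or an `AAStringSet`.
#' @param reference_name Name of the reference sequence in the alignment.
#' @param position 1-based residue position in the ungapped reference.
#' @param conserved_threshold Fraction at or above which the residue is
#'   flagged conserved. Default 1.0 (unanimity).
#' @param count_gaps Include gap characters in the denominator. Default
#'   `FALSE`.
#' @return An object of class `conservation_column`: list with `residues`
#'   (named column characters), `reference_residue`, `alignment_column`,
#'   `conserved_fraction`, `is_conserved`, `n_used`.
#' @examples
#' aln <- c(fish = "MR-K", human = "MRAK", frog = "MKAK")
#' conservation_at(aln, "fish", 2)
#' @export
conservation_at <- function(alignment, reference_name, position,
                            conserved_threshold = 1.0, count_gaps = FALSE) {
  if (methods::is(alignment, "XStringSet")) {
    alignment <- as.character(alignment)
  }
  if (!is.character(alignment) || is.null(names(alignment))) {
    ps_stop("poolscreen_config_error",
            "'alignment' must be a named character vector or AAStringSet")
  }
  if (!reference_name %in% names(alignment)) {
    ps_stop("poolscreen_config_error",
            "reference sequence '%s' not found in alignment", reference_name)
  }
  if (length(unique(nchar(alignment))) > 1L) {
    ps_stop("poolscreen_validation_error",
            "alignment sequences have unequal lengths")
  }
  ref_chars <- strsplit(alignment[[reference_name]], "")[[1]]
  residue_cols <- which(!ref_chars %in% GAP_CHARS)
  if (!is_count(position) || position < 1 ||
      position > length(residue_cols)) {
    ps_stop("poolscreen_range_error",
            "residue position %s beyond reference length %d",
            toString(position), length(residue_cols))
  }
  col <- residue_cols[position]
  residues <- substring(alignment, col, col)
  ref_residue <- ref_chars[col]
  use <- if (count_gaps) rep(TRUE, length(residues)) else
    !residues %in% GAP_CHARS
  frac <- mean(residues[use] == ref_residue)
  structure(list(residues = residues,
                 reference_residue = ref_residue,
                 alignment_column = col,
                 conserved_fraction = frac,
                 is_conserved = frac >= conserved_threshold,
                 n_used = sum(use)),
            class = "conservation_column")
}

#' @export
print.conservation_column <- function(x, ...) {
  cat(sprintf("Alignment column %d (reference residue %s)\n",
              x$alignment_column, x$reference_residue))
  cat(sprintf("  %s\n",
              paste(sprintf("%s:%s", names(x$residues), x$residues),
                    collapse = "  ")))
  cat(sprintf("  conserved fraction %.3f over %d sequences%s\n",
              x$conserved_fraction, x$n_used,
              if (x$is_conserved) " (conserved)" else ""))
  invisible(x)
}

#' Write a consequence table to TSV
#'
#' @param calls Consequence data frame from [call_consequences()],
#'   optionally carrying a `conserved_fraction` column.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_consequence_table <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
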