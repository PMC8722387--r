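# Transcript models: cDNA sequences (FASTA) with CDS bounds in a sidecar
# table. De novo transcripts have no genomic strand; all coordinates are
# 1-based on the transcript's own forward orientation.

#' Validate transcript models
#'
#' Checks that CDS bounds lie inside the cDNA, that the CDS length is
#' divisible by three and, by default, that the CDS begins with ATG and ends
#' with a stop codon (disable with `require_orf = FALSE` for partial ORFs).
#' Sequences are upper-cased and RNA `U` is normalized to `T`.
#'
#' @param x Data frame with columns `transcript_id`, `cdna`, `cds_start`,
#'   `cds_end`.
#' @param require_orf Require ATG start and stop-codon end. Default `TRUE`.
#' @return The normalized, validated transcript data frame.
#' @export
validate_transcripts <- function(x, require_orf = TRUE) {
  needed <- c("transcript_id", "cdna", "cds_start", "cds_end")
  if (!is.data.frame(x) || !all(needed %in% names(x))) {
    ps_stop("poolscreen_validation_error",
            "transcript table must have columns %s",
            paste(needed, collapse = ", "))
  }
  x <- x[, needed]
  if (anyDuplicated(x$transcript_id)) {
    ps_stop("poolscreen_validation_error",
            "duplicate transcript_id '%s'",
            x$transcript_id[duplicated(x$transcript_id)][1])
  }
  x$cdna <- chartr("u", "t", x$cdna)
  x$cdna <- chartr("U", "T", toupper(x$cdna))
  bad <- grepl("[^ACGTN]", x$cdna)
  if (any(bad)) {
    ps_stop("poolscreen_validation_error",
            "transcript '%s' contains non-nucleotide characters",
            x$transcript_id[bad][1])
  }
  x$cds_start <- as.integer(x$cds_start)
  x$cds_end <- as.integer(x$cds_end)
  len <- nchar(x$cdna)
  bad <- is.na(x$cds_start) | is.na(x$cds_end) |
    x$cds_start < 1L | x$cds_start >= x$cds_end | x$cds_end > len
  if (any(bad)) {
    ps_stop("poolscreen_validation_error",
            "transcript '%s': CDS bounds [%s, %s] out of range for length %d",
            x$transcript_id[bad][1], x$cds_start[bad][1], x$cds_end[bad][1],
            len[bad][1])
  }
  cds_len <- x$cds_end - x$cds_start + 1L
  bad <- cds_len %% 3L != 0L
  if (any(bad)) {
    ps_stop("poolscreen_validation_error",
            "transcript '%s': CDS length %d not divisible by 3",
            x$transcript_id[bad][1], cds_len[bad][1])
  }
  if (require_orf) {
    first <- substr(x$cdna, x$cds_start, x$cds_start + 2L)
    last <- substr(x$cdna, x$cds_end - 2L, x$cds_end)
    bad <- first != "ATG"
    if (any(bad)) {
      ps_stop("poolscreen_validation_error",
              "transcript '%s': CDS does not begin with ATG (got %s)",
              x$transcript_id[bad][1], first[bad][1])
    }
    bad <- !last %in% STOP_CODONS
    if (any(bad)) {
      ps_stop("poolscreen_validation_error",
              "transcript '%s': CDS does not end with a stop codon (got %s)",
              x$transcript_id[bad][1], last[bad][1])
    }
  }
  rownames(x) <- NULL
  x
}

#' Read transcript cDNAs with a CDS sidecar table
#'
#' Loads a FASTA of transcript cDNA sequences and a tab-separated sidecar
#' `transcript_id cds_start cds_end` with 1-based inclusive CDS bounds, and
#' validates the combined models (see [validate_transcripts()]).
#'
#' @param fasta_path Transcript FASTA; record ids (first whitespace token)
#'   must be unique.
#' @param cds_path Sidecar TSV; every row must reference a FASTA id.
#' @param require_orf Passed to [validate_transcripts()].
#' @return Transcript model data frame (`transcript_id`, `cdna`,
#'   `cds_start`, `cds_end`).
#' @export
read_transcripts <- function(fasta_path, cds_path, require_orf = TRUE) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    ps_stop("poolscreen_validation_error",
            "duplicate FASTA id '%s' in %s", ids[duplicated(ids)][1],
            fasta_path)
  }
  cds <- read.delim(cds_path, check.names = FALSE)
  needed <- c("transcript_id", "cds_start", "cds_end")
  if (!all(needed %in% names(cds))) {
    ps_stop("poolscreen_parse_error",
            "%s: malformed header; expected columns %s", cds_path,
            paste(needed, collapse = " "))
  }
  missing <- setdiff(cds$transcript_id, ids)
  if (length(missing)) {
    ps_stop("poolscreen_validation_error",
            "sidecar id(s) absent from FASTA: %s",
            paste(missing, collapse = ", "))
  }
  x <- data.frame(transcript_id = cds$transcript_id,
                  cdna = as.character(seqs)[match(cds$transcript_id, ids)],
                  cds_start = cds$cds_start,
                  cds_end = cds$cds_end,
                  stringsAsFactors = FALSE)
  validate_transcripts(x, require_orf = require_orf)
}

#' Write transcript models to FASTA plus CDS sidecar
#'
#' @param x Transcript model data frame.
#' @param fasta_path,cds_path Output paths.
#' @return Invisibly, `c(fasta_path, cds_path)`.
#' @export
write_transcripts <- function(x, fasta_path, cds_path) {
  x <- validate_transcripts(x, require_orf = FALSE)
  seqs <- Biostrings::DNAStringSet(setNames(x$cdna, x$transcript_id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  write.table(x[, c("transcript_id", "cds_start", "cds_end")], cds_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, cds_path))
}
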