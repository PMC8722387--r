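#' Export variants to VCF
#'
#' Writes one VCF v4.3 record per variant with `CHROM` set to the transcript
#' id, `POS` to the 1-based transcript position (both conventions are
#' 1-based, so no coordinate shift is performed), `REF`/`ALT` from the
#' alleles, and per-pool read counts as `AD` sample fields for the samples
#' `WT`, `MUT` and `SIB`. Transcript lengths populate the contig header.
#'
#' @param variants Variant count table (see [read_variant_table()]).
#' @param transcripts Transcript model data frame; every
#'   `variants$transcript_id` must be present.
#' @param path Output path (plain-text `.vcf`).
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(variants, transcripts, path) {
  variants <- validate_variant_table(variants)
  transcripts <- validate_transcripts(transcripts, require_orf = FALSE)
  missing <- setdiff(unique(variants$transcript_id),
                     transcripts$transcript_id)
  if (length(missing)) {
    ps_stop("poolscreen_validation_error",
            "variants reference transcript(s) missing from the model: %s",
            paste(missing, collapse = ", "))
  }
  samples <- c("WT", "MUT", "SIB")
  seqlen <- setNames(nchar(transcripts$cdna), transcripts$transcript_id)
  n <- nrow(variants)
  gr <- GenomicRanges::GRanges(
    seqnames = if (n) variants$transcript_id else character(0),
    ranges = IRanges::IRanges(start = variants$position, width = 1L),
    seqlengths = seqlen)
  names(gr) <- variants$variant_id
  ad_pair <- function(r, a) {
    lapply(seq_along(r), function(i) c(r[i], a[i]))
  }
  ad <- matrix(c(ad_pair(variants$wt_ref, variants$wt_alt),
                 ad_pair(variants$mut_ref, variants$mut_alt),
                 ad_pair(variants$sib_ref, variants$sib_alt)),
               ncol = 3L, dimnames = list(variants$variant_id, samples))
  hdr <- VariantAnnotation::VCFHeader(samples = samples)
  VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
    fileformat = S4Vectors::DataFrame(Value = "VCFv4.3",
                                      row.names = "fileformat"))
  VariantAnnotation::geno(hdr) <- S4Vectors::DataFrame(
    Number = "R", Type = "Integer",
    Description = "Read depth for the ref and alt alleles, per pool",
    row.names = "AD")
  vcf <- VariantAnnotation::VCF(
    rowRanges = gr,
    colData = S4Vectors::DataFrame(row.names = samples),
    fixed = S4Vectors::DataFrame(
      REF = Biostrings::DNAStringSet(variants$ref),
      ALT = Biostrings::DNAStringSetList(as.list(variants$alt)),
      QUAL = rep(NA_real_, n),
      FILTER = rep("PASS", n)),
    geno = S4Vectors::SimpleList(AD = ad),
    collapsed = TRUE)
  S4Vectors::metadata(vcf)$header <- hdr
  VariantAnnotation::writeVcf(vcf, path)
  invisible(path)
}
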