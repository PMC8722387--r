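#' Parameters of a simulated selfing cross
#'
#' Describes the cross whose pooled RNA-seq allele counts are simulated by
#' [simulate_cross()]: an F2 brood of a single self-fertilizing parent that is
#' heterozygous for one recessive lethal allele, on a near-isogenic background
#' carrying mutagen-induced and residual strain variants. Defaults describe a
#' screen of 20 embryos per phenotype pool sequenced to a mean per-site depth
#' of 50 reads, with 5000 non-causal variant sites.
#'
#' @param n_embryos_per_pool Embryos pooled per phenotype group (mutant,
#'   sibling, wild type). Default 20.
#' @param n_background_variants Number of non-causal variant sites (induced
#'   mutations plus residual strain polymorphism). Default 5000.
#' @param residual_het_rate Probability that a background site is a residual
#'   strain polymorphism, heterozygous in both the wild-type strain and the
#'   mutagenized founder. Default `3e-4`, the non-isogenic fraction of a
#'   highly inbred line (99.97% SNP homozygosity).
#' @param enu_het_rate Probability that a background site is an induced
#'   mutation still heterozygous in the founder; the remaining sites are
#'   homozygous in the founder (split evenly between reference and alternate
#'   relative to the wild-type strain, i.e. fixed differences). Default 0.1:
#'   after repeated generations of selfing most induced variants are fixed.
#' @param depth_mean,depth_dispersion Per-site, per-pool read depth is drawn
#'   from a negative binomial with this mean and size (dispersion) parameter;
#'   large `depth_dispersion` approaches Poisson coverage. Defaults 50 and 10.
#' @param seq_error_rate Per-read probability of miscalling the allele;
#'   errors flip between the two alleles symmetrically. Default 0.005.
#' @param expression_weight_dispersion Variance of per-embryo expression
#'   weights (gamma with mean 1). RNA pools measure expression-weighted
#'   allele dosage; 0 (the default) models equal expression across embryos.
#' @param n_transcripts Number of synthetic transcripts carrying the variant
#'   sites. Default 300.
#' @param cds_codon_range Length-2 integer range of CDS codon counts per
#'   transcript (start and stop codon included). Default `c(150, 450)`.
#' @param utr_lengths Length-2 integer vector: 5' and 3' UTR lengths in nt.
#'   Default `c(60, 100)`.
#' @param causal_allele Optional list `(transcript_id, position, ref, alt)`
#'   naming the planted recessive mutation when simulating on user-supplied
#'   transcripts. `NULL` (default) lets the generator plant a missense
#'   C-to-T transition (an arginine-to-cysteine codon change) at a random
#'   internal CDS codon.
#' @param n_downregulated Number of transcripts given a planted expression
#'   decrease in the mutant pool for the coverage comparison. Default 30.
#' @param downregulation_lfc log2 fold change applied to planted
#'   downregulated transcripts. Default -2.
#' @param seed Integer seed for the pseudo-random stream. Mandatory: the
#'   generator never seeds itself from the clock.
#'
#' @return An object of class `cross_model` (a validated named list).
#' @seealso [simulate_cross()], [build_pools()], [sequence_pools()]
#' @examples
#' model <- cross_model(seed = 1, n_background_variants = 100,
#'                      n_transcripts = 20)
#' model
#' @export
cross_model <- function(n_embryos_per_pool = 20L,
                        n_background_variants = 5000L,
                        residual_het_rate = 3e-4,
                        enu_het_rate = 0.1,
                        depth_mean = 50,
                        depth_dispersion = 10,
                        seq_error_rate = 0.005,
                        expression_weight_dispersion = 0,
                        n_transcripts = 300L,
                        cds_codon_range = c(150L, 450L),
                        utr_lengths = c(60L, 100L),
                        causal_allele = NULL,
                        n_downregulated = 30L,
                        downregulation_lfc = -2,
                        seed) {
  if (missing(seed)) {
    ps_stop("poolscreen_config_error",
            "cross_model() requires an explicit integer 'seed'")
  }
  if (!is_count(seed)) {
    ps_stop("poolscreen_config_error", "'seed' must be a single integer")
  }
  if (!is_count(n_embryos_per_pool) || n_embryos_per_pool < 1) {
    ps_stop("poolscreen_config_error",
            "'n_embryos_per_pool' must be an integer >= 1")
  }
  if (!is_count(n_background_variants)) {
    ps_stop("poolscreen_config_error",
            "'n_background_variants' must be a non-negative integer")
  }
  for (nm in c("residual_het_rate", "enu_het_rate", "seq_error_rate")) {
    if (!is_rate(get(nm))) {
      ps_stop("poolscreen_config_error", "'%s' must be a rate in [0, 1]", nm)
    }
  }
  if (residual_het_rate + enu_het_rate > 1) {
    ps_stop("poolscreen_config_error",
            "residual_het_rate + enu_het_rate must not exceed 1")
  }
  if (!is.numeric(depth_mean) || length(depth_mean) != 1L || depth_mean <= 0) {
    ps_stop("poolscreen_config_error", "'depth_mean' must be > 0")
  }
  if (!is.numeric(depth_dispersion) || length(depth_dispersion) != 1L ||
      depth_dispersion <= 0) {
    ps_stop("poolscreen_config_error", "'depth_dispersion' must be > 0")
  }
  if (!is.numeric(expression_weight_dispersion) ||
      expression_weight_dispersion < 0) {
    ps_stop("poolscreen_config_error",
            "'expression_weight_dispersion' must be >= 0")
  }
  if (!is_count(n_transcripts) || n_transcripts < 1) {
    ps_stop("poolscreen_config_error", "'n_transcripts' must be >= 1")
  }
  cds_codon_range <- as.integer(cds_codon_range)
  if (length(cds_codon_range) != 2L || any(cds_codon_range < 3L) ||
      cds_codon_range[1] > cds_codon_range[2]) {
    ps_stop("poolscreen_config_error",
            "'cds_codon_range' must be an increasing pair of integers >= 3")
  }
  utr_lengths <- as.integer(utr_lengths)
  if (length(utr_lengths) != 2L || any(utr_lengths < 1L)) {
    ps_stop("poolscreen_config_error",
            "'utr_lengths' must be two positive integers")
  }
  if (!is.null(causal_allele)) {
    needed <- c("transcript_id", "position", "ref", "alt")
    if (!is.list(causal_allele) || !all(needed %in% names(causal_allele))) {
      ps_stop("poolscreen_config_error",
              "'causal_allele' must be a list with fields %s",
              paste(needed, collapse = ", "))
    }
  }
  if (!is_count(n_downregulated)) {
    ps_stop("poolscreen_config_error",
            "'n_downregulated' must be a non-negative integer")
  }
  structure(
    list(n_embryos_per_pool = as.integer(n_embryos_per_pool),
         n_background_variants = as.integer(n_background_variants),
         residual_het_rate = residual_het_rate,
         enu_het_rate = enu_het_rate,
         depth_mean = depth_mean,
         depth_dispersion = depth_dispersion,
         seq_error_rate = seq_error_rate,
         expression_weight_dispersion = expression_weight_dispersion,
         n_transcripts = as.integer(n_transcripts),
         cds_codon_range = cds_codon_range,
         utr_lengths = utr_lengths,
         causal_allele = causal_allele,
         n_downregulated = as.integer(n_downregulated),
         downregulation_lfc = downregulation_lfc,
         seed = as.integer(seed)),
    class = "cross_model")
}

#' @export
print.cross_model <- function(x, ...) {
  cat("Selfing-cross simulation model\n")
  cat(sprintf("  embryos per pool     : %d\n", x$n_embryos_per_pool))
  cat(sprintf("  background variants  : %d\n", x$n_background_variants))
  cat(sprintf("  founder het rates    : residual %.4g + induced %.4g\n",
              x$residual_het_rate, x$enu_het_rate))
  cat(sprintf("  depth (NB mean,size) : %.4g, %.4g\n",
              x$depth_mean, x$depth_dispersion))
  cat(sprintf("  sequencing error     : %.4g per read\n", x$seq_error_rate))
  cat(sprintf("  transcripts          : %d\n", x$n_transcripts))
  cat(sprintf("  seed                 : %d\n", x$seed))
  invisible(x)
}
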