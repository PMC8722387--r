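# Synthetic data generator: selfing F2 segregation, pooling by phenotype,
# and allele-count sequencing of the pools.

SENSE_CODONS <- local({
  all64 <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
})
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulate clean-ORF transcript models
#'
#' Generates random transcript cDNAs: a 5' UTR, an open reading frame (ATG,
#' sense codons, one stop), and a 3' UTR. Consumes the R random stream.
#'
#' @param n_transcripts Number of transcripts.
#' @param cds_codon_range Integer range of codon counts (incl. start/stop).
#' @param utr_lengths 5' and 3' UTR lengths (nt).
#' @return A transcript model data frame with columns `transcript_id`,
#'   `cdna`, `cds_start`, `cds_end` (1-based inclusive CDS bounds).
#' @examples
#' set.seed(1)
#' tx <- simulate_transcripts(3, c(10, 20), c(6, 8))
#' tx$cds_start
#' @export
simulate_transcripts <- function(n_transcripts,
                                 cds_codon_range = c(150L, 450L),
                                 utr_lengths = c(60L, 100L)) {
  cds_codon_range <- as.integer(cds_codon_range)
  n_codons <- sample(seq(cds_codon_range[1], cds_codon_range[2]),
                     n_transcripts, replace = TRUE)
  utr5 <- as.integer(utr_lengths[1])
  utr3 <- as.integer(utr_lengths[2])
  cdna <- vapply(n_codons, function(k) {
    body <- sample(SENSE_CODONS, k - 2L, replace = TRUE)
    paste0(paste(sample(BASES, utr5, replace = TRUE), collapse = ""),
           "ATG", paste(body, collapse = ""),
           sample(STOP_CODONS, 1L),
           paste(sample(BASES, utr3, replace = TRUE), collapse = ""))
  }, character(1))
  data.frame(transcript_id = sprintf("tx%04d", seq_len(n_transcripts)),
             cdna = cdna,
             cds_start = utr5 + 1L,
             cds_end = utr5 + 3L * n_codons,
             stringsAsFactors = FALSE)
}

#' Selfing segregation of a heterozygous founder
#'
#' Draws offspring genotypes at one locus from a self-fertilizing
#' heterozygous parent: each offspring receives two independent gametes, so
#' genotypes segregate 1:2:1 (hom_ref : het : hom_alt). Consumes the R
#' random stream; seed with [set.seed()] for reproducibility.
#'
#' @param founder_genotype Genotype class of the founder at the locus; must
#'   be `"het"` (a homozygous founder does not segregate and is rejected).
#' @param n_offspring Number of offspring to draw.
#' @return Character vector of genotype classes
#'   (`"hom_ref"`, `"het"`, `"hom_alt"`), length `n_offspring`.
#' @examples
#' set.seed(1)
#' table(segregate_selfing("het", 1000))
#' @export
segregate_selfing <- function(founder_genotype, n_offspring) {
  if (length(founder_genotype) != 1L ||
      !founder_genotype %in% GENOTYPE_CLASSES) {
    ps_stop("poolscreen_config_error",
            "founder_genotype must be one of %s",
            paste(GENOTYPE_CLASSES, collapse = ", "))
  }
  if (founder_genotype != "het") {
    ps_stop("poolscreen_config_error",
            "selfing segregation requires a heterozygous founder; got '%s'",
            founder_genotype)
  }
  if (!is_count(n_offspring)) {
    ps_stop("poolscreen_config_error",
            "'n_offspring' must be a non-negative integer")
  }
  if (n_offspring == 0L) return(character(0))
  dosage_to_genotype(rbinom(n_offspring, 2L, 0.5))
}

# Draw founder genotypes (alt dosage 0/1/2) and residual-polymorphism flags
# for the background sites. Residual sites are strain polymorphisms shared
# with the wild-type strain; induced het sites and fixed differences are not.
draw_founder_background <- function(model) {
  s <- model$n_background_variants
  p_het <- model$residual_het_rate + model$enu_het_rate
  u <- stats::runif(s)
  het <- u < p_het
  residual <- het & (u < model$residual_het_rate)
  dosage <- integer(s)
  dosage[het] <- 1L
  hom <- which(!het)
  dosage[hom] <- 2L * rbinom(length(hom), 1L, 0.5)
  list(dosage = dosage, residual = residual)
}

# Genotype matrix (sites x embryos, alt dosage 0/1/2) for selfed offspring of
# a founder with the given per-site dosages. Het sites segregate Binom(2, .5)
# per embryo; hom sites are fixed.
selfed_genotypes <- function(founder_dosage, n_embryos) {
  s <- length(founder_dosage)
  g <- matrix(rep(founder_dosage, n_embryos), nrow = s)
  het <- which(founder_dosage == 1L)
  if (length(het)) {
    g[het, ] <- matrix(rbinom(length(het) * n_embryos, 2L, 0.5),
                       nrow = length(het))
  }
  g
}

#' Build phenotype-sorted embryo pools for a selfing cross
#'
#' Simulates the F2 brood of a single selfing founder heterozygous for one
#' recessive causal allele, sorts embryos by phenotype and pools them:
#' the mutant pool holds `n_embryos_per_pool` embryos homozygous for the
#' causal allele; the sibling pool holds phenotypically normal embryos
#' (homozygous-reference : heterozygous in expected ratio 1:2); the wild-type
#' pool holds embryos of the unmutagenized strain, homozygous reference
#' everywhere except residual strain polymorphisms. Background variants
#' segregate independently of phenotype. Consumes the R random stream.
#'
#' @param model A [cross_model()].
#' @return An object of class `pool_set`: a list with genotype matrices
#'   `mut`, `sib`, `wt` (sites x embryos, alt-allele dosage 0/1/2), the
#'   index `causal_index` of the causal site, per-site founder information,
#'   and a `truth` data frame (founder genotype class, residual flag, causal
#'   flag, expected per-pool alt-allele fractions).
#' @examples
#' m <- cross_model(seed = 1, n_background_variants = 10, n_transcripts = 5)
#' set.seed(m$seed)
#' pools <- build_pools(m)
#' pools$truth[pools$causal_index, ]
#' @export
build_pools <- function(model) {
  if (!inherits(model, "cross_model")) {
    ps_stop("poolscreen_config_error", "'model' must be a cross_model object")
  }
  n <- model$n_embryos_per_pool
  bg <- draw_founder_background(model)
  s_total <- model$n_background_variants + 1L
  causal_index <- sample.int(s_total, 1L)

  founder_dosage <- append(bg$dosage, 1L, after = causal_index - 1L)
  residual <- append(bg$residual, FALSE, after = causal_index - 1L)

  mut <- selfed_genotypes(founder_dosage, n)
  sib <- selfed_genotypes(founder_dosage, n)
  # Phenotype selection acts only at the causal site.
  mut[causal_index, ] <- 2L
  sib[causal_index, ] <- sample(c(0L, 1L), n, replace = TRUE,
                                prob = c(1, 2) / 3)

  wt_dosage <- ifelse(residual, 1L, 0L)
  wt <- selfed_genotypes(wt_dosage, n)

  causal <- seq_len(s_total) == causal_index
  exp_mut <- founder_dosage / 2
  exp_sib <- founder_dosage / 2
  exp_mut[causal] <- 1
  exp_sib[causal] <- 1 / 3
  exp_wt <- ifelse(residual, 0.5, 0)

  truth <- data.frame(
    site = seq_len(s_total),
    causal = causal,
    founder_genotype = dosage_to_genotype(founder_dosage),
    wt_strain_genotype = dosage_to_genotype(ifelse(residual, 1L, 0L)),
    expected_wt_alt_fraction = exp_wt,
    expected_mut_alt_fraction = exp_mut,
    expected_sib_alt_fraction = exp_sib,
    stringsAsFactors = FALSE)

  structure(list(model = model, causal_index = causal_index,
                 founder_dosage = founder_dosage, residual = residual,
                 mut = mut, sib = sib, wt = wt, truth = truth,
                 sites = NULL),
            class = "pool_set")
}

# Expression-weighted pool alt-allele dosage in [0, 1] for one pool.
pool_dosage <- function(g, weight_dispersion) {
  n <- ncol(g)
  if (weight_dispersion > 0) {
    shape <- 1 / weight_dispersion
    w <- rgamma(n, shape = shape, rate = shape)
    as.vector(g %*% w) / (2 * sum(w))
  } else {
    rowMeans(g) / 2
  }
}

#' Sequence embryo pools into a per-pool allele count table
#'
#' Draws per-site read depth for each pool from a negative binomial
#' (`depth_mean`, `depth_dispersion`) and alternate-read counts from a
#' binomial whose success probability is the pool's (expression-weighted)
#' alt-allele dosage adjusted for symmetric sequencing error:
#' `p = d (1 - e) + (1 - d) e`. Consumes the R random stream.
#'
#' @param pools A `pool_set` from [build_pools()], with site annotations
#'   attached by [simulate_cross()] (or a `sites` data frame supplied here).
#' @param model The [cross_model()] used to build the pools.
#' @param sites Optional data frame with columns `variant_id`,
#'   `transcript_id`, `position`, `ref`, `alt` (one row per site, in site
#'   order); defaults to `pools$sites`.
#' @return A variant count table (see [read_variant_table()] for the
#'   column contract).
#' @export
sequence_pools <- function(pools, model, sites = NULL) {
  if (!inherits(pools, "pool_set")) {
    ps_stop("poolscreen_config_error", "'pools' must be a pool_set object")
  }
  sites <- sites %||% pools$sites
  s <- nrow(pools$mut)
  if (is.null(sites)) {
    # Placeholder site annotations for pool-level experiments that never
    # touch transcripts.
    sites <- data.frame(variant_id = sprintf("v%05d", seq_len(s)),
                        transcript_id = "unplaced",
                        position = seq_len(s),
                        ref = "A", alt = "C",
                        stringsAsFactors = FALSE)
  }
  if (nrow(sites) != s) {
    ps_stop("poolscreen_config_error",
            "'sites' has %d rows but pools carry %d sites", nrow(sites), s)
  }
  e <- model$seq_error_rate
  one_pool <- function(g) {
    d <- pool_dosage(g, model$expression_weight_dispersion)
    depth <- rnbinom(s, size = model$depth_dispersion, mu = model$depth_mean)
    alt <- rbinom(s, depth, d * (1 - e) + (1 - d) * e)
    cbind(ref = depth - alt, alt = alt)
  }
  wt <- one_pool(pools$wt)
  mut <- one_pool(pools$mut)
  sib <- one_pool(pools$sib)
  tab <- data.frame(variant_id = sites$variant_id,
                    transcript_id = sites$transcript_id,
                    position = as.integer(sites$position),
                    ref = sites$ref, alt = sites$alt,
                    wt_ref = wt[, "ref"], wt_alt = wt[, "alt"],
                    mut_ref = mut[, "ref"], mut_alt = mut[, "alt"],
                    sib_ref = sib[, "ref"], sib_alt = sib[, "alt"],
                    stringsAsFactors = FALSE)
  validate_variant_table(tab)
}

# Assign each site a (transcript, position) and ref/alt alleles; plant the
# causal missense allele, overwriting the host codon with an arginine codon
# so the planted change is the classic C>T, Arg->Cys transition.
assign_sites <- function(model, transcripts, causal_index) {
  s_total <- model$n_background_variants + 1L
  lens <- nchar(transcripts$cdna)
  offsets <- cumsum(c(0L, lens[-length(lens)]))
  total <- sum(lens)
  if (total < s_total) {
    ps_stop("poolscreen_config_error",
            "transcript set too small: %d nt for %d variant sites",
            total, s_total)
  }

  if (is.null(model$causal_allele)) {
    ctx <- sample.int(nrow(transcripts), 1L)
    n_codons <- (transcripts$cds_end[ctx] - transcripts$cds_start[ctx] + 1L) %/% 3L
    codon_i <- sample(2:(n_codons - 1L), 1L)
    cpos <- transcripts$cds_start[ctx] + 3L * (codon_i - 1L)
    substr(transcripts$cdna[ctx], cpos, cpos + 2L) <- "CGC"
    causal <- list(transcript_idx = ctx, position = cpos,
                   ref = "C", alt = "T")
  } else {
    ca <- model$causal_allele
    ctx <- match(ca$transcript_id, transcripts$transcript_id)
    if (is.na(ctx)) {
      ps_stop("poolscreen_config_error",
              "causal_allele transcript '%s' not in transcript set",
              ca$transcript_id)
    }
    base <- substr(transcripts$cdna[ctx], ca$position, ca$position)
    if (base != ca$ref) {
      ps_stop("poolscreen_data_error",
              "causal_allele ref '%s' does not match cDNA base '%s' at %s:%d",
              ca$ref, base, ca$transcript_id, ca$position)
    }
    causal <- list(transcript_idx = ctx, position = as.integer(ca$position),
                   ref = ca$ref, alt = ca$alt)
  }
  causal_global <- offsets[causal$transcript_idx] + causal$position

  pool_global <- setdiff(sample.int(total, min(total, s_total + 1L)),
                         causal_global)[seq_len(s_total - 1L)]
  global <- integer(s_total)
  global[causal_index] <- causal_global
  global[-causal_index] <- pool_global

  tx_idx <- findInterval(global - 1L, cumsum(lens), left.open = FALSE) + 1L
  pos <- global - offsets[tx_idx]
  ref <- substring(transcripts$cdna[tx_idx], pos, pos)
  alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), character(1),
                USE.NAMES = FALSE)
  alt[causal_index] <- causal$alt
  ref[causal_index] <- causal$ref

  list(transcripts = transcripts,
       sites = data.frame(variant_id = sprintf("v%05d", seq_len(s_total)),
                          transcript_id = transcripts$transcript_id[tx_idx],
                          position = pos,
                          ref = ref, alt = alt,
                          stringsAsFactors = FALSE))
}

# Per-transcript coverage comparison table with a planted downregulated set.
simulate_coverage <- function(model, transcripts) {
  n <- nrow(transcripts)
  base_mu <- rlnorm(n, meanlog = log(model$depth_mean), sdlog = 1)
  n_down <- min(model$n_downregulated, n)
  down <- sort(sample.int(n, n_down))
  lfc <- rep(0, n)
  lfc[down] <- model$downregulation_lfc
  sib <- rnbinom(n, size = model$depth_dispersion, mu = base_mu)
  mut <- rnbinom(n, size = model$depth_dispersion, mu = base_mu * 2^lfc)
  list(coverage = data.frame(gene_id = transcripts$transcript_id,
                             mut_depth = mut, sib_depth = sib,
                             stringsAsFactors = FALSE),
       downregulated = transcripts$transcript_id[down])
}

#' Simulate a full pooled RNA-seq screening data set
#'
#' End-to-end generator: seeds the random stream from the model, simulates
#' transcripts (unless supplied), plants the causal missense allele, builds
#' phenotype pools, sequences them into a per-pool allele count table, and
#' simulates a per-gene coverage comparison with a planted downregulated
#' gene set. Identical `(model, seed)` pairs yield byte-identical outputs.
#'
#' @param model A [cross_model()].
#' @param transcripts Optional transcript model data frame (see
#'   [read_transcripts()]); when supplied, `model$causal_allele` must name
#'   the planted mutation.
#' @return An object of class `cross_sim`: list with elements `variants`
#'   (count table), `transcripts`, `truth` (per-variant ground truth incl.
#'   `variant_id` and expected alt fractions), `coverage`, `downregulated`,
#'   `pools` (the `pool_set`), and `model`.
#' @examples
#' sim <- simulate_cross(cross_model(seed = 7, n_background_variants = 50,
#'                                   n_transcripts = 10))
#' sim$truth[sim$truth$causal, c("variant_id", "expected_sib_alt_fraction")]
#' @export
simulate_cross <- function(model, transcripts = NULL) {
  if (!inherits(model, "cross_model")) {
    ps_stop("poolscreen_config_error", "'model' must be a cross_model object")
  }
  set.seed(model$seed)
  if (is.null(transcripts)) {
    transcripts <- simulate_transcripts(model$n_transcripts,
                                        model$cds_codon_range,
                                        model$utr_lengths)
  } else {
    transcripts <- validate_transcripts(transcripts)
    if (is.null(model$causal_allele)) {
      ps_stop("poolscreen_config_error",
              "supply model$causal_allele when simulating on given transcripts")
    }
  }
  pools <- build_pools(model)
  placed <- assign_sites(model, transcripts, pools$causal_index)
  pools$sites <- placed$sites
  variants <- sequence_pools(pools, model)
  expr <- simulate_coverage(model, placed$transcripts)
  truth <- cbind(placed$sites, pools$truth[, -1L, drop = FALSE])
  structure(list(variants = variants,
                 transcripts = placed$transcripts,
                 truth = truth,
                 coverage = expr$coverage,
                 downregulated = expr$downregulated,
                 pools = pools,
                 model = model),
            class = "cross_sim")
}

#' Write a simulated data set to a directory
#'
#' Writes `variants.tsv` (count-table dialect), `transcripts.fa` plus
#' `transcripts_cds.tsv`, `truth.tsv`, `gene_coverage.tsv` and
#' `downregulated_genes.txt`.
#'
#' @param sim A `cross_sim` from [simulate_cross()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cross_sim <- function(sim, dir) {
  if (!inherits(sim, "cross_sim")) {
    ps_stop("poolscreen_config_error", "'sim' must be a cross_sim object")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(variants = file.path(dir, "variants.tsv"),
             fasta = file.path(dir, "transcripts.fa"),
             cds = file.path(dir, "transcripts_cds.tsv"),
             truth = file.path(dir, "truth.tsv"),
             coverage = file.path(dir, "gene_coverage.tsv"),
             downregulated = file.path(dir, "downregulated_genes.txt"))
  write_variant_table(sim$variants, paths["variants"])
  write_transcripts(sim$transcripts, paths["fasta"], paths["cds"])
  write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$coverage, paths["coverage"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(sim$downregulated, paths["downregulated"])
  invisible(paths)
}
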