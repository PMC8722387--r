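# Internal helpers shared across modules.

# Classed errors so callers (and tests) can distinguish configuration,
# parsing, validation, data-integrity and range failures.
ps_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "poolscreen_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Genotype classes of a diploid selfing line, as alt-allele dosage 0/1/2.
GENOTYPE_CLASSES <- c("hom_ref", "het", "hom_alt")

genotype_to_dosage <- function(genotype) {
  idx <- match(genotype, GENOTYPE_CLASSES)
  if (anyNA(idx)) {
    ps_stop("poolscreen_config_error",
            "unknown genotype class: %s",
            paste(unique(genotype[is.na(idx)]), collapse = ", "))
  }
  idx - 1L
}

dosage_to_genotype <- function(dosage) GENOTYPE_CLASSES[dosage + 1L]

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == trunc(x)
}

is_rate <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x <= 1
}

BASES <- c("A", "C", "G", "T")
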