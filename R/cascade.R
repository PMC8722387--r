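# The six-screen filtering cascade over per-pool allele counts, plus the
# non-synonymous condition. Each screen is a pure per-row predicate; the
# cascade is their ordered conjunction, so the final candidate set does not
# depend on screen order (only the per-screen survivor counts do).

#' Alternate-allele read fraction
#'
#' `alt / (ref + alt)`, vectorized. Zero total depth has no defined
#' fraction and returns `NA` (never 0), so downstream screens can treat
#' "no reads" conservatively.
#'
#' @param ref,alt Non-negative read counts (recycled to common length).
#' @return Numeric vector of fractions in `[0, 1]`, `NA` at zero depth.
#' @examples
#' alt_fraction(c(30, 0, 0), c(0, 30, 0))
#' @export
alt_fraction <- function(ref, alt) {
  if (any(ref < 0, na.rm = TRUE) || any(alt < 0, na.rm = TRUE)) {
    ps_stop("poolscreen_validation_error", "read counts must be non-negative")
  }
  total <- ref + alt
  ifelse(total > 0, alt / total, NA_real_)
}

# A screen referencing an undefined (zero-depth) fraction fails.
defined_and <- function(x) !is.na(x) & x

#' Screen 1: homozygous difference between wild-type and mutant pools
#'
#' Passes when both the WT and mutant pools have defined alt fractions, each
#' pool is homozygous (alt fraction at least `screen1_hom_fraction`, or at
#' most one minus it), and the two pools are fixed for *different* alleles.
#'
#' @param variants Variant count table (one or more rows).
#' @param thresholds A [screen_thresholds()].
#' @return Logical vector, one element per row.
#' @export
screen1_hom_difference <- function(variants, thresholds = screen_thresholds()) {
  h <- thresholds$screen1_hom_fraction
  fwt <- alt_fraction(variants$wt_ref, variants$wt_alt)
  fmut <- alt_fraction(variants$mut_ref, variants$mut_alt)
  defined_and((fwt >= h & fmut <= 1 - h) | (fwt <= 1 - h & fmut >= h))
}

#' Screen 2: full enrichment (100% mutant, 0% wild type)
#'
#' Passes when the mutant pool alt fraction equals
#' `mut_alt_fraction_required` (default exactly 1: no mutant-pool reference
#' reads) and the WT pool alt fraction equals `wt_alt_fraction_max`
#' (default exactly 0: no WT alternate reads), both fractions defined.
#'
#' @inheritParams screen1_hom_difference
#' @return Logical vector.
#' @export
screen2_full_enrichment <- function(variants, thresholds = screen_thresholds()) {
  fwt <- alt_fraction(variants$wt_ref, variants$wt_alt)
  fmut <- alt_fraction(variants$mut_ref, variants$mut_alt)
  defined_and(fmut == thresholds$mut_alt_fraction_required &
                fwt == thresholds$wt_alt_fraction_max)
}

#' Screen 3: wild-type pool depth ("WT read is more than ten")
#' @inheritParams screen1_hom_difference
#' @return Logical vector.
#' @export
screen3_wt_depth <- function(variants, thresholds = screen_thresholds()) {
  variants$wt_ref + variants$wt_alt > thresholds$wt_min_total
}

#' Screen 4: mutant pool depth ("mutant read is more than five")
#' @inheritParams screen1_hom_difference
#' @return Logical vector.
#' @export
screen4_mut_depth <- function(variants, thresholds = screen_thresholds()) {
  variants$mut_ref + variants$mut_alt > thresholds$mut_min_total
}

#' Screen 5: sibling pool heterozygous, both alleles well covered
#'
#' Passes when the sibling pool shows strictly more than
#' `sib_min_each_allele` reads of the reference allele *and* of the
#' alternate allele ("heterozygous and more than four from each variant").
#'
#' @inheritParams screen1_hom_difference
#' @return Logical vector.
#' @export
screen5_sib_het <- function(variants, thresholds = screen_thresholds()) {
  variants$sib_ref > thresholds$sib_min_each_allele &
    variants$sib_alt > thresholds$sib_min_each_allele
}

#' Screen 6: sibling allele ratio (reference reads exceed alternate reads)
#'
#' Passes when sibling reference reads strictly exceed sibling alternate
#' reads — the Mendelian expectation for a recessive allele, whose carriers
#' contribute at most half alternate reads. Ties fail.
#'
#' @inheritParams screen1_hom_difference
#' @return Logical vector.
#' @export
screen6_sib_ratio <- function(variants, thresholds = screen_thresholds()) {
  variants$sib_ref > variants$sib_alt
}

NONSYNONYMOUS_CLASSES <- c("missense", "nonsense", "stop_loss")

# Normalize the consequence argument to a named class vector.
consequence_lookup <- function(consequences) {
  if (is.null(consequences)) return(NULL)
  if (is.data.frame(consequences)) {
    if (!all(c("variant_id", "consequence_class") %in% names(consequences))) {
      ps_stop("poolscreen_config_error",
              "'consequences' must have columns variant_id, consequence_class")
    }
    return(setNames(consequences$consequence_class, consequences$variant_id))
  }
  if (is.character(consequences) && !is.null(names(consequences))) {
    return(consequences)
  }
  ps_stop("poolscreen_config_error",
          "'consequences' must be a consequence table or named class vector")
}

screen_nonsynonymous <- function(variants, classes) {
  cls <- classes[variants$variant_id]
  missing <- variants$variant_id[is.na(cls)]
  if (length(missing)) {
    ps_stop("poolscreen_config_error",
            "non-synonymous screen requested but no consequence call for: %s",
            paste(head(missing, 5L), collapse = ", "))
  }
  unname(cls %in% NONSYNONYMOUS_CLASSES)
}

#' Run the variant screening cascade
#'
#' Applies Screens 1-6 in order, then (by default) the non-synonymous
#' protein-consequence condition, to a per-pool variant count table, and
#' reports per-screen survivor counts together with the final candidate
#' list — the table-of-screens view of a pooled bulk-segregant mutation
#' screen. All screens are conjunctive per-row predicates, so the final set
#' is order-invariant; the survivor counts mirror the order used.
#'
#' @param variants Variant count table (see [read_variant_table()]).
#' @param thresholds A [screen_thresholds()].
#' @param consequences Consequence calls for the variants: the data frame
#'   from [call_consequences()] or a named `consequence_class` vector.
#'   Required when the non-synonymous condition is active; calls are only
#'   needed for variants that reach that condition.
#' @param nonsyn_mode Placement of the non-synonymous condition: `"final"`
#'   (the default when `thresholds$require_nonsynonymous` is `TRUE`) applies
#'   it after Screen 6; `"prefilter"` applies it before Screen 1; `"off"`
#'   disables it. Final candidates are identical for `"final"` and
#'   `"prefilter"`; only per-screen counts differ.
#' @return An object of class `cascade_report`: list with `screens` (data
#'   frame of screen label and survivor count), `survivor_ids` (list of id
#'   vectors per screen), `candidates` (surviving rows with per-pool alt
#'   fractions, sorted by transcript and position), `n_input`,
#'   `thresholds` and `nonsyn_mode`.
#' @examples
#' tab <- data.frame(variant_id = "v1", transcript_id = "tx1",
#'                   position = 5L, ref = "C", alt = "T",
#'                   wt_ref = 20L, wt_alt = 0L, mut_ref = 0L, mut_alt = 25L,
#'                   sib_ref = 12L, sib_alt = 7L)
#' run_cascade(tab, consequences = c(v1 = "missense"))
#' @export
run_cascade <- function(variants, thresholds = screen_thresholds(),
                        consequences = NULL, nonsyn_mode = NULL) {
  variants <- validate_variant_table(variants)
  if (!inherits(thresholds, "screen_thresholds")) {
    ps_stop("poolscreen_config_error",
            "'thresholds' must be a screen_thresholds object")
  }
  nonsyn_mode <- nonsyn_mode %||%
    (if (thresholds$require_nonsynonymous) "final" else "off")
  nonsyn_mode <- match.arg(nonsyn_mode, c("final", "prefilter", "off"))
  classes <- consequence_lookup(consequences)
  if (nonsyn_mode != "off" && is.null(classes)) {
    ps_stop("poolscreen_config_error",
            "nonsyn_mode '%s' requires consequence calls", nonsyn_mode)
  }

  steps <- list(
    hom_difference = screen1_hom_difference,
    full_enrichment = screen2_full_enrichment,
    wt_depth = screen3_wt_depth,
    mut_depth = screen4_mut_depth,
    sib_het = screen5_sib_het,
    sib_ratio = screen6_sib_ratio)
  nonsyn_step <- function(v, t) screen_nonsynonymous(v, classes)
  if (nonsyn_mode == "final") {
    steps <- c(steps, list(nonsynonymous = nonsyn_step))
  } else if (nonsyn_mode == "prefilter") {
    steps <- c(list(nonsynonymous = nonsyn_step), steps)
  }

  surviving <- variants
  labels <- names(steps)
  counts <- integer(length(steps))
  survivor_ids <- vector("list", length(steps))
  names(survivor_ids) <- labels
  for (i in seq_along(steps)) {
    if (nrow(surviving)) {
      keep <- steps[[i]](surviving, thresholds)
      surviving <- surviving[keep, , drop = FALSE]
    }
    counts[i] <- nrow(surviving)
    survivor_ids[[i]] <- surviving$variant_id
  }

  candidates <- surviving[order(surviving$transcript_id,
                                surviving$position), , drop = FALSE]
  rownames(candidates) <- NULL
  candidates$wt_alt_fraction <-
    alt_fraction(candidates$wt_ref, candidates$wt_alt)
  candidates$mut_alt_fraction <-
    alt_fraction(candidates$mut_ref, candidates$mut_alt)
  candidates$sib_alt_fraction <-
    alt_fraction(candidates$sib_ref, candidates$sib_alt)
  if (!is.null(classes)) {
    candidates$consequence_class <- unname(classes[candidates$variant_id])
  }

  structure(list(screens = data.frame(screen = seq_along(steps),
                                      label = labels,
                                      n_survivors = counts,
                                      stringsAsFactors = FALSE),
                 survivor_ids = survivor_ids,
                 candidates = candidates,
                 n_input = nrow(variants),
                 thresholds = thresholds,
                 nonsyn_mode = nonsyn_mode),
            class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat(sprintf("Variant screening cascade: %d input variants\n", x$n_input))
  for (i in seq_len(nrow(x$screens))) {
    cat(sprintf("  %-16s %6d survivors\n",
                x$screens$label[i], x$screens$n_survivors[i]))
  }
  n <- nrow(x$candidates)
  cat(sprintf("Final candidates: %d\n", n))
  if (n > 0 && n <= 10) {
    cols <- intersect(c("variant_id", "transcript_id", "position", "ref",
                        "alt", "mut_alt_fraction", "sib_alt_fraction",
                        "wt_alt_fraction", "consequence_class"),
                      names(x$candidates))
    print(x$candidates[, cols], row.names = FALSE)
  }
  invisible(x)
}

#' Write a cascade report to TSV files
#'
#' `report_path` receives the per-screen survivor counts (the shape of a
#' screening summary table); `candidates_path` the final candidate rows with
#' per-pool counts and alt fractions.
#'
#' @param report A `cascade_report` from [run_cascade()].
#' @param report_path,candidates_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_cascade_report <- function(report, report_path, candidates_path) {
  if (!inherits(report, "cascade_report")) {
    ps_stop("poolscreen_config_error", "'report' must be a cascade_report")
  }
  write.table(report$screens, report_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(report$candidates, candidates_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(report_path, candidates_path))
}
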