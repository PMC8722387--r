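#' Numeric criteria of the variant screening cascade
#'
#' Thresholds for the six read-count screens plus the non-synonymous
#' condition. All "more than" comparisons are strict (`>`); ties fail.
#'
#' @param wt_min_total Screen 3: total wild-type pool reads must be strictly
#'   greater than this. Default 10 ("more than ten").
#' @param mut_min_total Screen 4: total mutant pool reads must be strictly
#'   greater than this. Default 5 ("more than five").
#' @param sib_min_each_allele Screen 5: sibling pool must show strictly more
#'   than this many reads of *each* allele. Default 4 ("more than four from
#'   each variant").
#' @param mut_alt_fraction_required Screen 2: required mutant-pool alternate
#'   allele fraction. Default 1.0 — exact 100% enrichment, i.e. zero mutant
#'   reference reads.
#' @param wt_alt_fraction_max Screen 2: required wild-type pool alternate
#'   allele fraction. Default 0.0 — exactly zero wild-type alternate reads.
#' @param screen1_hom_fraction Screen 1 calls a pool "homozygous" when its
#'   alt fraction is at least this value (or at most one minus it). Must lie
#'   in (0.5, 1]. Default 0.9.
#' @param require_nonsynonymous Apply the non-synonymous protein-consequence
#'   condition as the final screen. Default `TRUE`.
#' @return An object of class `screen_thresholds`.
#' @seealso [run_cascade()]
#' @export
screen_thresholds <- function(wt_min_total = 10L,
                              mut_min_total = 5L,
                              sib_min_each_allele = 4L,
                              mut_alt_fraction_required = 1.0,
                              wt_alt_fraction_max = 0.0,
                              screen1_hom_fraction = 0.9,
                              require_nonsynonymous = TRUE) {
  for (nm in c("wt_min_total", "mut_min_total", "sib_min_each_allele")) {
    if (!is_count(get(nm))) {
      ps_stop("poolscreen_config_error",
              "'%s' must be a non-negative integer", nm)
    }
  }
  if (!is_rate(mut_alt_fraction_required) || !is_rate(wt_alt_fraction_max)) {
    ps_stop("poolscreen_config_error",
            "enrichment fractions must lie in [0, 1]")
  }
  if (wt_alt_fraction_max >= mut_alt_fraction_required) {
    ps_stop("poolscreen_config_error",
            "wt_alt_fraction_max (%.3g) must be < mut_alt_fraction_required (%.3g)",
            wt_alt_fraction_max, mut_alt_fraction_required)
  }
  if (!is.numeric(screen1_hom_fraction) ||
      screen1_hom_fraction <= 0.5 || screen1_hom_fraction > 1) {
    ps_stop("poolscreen_config_error",
            "'screen1_hom_fraction' must lie in (0.5, 1]")
  }
  if (!is.logical(require_nonsynonymous) || is.na(require_nonsynonymous)) {
    ps_stop("poolscreen_config_error",
            "'require_nonsynonymous' must be TRUE or FALSE")
  }
  structure(list(wt_min_total = as.integer(wt_min_total),
                 mut_min_total = as.integer(mut_min_total),
                 sib_min_each_allele = as.integer(sib_min_each_allele),
                 mut_alt_fraction_required = mut_alt_fraction_required,
                 wt_alt_fraction_max = wt_alt_fraction_max,
                 screen1_hom_fraction = screen1_hom_fraction,
                 require_nonsynonymous = require_nonsynonymous),
            class = "screen_thresholds")
}

#' @export
print.screen_thresholds <- function(x, ...) {
  cat("Screening thresholds (strict 'more than' comparisons)\n")
  cat(sprintf("  Screen 1: pools homozygous at alt fraction >= %.2f, opposite alleles\n",
              x$screen1_hom_fraction))
  cat(sprintf("  Screen 2: mutant alt fraction = %.2f, WT alt fraction = %.2f\n",
              x$mut_alt_fraction_required, x$wt_alt_fraction_max))
  cat(sprintf("  Screen 3: WT reads  > %d\n", x$wt_min_total))
  cat(sprintf("  Screen 4: MUT reads > %d\n", x$mut_min_total))
  cat(sprintf("  Screen 5: SIB reads > %d for each allele\n",
              x$sib_min_each_allele))
  cat("  Screen 6: SIB ref reads > SIB alt reads\n")
  cat(sprintf("  Non-synonymous condition: %s\n",
              if (x$require_nonsynonymous) "on" else "off"))
  invisible(x)
}
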