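# Flat per-pool variant count table: the interface between assembly-based
# variant calling (bubble counts collapsed per variant) and the screen math.

VARIANT_TABLE_COLUMNS <- c("variant_id", "transcript_id", "position",
                           "ref", "alt",
                           "wt_ref", "wt_alt", "mut_ref", "mut_alt",
                           "sib_ref", "sib_alt")
COUNT_COLUMNS <- c("wt_ref", "wt_alt", "mut_ref", "mut_alt",
                   "sib_ref", "sib_alt")

#' Validate a per-pool variant count table
#'
#' Checks the column contract of the variant-table dialect: one row per
#' biallelic transcript variant with non-negative ref/alt read counts for the
#' wild-type (`wt`), mutant (`mut`) and sibling (`sib`) pools. Positions are
#' 1-based on the transcript cDNA; alleles are single upper-case bases;
#' `ref != alt`; `variant_id` values are unique.
#'
#' @param x Data frame to validate.
#' @param where Optional file name used in error messages.
#' @return The validated table, with count and position columns as integers,
#'   invisibly usable downstream.
#' @export
validate_variant_table <- function(x, where = NULL) {
  label <- if (is.null(where)) "variant table" else where
  bad_line <- function(i, fmt, ...) {
    # +1 for the header line so messages point at file lines.
    ps_stop("poolscreen_parse_error",
            paste0("%s, line %d: ", fmt), label, i + 1L, ...)
  }
  if (!is.data.frame(x)) {
    ps_stop("poolscreen_parse_error", "%s: not a data frame", label)
  }
  if (!identical(names(x), VARIANT_TABLE_COLUMNS)) {
    ps_stop("poolscreen_parse_error",
            "%s: malformed header; expected columns '%s', got '%s'",
            label,
            paste(VARIANT_TABLE_COLUMNS, collapse = " "),
            paste(names(x), collapse = " "))
  }
  for (col in c("position", COUNT_COLUMNS)) {
    v <- x[[col]]
    if (is.character(v)) {
      ok <- grepl("^[0-9]+$", v)
      if (any(!ok)) {
        bad_line(which(!ok)[1], "non-integer value '%s' in column '%s'",
                 v[which(!ok)[1]], col)
      }
      v <- as.integer(v)
    }
    if (!is.numeric(v) || anyNA(v) || any(v != trunc(v))) {
      bad_line(which(is.na(v) | v != trunc(v))[1],
               "non-integer value in column '%s'", col)
    }
    if (any(v < 0)) {
      bad_line(which(v < 0)[1], "negative value in column '%s'", col)
    }
    x[[col]] <- as.integer(v)
  }
  if (any(x$position < 1L)) {
    bad_line(which(x$position < 1L)[1], "position must be >= 1")
  }
  for (col in c("ref", "alt")) {
    ok <- x[[col]] %in% BASES
    if (any(!ok)) {
      bad_line(which(!ok)[1], "allele '%s' in column '%s' is not one of %s",
               x[[col]][which(!ok)[1]], col, paste(BASES, collapse = "/"))
    }
  }
  same <- x$ref == x$alt
  if (any(same)) {
    bad_line(which(same)[1], "ref and alt alleles are identical")
  }
  dup <- duplicated(x$variant_id)
  if (any(dup)) {
    bad_line(which(dup)[1], "duplicate variant_id '%s'",
             x$variant_id[which(dup)[1]])
  }
  rownames(x) <- NULL
  x
}

#' Read a per-pool variant count table
#'
#' Reads the tab-separated variant-table dialect: UTF-8 TSV with header
#' `variant_id transcript_id position ref alt wt_ref wt_alt mut_ref mut_alt
#' sib_ref sib_alt`, no quoting, explicit zero counts (never `.`). Row order
#' is preserved; every row is validated (see [validate_variant_table()]) and
#' malformed input fails with the offending line number.
#'
#' @param path Path to the TSV file.
#' @return A validated variant count table (data frame).
#' @seealso [write_variant_table()]
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) {
    ps_stop("poolscreen_parse_error", "no such file: %s", path)
  }
  x <- read.delim(path, colClasses = "character", check.names = FALSE,
                  quote = "", comment.char = "")
  validate_variant_table(x, where = path)
}

#' Write a per-pool variant count table
#'
#' @param x Variant count table (validated before writing).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_variant_table <- function(x, path) {
  x <- validate_variant_table(x)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
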