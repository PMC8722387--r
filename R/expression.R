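# Coverage-based expression comparison between mutant and sibling pools:
# per-million normalization, pseudo-counted log2 ratio, ranking of
# downregulated genes. Ranking only - no dispersion model, no p-values.

#' Read a per-gene depth table
#'
#' Tab-separated with header `gene_id mut_depth sib_depth`; depths are mean
#' per-base read coverage over each gene's transcript, per pool.
#'
#' @param path Input TSV path.
#' @return Data frame with the three columns, depths numeric.
#' @export
read_gene_depths <- function(path) {
  x <- read.delim(path, check.names = FALSE)
  needed <- c("gene_id", "mut_depth", "sib_depth")
  if (!all(needed %in% names(x))) {
    ps_stop("poolscreen_parse_error",
            "%s: malformed header; expected columns %s", path,
            paste(needed, collapse = " "))
  }
  x <- x[, needed]
  for (col in c("mut_depth", "sib_depth")) {
    x[[col]] <- as.numeric(x[[col]])
    if (anyNA(x[[col]]) || any(x[[col]] < 0)) {
      ps_stop("poolscreen_parse_error",
              "%s: column '%s' must be non-negative numeric", path, col)
    }
  }
  x
}

#' Normalized coverage comparison between mutant and sibling pools
#'
#' Scales each pool's depths to a common total (`scale`, counts-per-million
#' by default) and computes the pseudo-counted log2 ratio
#' `log2((mut + pc) / (sib + pc))` on the normalized values. Deterministic;
#' invariant under rescaling either pool's depths.
#'
#' @param depths Data frame `gene_id`, `mut_depth`, `sib_depth` (depths
#'   >= 0), e.g. from [read_gene_depths()].
#' @param pseudo_count Added to both normalized coverages before the ratio;
#'   must be > 0 so the log ratio is always finite. Default 1.
#' @param scale Per-pool normalization target. Default `1e6`.
#' @return Data frame `gene_id`, `mut_depth`, `sib_depth`, `mut_norm`,
#'   `sib_norm`, `log2_ratio`.
#' @examples
#' d <- data.frame(gene_id = c("a", "b"), mut_depth = c(10, 0),
#'                 sib_depth = c(10, 40))
#' coverage_table(d)$log2_ratio
#' @export
coverage_table <- function(depths, pseudo_count = 1, scale = 1e6) {
  needed <- c("gene_id", "mut_depth", "sib_depth")
  if (!is.data.frame(depths) || !all(needed %in% names(depths))) {
    ps_stop("poolscreen_config_error",
            "'depths' must have columns %s", paste(needed, collapse = ", "))
  }
  if (!is.numeric(pseudo_count) || pseudo_count <= 0) {
    ps_stop("poolscreen_config_error", "'pseudo_count' must be > 0")
  }
  if (any(depths$mut_depth < 0) || any(depths$sib_depth < 0)) {
    ps_stop("poolscreen_validation_error", "depths must be non-negative")
  }
  mut_total <- sum(depths$mut_depth)
  sib_total <- sum(depths$sib_depth)
  if (mut_total == 0 || sib_total == 0) {
    ps_stop("poolscreen_validation_error",
            "cannot normalize: a pool has zero total depth")
  }
  mut_norm <- depths$mut_depth / mut_total * scale
  sib_norm <- depths$sib_depth / sib_total * scale
  data.frame(gene_id = depths$gene_id,
             mut_depth = depths$mut_depth,
             sib_depth = depths$sib_depth,
             mut_norm = mut_norm,
             sib_norm = sib_norm,
             log2_ratio = log2((mut_norm + pseudo_count) /
                                 (sib_norm + pseudo_count)),
             stringsAsFactors = FALSE)
}

#' Top downregulated genes
#'
#' The `n` records with the most negative log2 mutant/sibling ratio, ranked
#' from most downregulated; ties are broken by `gene_id` lexicographic
#' order so the ranking is deterministic under permutation of the input.
#'
#' @param records Output of [coverage_table()].
#' @param n Number of genes to return (clamped to the table size).
#' @return The ranked sublist with a `rank` column (1 = most downregulated).
#' @export
top_downregulated <- function(records, n = 30L) {
  if (!is.data.frame(records) ||
      !all(c("gene_id", "log2_ratio") %in% names(records))) {
    ps_stop("poolscreen_config_error",
            "'records' must be a coverage table with gene_id and log2_ratio")
  }
  if (!is_count(n)) {
    ps_stop("poolscreen_config_error", "'n' must be a non-negative integer")
  }
  ord <- order(records$log2_ratio, records$gene_id)
  k <- min(n, nrow(records))
  out <- records[ord[seq_len(k)], , drop = FALSE]
  out$rank <- seq_len(k)
  rownames(out) <- NULL
  out
}

#' Write an expression ranking to TSV
#' @param records Data frame (ranked or full coverage table).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_expression_table <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
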