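# Expression-profiling arithmetic: differential-expression filtering at a
# linear fold-change threshold and a p cutoff, and overlap of two gene
# sets with a percentage and an optional hypergeometric enrichment p.

#' Filter differentially expressed genes
#'
#' Up-regulated: `fold_change >= fc_threshold` and `p < p_threshold`.
#' Down-regulated: `fold_change <= 1/fc_threshold` and `p < p_threshold`.
#' Fold changes are linear-scale treated/control ratios, so the fold
#' boundary is inclusive on both sides.  When the table has no `p_value`
#' column, per-gene p values are computed from replicate columns by a
#' two-sided Welch (unequal-variance) t test.
#'
#' @param expr Data.frame with a `gene` column plus either
#'   `fold_change` and `p_value` columns, or `fold_change` and replicate
#'   expression columns named in `group1` / `group2`.
#' @param fc_threshold Linear fold-change threshold (default 1.5).
#' @param p_threshold p-value cutoff (default 0.01).
#' @param group1,group2 Column names of the two replicate groups (each
#'   length >= 2) used to compute p when `p_value` is absent.
#' @return List of class `deg_result`: `up_genes`, `down_genes`,
#'   `n_total_regulated`, and the thresholds used.
#' @export
filter_deg <- function(expr, fc_threshold = 1.5, p_threshold = 0.01,
                       group1 = NULL, group2 = NULL) {
  if (!"gene" %in% names(expr) || !"fold_change" %in% names(expr))
    sf_stop("expression table needs 'gene' and 'fold_change' columns",
            class = "screenforge_format_error")
  if (any(expr$fold_change <= 0)) sf_stop("fold_change must be positive")
  if (fc_threshold < 1) sf_stop("fc_threshold must be >= 1")

  if ("p_value" %in% names(expr)) {
    p <- expr$p_value
    if (any(p < 0 | p > 1, na.rm = TRUE)) sf_stop("p_value must lie in [0, 1]")
  } else {
    if (is.null(group1) || is.null(group2))
      sf_stop("either a p_value column or both replicate groups are required")
    if (length(group1) < 2 || length(group2) < 2)
      sf_stop("each replicate group needs at least 2 columns")
    g1 <- as.matrix(expr[, group1, drop = FALSE])
    g2 <- as.matrix(expr[, group2, drop = FALSE])
    p <- vapply(seq_len(nrow(expr)), function(i)
      stats::t.test(g1[i, ], g2[i, ], var.equal = FALSE)$p.value, numeric(1))
  }

  up <- expr$gene[expr$fold_change >= fc_threshold & p < p_threshold]
  down <- expr$gene[expr$fold_change <= 1 / fc_threshold & p < p_threshold]
  structure(list(up_genes = up, down_genes = down,
                 n_total_regulated = length(up) + length(down),
                 fc_threshold = fc_threshold, p_threshold = p_threshold),
            class = "deg_result")
}

#' @export
print.deg_result <- function(x, ...) {
  cat(sprintf("DEG filter (FC >= %.3g, p < %.3g): %d up, %d down, %d total\n",
              x$fc_threshold, x$p_threshold,
              length(x$up_genes), length(x$down_genes), x$n_total_regulated))
  invisible(x)
}

#' Overlap of two gene sets
#'
#' Reports the overlap count, the percentage of set `a` overlapping `b`,
#' and the upper-tail hypergeometric probability of seeing an overlap at
#' least this large when `|b|` genes are drawn from a universe of
#' `universe_size` containing `|a|` marked genes.  The hypergeometric p is
#' an optional enrichment annotation, not a calling criterion.
#'
#' @param a,b Character vectors of gene symbols (duplicates dropped).
#' @param universe_size Size of the gene universe; must be at least
#'   `|a U b|`.
#' @return List of class `overlap_result`: `n_a`, `n_b`, `n_overlap`,
#'   `percent_of_a`, `hypergeometric_p`.
#' @export
#' @examples
#' overlap_sets(paste0("g", 1:473), paste0("g", 1:125), 20000)$percent_of_a
overlap_sets <- function(a, b, universe_size) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  n_union <- length(union(a, b))
  if (universe_size < n_union)
    sf_stop(sprintf("universe_size %d smaller than |a U b| = %d",
                    universe_size, n_union))
  n_overlap <- length(intersect(a, b))
  percent <- if (length(a) > 0) 100 * n_overlap / length(a) else NA_real_
  p <- stats::phyper(n_overlap - 1, length(a), universe_size - length(a),
                     length(b), lower.tail = FALSE)
  structure(list(n_a = length(a), n_b = length(b), n_overlap = n_overlap,
                 percent_of_a = percent, hypergeometric_p = p),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Overlap: %d of %d (%.0f%% of A), |B| = %d, hypergeometric p = %.3g\n",
              x$n_overlap, x$n_a, x$percent_of_a, x$n_b, x$hypergeometric_p))
  invisible(x)
}

#' Read an expression table from CSV
#' @param path CSV with header `gene,fold_change[,p_value,...]`.
#' @return data.frame.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) sf_stop(sprintf("file not found: %s", path))
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a gene-set file (one symbol per line)
#' @param path Text file, one gene symbol per line.
#' @return Character vector.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) sf_stop(sprintf("file not found: %s", path))
  x <- trimws(readLines(path))
  x[nzchar(x)]
}
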