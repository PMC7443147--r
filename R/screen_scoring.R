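# Guide and gene scoring: the guide score is the median-corrected log2
# fold change of a guide's normalized abundance between the treated
# (marker-sorted) and control arms; the gene score is the mean of its
# guides' corrected scores; a gene is called a hit when at least
# `min_concordant` of its guides shift in the same direction past tau.
#
# tau defaults to 0.5 log2 units (~1.4-fold): at tau = 0 the sign of a
# null guide's corrected LFC is a fair coin and >= 3-of-4 concordance
# would be called on 10/16 of untouched genes at any sequencing depth,
# so a sign-only rule cannot separate hits from sampling noise.

#' Per-guide log fold changes with median correction
#'
#' For each guide, `lfc_raw` is the mean of its log2-normalized values
#' over the treated columns minus the mean over the control columns.
#' `lfc_corrected` subtracts the median of all guides' `lfc_raw` (global
#' centering), so the bulk of guides — which do nothing — sit at zero.
#'
#' @param log_matrix A `normalized_matrix` on the log2 scale.
#' @param treated_samples,control_samples Disjoint non-empty character
#'   vectors of column names.
#' @param lib Optional `guide_library` supplying the gene column.
#' @param median_correct Apply median centering (default TRUE).
#' @return data.frame `guide_id, gene, lfc_raw, lfc_corrected`.
#' @export
guide_scores <- function(log_matrix, treated_samples, control_samples,
                         lib = NULL, median_correct = TRUE) {
  sc <- attr(log_matrix, "scale")
  if (is.null(sc) || sc != "log2")
    sf_stop("guide_scores expects a log2-scale matrix")
  if (length(treated_samples) == 0 || length(control_samples) == 0)
    sf_stop("treated and control sample lists must be non-empty")
  if (length(intersect(treated_samples, control_samples)) > 0)
    sf_stop("treated and control sample lists overlap")
  unknown <- setdiff(c(treated_samples, control_samples), colnames(log_matrix))
  if (length(unknown) > 0)
    sf_stop(sprintf("unknown sample id(s): %s", paste(unknown, collapse = ", ")))

  m <- unclass(log_matrix)
  lfc_raw <- rowMeans(m[, treated_samples, drop = FALSE]) -
    rowMeans(m[, control_samples, drop = FALSE])
  lfc_corrected <- if (median_correct) lfc_raw - stats::median(lfc_raw) else lfc_raw

  gene <- NA_character_
  if (!is.null(lib)) {
    lib <- validate_library(lib)
    gene <- lib$gene[match(rownames(m), lib$guide_id)]
  }
  data.frame(guide_id = rownames(m), gene = gene,
             lfc_raw = unname(lfc_raw), lfc_corrected = unname(lfc_corrected),
             stringsAsFactors = FALSE)
}

#' Gene-level scores and concordance hit calls
#'
#' The gene score is the mean of the gene's guides' corrected log fold
#' changes.  A guide counts toward `n_up` when `lfc_corrected > tau` and
#' toward `n_down` when `lfc_corrected < -tau` (strict inequalities, so a
#' guide scoring exactly at the threshold is neutral).  A gene is a hit
#' when one side reaches `min_concordant` guides; with the 4-guide design
#' and the default `min_concordant = 3` the two sides cannot both qualify.
#' Genes with fewer than `min_concordant` guides are flagged not-callable
#' with a warning.
#'
#' @param gscores Guide-score table from [guide_scores()].
#' @param lib A `guide_library` mapping guides to genes.
#' @param tau Concordance threshold on `lfc_corrected`, in log2 units
#'   (default 0.5, about a 1.4-fold shift; 0 degenerates to a sign test
#'   that calls most null genes by chance).
#' @param min_concordant Guides required on one side (default 3).
#' @return data.frame `gene, score, n_guides, n_up, n_down, hit, direction`.
#' @export
gene_scores <- function(gscores, lib, tau = 0.5, min_concordant = 3L) {
  lib <- validate_library(lib)
  if (tau < 0) sf_stop("tau must be nonnegative")
  if (min_concordant < 1) sf_stop("min_concordant must be positive")
  idx <- match(gscores$guide_id, lib$guide_id)
  if (any(is.na(idx)))
    sf_stop(sprintf("guide(s) absent from library: %s",
                    paste(utils::head(gscores$guide_id[is.na(idx)], 5),
                          collapse = ", ")))
  gene <- factor(lib$gene[idx], levels = unique(lib$gene[idx]))
  x <- gscores$lfc_corrected

  score <- tapply(x, gene, mean)
  n_guides <- tapply(x, gene, length)
  n_up <- tapply(x, gene, function(v) sum(v > tau))
  n_down <- tapply(x, gene, function(v) sum(v < -tau))

  res <- data.frame(gene = names(score),
                    score = unname(score),
                    n_guides = as.integer(n_guides),
                    n_up = as.integer(n_up),
                    n_down = as.integer(n_down),
                    stringsAsFactors = FALSE)
  callable <- res$n_guides >= min_concordant
  if (any(!callable))
    warning(sprintf("%d gene(s) have fewer than %d guides and are not callable",
                    sum(!callable), min_concordant))
  up_hit <- callable & res$n_up >= min_concordant
  down_hit <- callable & res$n_down >= min_concordant
  both <- up_hit & down_hit
  if (any(both)) {
    # only reachable when min_concordant <= n_guides/2; prefer the side
    # with more concordant guides, neither on an exact tie
    keep_up <- res$n_up[both] > res$n_down[both]
    keep_down <- res$n_down[both] > res$n_up[both]
    up_hit[both] <- keep_up
    down_hit[both] <- keep_down
  }
  res$hit <- up_hit | down_hit
  res$direction <- ifelse(up_hit, "up", ifelse(down_hit, "down", "none"))
  res
}

#' Rank genes by hit status and absolute score
#'
#' Hits of the requested direction come first, ordered by `|score|`
#' descending; remaining genes follow in the same order.  Ties break
#' lexicographically by gene symbol so the ranking is deterministic.
#'
#' @param genes Gene-score table from [gene_scores()].
#' @param direction `"up"` or `"down"`.
#' @return The reordered gene-score table with a `rank` column.
#' @export
rank_genes <- function(genes, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (nrow(genes) == 0) sf_stop("empty gene table")
  is_hit <- genes$hit & genes$direction == direction
  ord <- order(!is_hit, -abs(genes$score), genes$gene)
  out <- genes[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write guide or gene score tables as TSV
#' @param scores A data.frame of scores.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
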