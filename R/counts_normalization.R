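# Normalization as used for pooled-screen count matrices: reads per
# million within each sequenced sample, then log2 after adding a
# pseudocount of 1 so guides with zero reads stay finite.

#' Reads-per-million normalization
#'
#' `value[g, s] = counts[g, s] / column_total(s) * 1e6`.  Each sequenced
#' sample (one barcoded condition) is normalized by its own total of
#' mapped reads.  Columns with zero total are an error unless
#' `allow_empty = TRUE`, in which case they are set to all zeros with a
#' warning.
#'
#' @param counts Nonnegative guide x sample matrix (integer counts).
#' @param allow_empty Tolerate all-zero columns (default FALSE).
#' @return Numeric matrix with the same dimnames, `scale` attribute
#'   `"rpm"`, class `normalized_matrix`.
#' @export
rpm_normalize <- function(counts, allow_empty = FALSE) {
  if (!is.matrix(counts)) sf_stop("counts must be a matrix")
  if (any(counts < 0)) sf_stop("counts must be nonnegative")
  totals <- colSums(counts)
  empty <- totals == 0
  if (any(empty) && !allow_empty)
    sf_stop(sprintf("sample(s) with zero total reads: %s",
                    paste(colnames(counts)[empty], collapse = ", ")))
  if (any(empty))
    warning(sprintf("empty sample(s) set to all-zero RPM: %s",
                    paste(colnames(counts)[empty], collapse = ", ")))
  denom <- ifelse(empty, 1, totals)
  rpm <- sweep(counts, 2, denom, "/") * 1e6
  rpm[, empty] <- 0
  structure(rpm, scale = "rpm", class = c("normalized_matrix", "matrix"))
}

#' log2(x + 1) transform of an RPM matrix
#'
#' The pseudocount of 1 keeps guides with zero reads finite (log2(1) = 0).
#' Refuses input that is already on the log2 scale.
#'
#' @param rpm A `normalized_matrix` on the rpm scale.
#' @return The matrix of `log2(rpm + 1)`, `scale` attribute `"log2"`.
#' @export
log2_transform <- function(rpm) {
  sc <- attr(rpm, "scale")
  if (is.null(sc) || sc != "rpm")
    sf_stop(sprintf("log2_transform expects an rpm-scale matrix (got scale '%s')",
                    if (is.null(sc)) "none" else sc))
  out <- log2(unclass(rpm) + 1)
  structure(out, scale = "log2", class = c("normalized_matrix", "matrix"))
}

#' Write a normalized matrix as TSV
#'
#' The scale is recorded in a `# scale: rpm|log2` comment line before the
#' header.  Values are rounded to 4 decimals on disk; in-memory values
#' keep full precision.
#'
#' @param mat A `normalized_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_normalized <- function(mat, path) {
  sc <- attr(mat, "scale")
  if (is.null(sc)) sf_stop("matrix has no scale attribute")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scale: %s", sc), con)
  df <- data.frame(guide_id = rownames(mat), round(unclass(mat), 4),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a normalized matrix from TSV
#' @param path TSV as written by [write_normalized()].
#' @return A `normalized_matrix` with its recorded scale.
#' @export
read_normalized <- function(path) {
  if (!file.exists(path)) sf_stop(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1)
  m <- regmatches(first, regexec("^# scale: (rpm|log2)$", first))[[1]]
  if (length(m) != 2)
    sf_stop("missing '# scale:' header line", class = "screenforge_format_error")
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$guide_id
  structure(mat, scale = m[2], class = c("normalized_matrix", "matrix"))
}
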