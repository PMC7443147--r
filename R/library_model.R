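# sgRNA library reference and sample sheet: the tables every other stage
# consumes.  A guide library is a plain data.frame with class
# "guide_library" and columns guide_id, gene, spacer (20-mer over ACGT).

#' Validate a guide library table
#'
#' Checks the structural invariants of an sgRNA library: required columns,
#' unique `guide_id` and `spacer`, and 20-nt A/C/G/T spacers.  Spacers are
#' uppercased before validation, so lowercase input is accepted.
#'
#' @param lib A data.frame with columns `guide_id`, `gene`, `spacer`.
#' @param spacer_length Required spacer length (default 20).
#' @return The validated library, invisibly classed as `guide_library`.
#' @export
validate_library <- function(lib, spacer_length = 20L) {
  required <- c("guide_id", "gene", "spacer")
  missing <- setdiff(required, names(lib))
  if (length(missing) > 0)
    sf_stop(sprintf("library is missing required column(s): %s",
                    paste(missing, collapse = ", ")),
            class = "screenforge_format_error")
  lib$guide_id <- as.character(lib$guide_id)
  lib$gene <- as.character(lib$gene)
  lib$spacer <- toupper(as.character(lib$spacer))
  if (nrow(lib) == 0)
    sf_stop("library contains no guides")

  bad_len <- which(nchar(lib$spacer) != spacer_length)
  if (length(bad_len) > 0)
    sf_stop(sprintf("spacer length %d != %d at row %d (guide_id '%s')",
                    nchar(lib$spacer[bad_len[1]]), spacer_length,
                    bad_len[1], lib$guide_id[bad_len[1]]))
  bad_alpha <- which(!is_acgt(lib$spacer))
  if (length(bad_alpha) > 0)
    sf_stop(sprintf("spacer contains non-ACGT characters at row %d (guide_id '%s')",
                    bad_alpha[1], lib$guide_id[bad_alpha[1]]))

  dup_id <- lib$guide_id[duplicated(lib$guide_id)]
  if (length(dup_id) > 0)
    sf_stop(sprintf("duplicate guide_id: %s",
                    paste(unique(dup_id), collapse = ", ")))
  if (anyDuplicated(lib$spacer)) {
    d <- lib$spacer[duplicated(lib$spacer)][1]
    ids <- lib$guide_id[lib$spacer == d]
    sf_stop(sprintf("duplicate spacer %s shared by guides: %s",
                    d, paste(ids, collapse = ", ")))
  }
  class(lib) <- unique(c("guide_library", class(lib)))
  invisible(lib)
}

#' Load an sgRNA library reference from CSV
#'
#' The library file is a 3-column CSV with header `guide_id,gene,spacer`.
#' Row order is preserved; spacers are uppercased on load.  (Public library
#' distributions such as Brunello ship in other layouts; convert by
#' selecting and renaming the guide identifier, gene symbol, and 20-nt
#' spacer columns into this header.)
#'
#' @param path Path to the CSV file.
#' @param spacer_length Required spacer length (default 20).
#' @return A `guide_library` data.frame.
#' @export
#' @examples
#' p <- tempfile(fileext = ".csv")
#' write_library(generate_library(3, 4, seed = 1), p)
#' lib <- load_library(p)
#' nrow(lib)  # 12
load_library <- function(path, spacer_length = 20L) {
  if (!file.exists(path)) sf_stop(sprintf("library file not found: %s", path))
  lib <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  validate_library(lib, spacer_length = spacer_length)
}

#' Write an sgRNA library to CSV
#'
#' @param lib A `guide_library` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path) {
  lib <- validate_library(lib)
  utils::write.csv(lib[, c("guide_id", "gene", "spacer")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Map each gene to its guide ids
#'
#' @param lib A validated `guide_library`.
#' @return Named list: gene -> character vector of guide_ids.
#' @export
library_genes <- function(lib) {
  split(lib$guide_id, factor(lib$gene, levels = unique(lib$gene)))
}

#' Check the library design against an expected guides-per-gene count
#'
#' Reports, per gene, the observed guide count and whether it matches the
#' expected design (4 guides per gene for Brunello-like genome-wide
#' knockout libraries).
#'
#' @param lib A `guide_library`.
#' @param expected_guides_per_gene Expected count (default 4).
#' @return A list of class `design_report` with elements `per_gene`
#'   (data.frame: gene, n_guides, pass), `expected`, and `pass` (overall).
#' @export
validate_design <- function(lib, expected_guides_per_gene = 4L) {
  lib <- validate_library(lib)
  stopifnot(expected_guides_per_gene >= 1)
  tab <- table(factor(lib$gene, levels = unique(lib$gene)))
  per_gene <- data.frame(gene = names(tab),
                         n_guides = as.integer(tab),
                         pass = as.integer(tab) == expected_guides_per_gene,
                         stringsAsFactors = FALSE)
  structure(list(per_gene = per_gene,
                 expected = as.integer(expected_guides_per_gene),
                 pass = all(per_gene$pass)),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("Design report: %d genes, expected %d guides/gene, %s\n",
              nrow(x$per_gene), x$expected,
              if (x$pass) "PASS" else "FAIL"))
  off <- x$per_gene[!x$per_gene$pass, , drop = FALSE]
  if (nrow(off) > 0) {
    cat("Deviating genes:\n")
    print(utils::head(off, 20), row.names = FALSE)
  }
  invisible(x)
}

#' Cells-per-guide coverage for a screen
#'
#' Infection coverage is the number of transduced cells divided by the
#' number of guides in the library; genome-wide screens typically aim for
#' a floor of several hundred cells per guide.
#'
#' @param n_cells Number of cells infected (positive).
#' @param lib A `guide_library`, or a positive integer number of guides.
#' @param floor Minimum acceptable cells/guide (default 300).
#' @return List with `cells_per_guide`, `n_guides`, `floor`, `meets_floor`.
#' @export
#' @examples
#' coverage_report(2.5e7, 76441)$cells_per_guide  # ~327
coverage_report <- function(n_cells, lib, floor = 300) {
  if (!is.numeric(n_cells) || length(n_cells) != 1 || n_cells <= 0)
    sf_stop("n_cells must be a single positive number")
  n_guides <- if (is.data.frame(lib)) nrow(lib) else as.numeric(lib)
  if (is.na(n_guides) || n_guides < 1)
    sf_stop("library is empty")
  cpg <- n_cells / n_guides
  list(cells_per_guide = cpg, n_guides = n_guides,
       floor = floor, meets_floor = cpg >= floor)
}

#' Validate a sample sheet table
#'
#' @param sheet Data.frame with columns `sample_id`, `barcode`,
#'   `condition`, `replicate` and optionally `fastq_path`.
#' @param for_scoring If TRUE, additionally require at least one control
#'   and one treated sample.
#' @return Validated sheet, invisibly classed as `sample_sheet`.
#' @export
validate_sample_sheet <- function(sheet, for_scoring = FALSE) {
  required <- c("sample_id", "barcode", "condition", "replicate")
  missing <- setdiff(required, names(sheet))
  if (length(missing) > 0)
    sf_stop(sprintf("sample sheet is missing column(s): %s",
                    paste(missing, collapse = ", ")),
            class = "screenforge_format_error")
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$barcode <- toupper(as.character(sheet$barcode))
  sheet$condition <- as.character(sheet$condition)
  sheet$replicate <- as.integer(sheet$replicate)
  if (nrow(sheet) == 0) sf_stop("sample sheet has no rows")
  if (anyDuplicated(sheet$sample_id))
    sf_stop("duplicate sample_id in sample sheet")
  if (anyDuplicated(sheet$barcode))
    sf_stop("duplicate barcode in sample sheet")
  bad <- which(nchar(sheet$barcode) != 8 | !is_acgt(sheet$barcode))
  if (length(bad) > 0)
    sf_stop(sprintf("barcode must be an 8-nt ACGT string (row %d: '%s')",
                    bad[1], sheet$barcode[bad[1]]))
  if (!all(sheet$condition %in% c("control", "treated")))
    sf_stop("condition must be 'control' or 'treated'")
  if (any(is.na(sheet$replicate)) || any(sheet$replicate < 1))
    sf_stop("replicate must be a positive integer")
  if (for_scoring &&
      (!any(sheet$condition == "control") || !any(sheet$condition == "treated")))
    sf_stop("scoring requires at least one control and one treated sample")
  class(sheet) <- unique(c("sample_sheet", class(sheet)))
  invisible(sheet)
}

#' Load a sample sheet from CSV
#'
#' Header: `sample_id,barcode,condition,replicate,fastq_path` (the last
#' column optional; used in per-file demultiplexing mode).
#'
#' @inheritParams validate_sample_sheet
#' @param path Path to the CSV file.
#' @return A `sample_sheet` data.frame.
#' @export
load_sample_sheet <- function(path, for_scoring = FALSE) {
  if (!file.exists(path)) sf_stop(sprintf("sample sheet not found: %s", path))
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(sheet, for_scoring = for_scoring)
}

#' Write a sample sheet to CSV
#' @param sheet A `sample_sheet`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  sheet <- validate_sample_sheet(sheet)
  cols <- intersect(c("sample_id", "barcode", "condition", "replicate",
                      "fastq_path"), names(sheet))
  utils::write.csv(as.data.frame(sheet)[, cols], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
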