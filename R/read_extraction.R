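# Read-level sgRNA extraction: find the vector anchor (CACCG by default)
# in each read, take the following 20 nt as the spacer, map it to the
# library, and demultiplex by the 8-nt sample barcode.
#
# Every read gets exactly one status, assigned in fixed precedence order:
#   unknown_barcode -> no_anchor -> insufficient_length -> unmapped_spacer -> ok

READ_STATUSES <- c("ok", "no_anchor", "insufficient_length",
                   "unmapped_spacer", "unknown_barcode")

#' Extract the sgRNA spacer following the vector anchor
#'
#' Searches each read for the leftmost exact occurrence of `anchor` and
#' returns the `spacer_length` characters immediately following it.  The
#' vector places the anchor 5' of every sgRNA insert, so the first hit is
#' the vector copy even if the anchor recurs downstream by chance.
#'
#' @param read_sequence Character vector of read sequences (IUPAC DNA;
#'   `N` allowed).
#' @param anchor Anchor sequence to search for (default `"CACCG"`).
#' @param spacer_length Number of characters to take after the anchor.
#' @return A data.frame with columns `spacer` (NA on failure) and
#'   `status` (`ok`, `no_anchor`, or `insufficient_length`).
#' @export
#' @examples
#' extract_spacer("TTACACCGACGTACGTACGTACGTACGTTTTT")
extract_spacer <- function(read_sequence, anchor = "CACCG",
                           spacer_length = 20L) {
  if (length(read_sequence) == 0)
    return(data.frame(spacer = character(0), status = character(0)))
  if (any(is.na(read_sequence)) || any(!nzchar(read_sequence)))
    sf_stop("empty read sequence")
  read_sequence <- toupper(read_sequence)
  pos <- regexpr(anchor, read_sequence, fixed = TRUE)
  start <- as.integer(pos) + nchar(anchor)
  end <- start + spacer_length - 1L
  status <- rep("ok", length(read_sequence))
  status[pos < 0] <- "no_anchor"
  status[pos > 0 & end > nchar(read_sequence)] <- "insufficient_length"
  spacer <- rep(NA_character_, length(read_sequence))
  okv <- status == "ok"
  spacer[okv] <- substr(read_sequence[okv], start[okv], end[okv])
  data.frame(spacer = spacer, status = status, stringsAsFactors = FALSE)
}

#' Map spacers to library guides
#'
#' With `max_mismatch = 0` the lookup is exact.  With `max_mismatch = 1`
#' an unmatched spacer is assigned to the unique library spacer at Hamming
#' distance 1; if two or more library spacers tie at the minimum distance
#' the read is left unmapped (ambiguity rule).
#'
#' @param spacer Character vector of candidate spacers (NA passes through
#'   as unmapped).
#' @param lib A `guide_library`.
#' @param max_mismatch 0 (exact, default) or 1.
#' @return Character vector of guide_ids, NA where unmapped.
#' @export
map_spacer <- function(spacer, lib, max_mismatch = 0L) {
  lib <- validate_library(lib)
  if (!max_mismatch %in% c(0L, 1L))
    sf_stop("max_mismatch must be 0 or 1")
  idx <- match(spacer, lib$spacer)
  guide <- lib$guide_id[idx]
  if (max_mismatch == 1L) {
    todo <- which(is.na(guide) & !is.na(spacer))
    if (length(todo) > 0) {
      k <- unique(nchar(lib$spacer))[1]
      # enumerate all 3k single-substitution neighbours of each unmatched
      # spacer and look each up exactly; cheaper than a pairwise scan
      for (i in todo) {
        s <- spacer[i]
        if (nchar(s) != k) next
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        hits <- character(0)
        for (p in seq_len(k)) {
          for (b in setdiff(DNA_ALPHABET, ch[p])) {
            v <- ch; v[p] <- b
            j <- match(paste0(v, collapse = ""), lib$spacer)
            if (!is.na(j)) hits <- c(hits, lib$guide_id[j])
          }
        }
        hits <- unique(hits)
        if (length(hits) == 1) guide[i] <- hits
      }
    }
  }
  guide
}

#' Demultiplex reads to samples
#'
#' In `per_file` mode every read of a FASTQ file belongs to the sample the
#' file is registered to in the sample sheet.  In `inline_prefix` mode the
#' first 8 characters of each read are the sample barcode and the spacer
#' is extracted from the remainder.  Barcode matching is exact.
#'
#' @param read_sequence Character vector of read sequences.
#' @param sheet A `sample_sheet`.
#' @param mode `"per_file"` or `"inline_prefix"`.
#' @param file_sample For `per_file` mode, the sample_id the file is
#'   registered to.
#' @return List with `sample_id` (NA = unknown barcode) and `rest` (the
#'   sequence available for spacer extraction).
#' @export
demultiplex <- function(read_sequence, sheet,
                        mode = c("per_file", "inline_prefix"),
                        file_sample = NULL) {
  mode <- match.arg(mode)
  sheet <- validate_sample_sheet(sheet)
  if (mode == "per_file") {
    if (is.null(file_sample) || !file_sample %in% sheet$sample_id)
      sf_stop("per_file mode requires a registered file_sample")
    return(list(sample_id = rep(file_sample, length(read_sequence)),
                rest = read_sequence))
  }
  bc <- substr(read_sequence, 1L, 8L)
  short <- nchar(read_sequence) < 8L
  sample_id <- sheet$sample_id[match(bc, sheet$barcode)]
  sample_id[short] <- NA_character_
  list(sample_id = sample_id, rest = substr(read_sequence, 9L, 1e6L))
}

#' Structural check of a 4-line FASTQ file
#'
#' Biostrings tolerates truncated trailing records, so record structure
#' (header '@', separator '+', 4-line multiples) is verified in a chunked
#' line scan that reports the offending record index.
#' @noRd
validate_fastq_structure <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  offset <- 0L
  repeat {
    chunk <- readLines(con, n = 400000L)
    if (length(chunk) == 0) break
    idx <- seq_along(chunk) + offset
    bad <- which((idx %% 4L == 1L & !startsWith(chunk, "@")) |
                 (idx %% 4L == 3L & !startsWith(chunk, "+")))
    if (length(bad) > 0)
      sf_stop(sprintf("malformed FASTQ in '%s': record %d (line %d)",
                      path, (idx[bad[1]] - 1L) %/% 4L + 1L, idx[bad[1]]),
              class = "screenforge_format_error")
    offset <- offset + length(chunk)
  }
  if (offset %% 4L != 0L)
    sf_stop(sprintf("malformed FASTQ in '%s': truncated record %d",
                    path, offset %/% 4L + 1L),
            class = "screenforge_format_error")
  offset %/% 4L
}

#' Read a FASTQ file into a character vector of sequences
#'
#' Plain or gzipped 4-line FASTQ.  Quality scores are ignored throughout
#' (the extraction applies no quality filter).
#' @noRd
read_fastq_sequences <- function(path) {
  if (!file.exists(path)) sf_stop(sprintf("FASTQ file not found: %s", path))
  n_records <- validate_fastq_structure(path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e)
      sf_stop(sprintf("malformed FASTQ in '%s': %s", path, conditionMessage(e)),
              class = "screenforge_format_error"))
  if (length(seqs) != n_records)
    sf_stop(sprintf("malformed FASTQ in '%s': parsed %d of %d records",
                    path, length(seqs), n_records),
            class = "screenforge_format_error")
  as.character(seqs, use.names = FALSE)
}

#' Count guide-level reads from FASTQ input
#'
#' Runs demultiplexing, anchor search, spacer extraction, and library
#' mapping over one or more FASTQ files and tallies reads with status
#' `ok` into a guide x sample count matrix.  Reads failing any step are
#' counted under their failure status, never silently dropped.
#'
#' @param fastq_inputs In `per_file` mode, a named character vector
#'   `sample_id -> fastq path` (or NULL to use the sheet's `fastq_path`
#'   column); in `inline_prefix` mode, a character vector of FASTQ paths
#'   whose reads carry the barcode as their first 8 nt.
#' @param lib A `guide_library`.
#' @param sheet A `sample_sheet`.
#' @param mode `"per_file"` (default) or `"inline_prefix"`.
#' @param anchor Vector anchor preceding the spacer (default `"CACCG"`).
#' @param spacer_length Spacer length (default 20).
#' @param max_mismatch Spacer mismatch tolerance, 0 or 1 (default 0).
#' @return List of class `screen_counts`: `counts` (integer matrix, rows =
#'   all library guides zero-filled, columns = sheet samples) and `stats`
#'   (an `extraction_stats` list: per-sample and total status tallies and
#'   `fraction_ok`).
#' @export
process_fastq <- function(fastq_inputs = NULL, lib, sheet,
                          mode = c("per_file", "inline_prefix"),
                          anchor = "CACCG", spacer_length = 20L,
                          max_mismatch = 0L) {
  mode <- match.arg(mode)
  lib <- validate_library(lib, spacer_length = spacer_length)
  sheet <- validate_sample_sheet(sheet)

  if (mode == "per_file") {
    if (is.null(fastq_inputs)) {
      if (!"fastq_path" %in% names(sheet) || any(!nzchar(sheet$fastq_path)))
        sf_stop("per_file mode needs fastq_inputs or a fastq_path column")
      fastq_inputs <- stats::setNames(sheet$fastq_path, sheet$sample_id)
    }
    if (is.null(names(fastq_inputs)) ||
        !all(names(fastq_inputs) %in% sheet$sample_id))
      sf_stop("per_file fastq_inputs must be named by registered sample_id")
  }

  samples <- sheet$sample_id
  counts <- matrix(0L, nrow = nrow(lib), ncol = length(samples),
                   dimnames = list(lib$guide_id, samples))
  tally_names <- c(READ_STATUSES)
  per_sample <- matrix(0L, nrow = length(samples), ncol = length(tally_names),
                       dimnames = list(samples, tally_names))
  unassigned <- stats::setNames(rep(0L, length(tally_names)), tally_names)

  process_one <- function(seqs, sample_ids) {
    status <- rep(NA_character_, length(seqs))
    unknown <- is.na(sample_ids)
    status[unknown] <- "unknown_barcode"
    ext <- extract_spacer_safe(seqs, unknown, anchor, spacer_length)
    status[!unknown] <- ext$status[!unknown]
    guide <- rep(NA_character_, length(seqs))
    okv <- !unknown & status == "ok"
    guide[okv] <- map_spacer(ext$spacer[okv], lib, max_mismatch)
    status[okv & is.na(guide)] <- "unmapped_spacer"
    okv <- status == "ok"
    # tallies
    for (st in tally_names) {
      sel <- status == st
      if (!any(sel)) next
      known <- sel & !is.na(sample_ids)
      if (any(known)) {
        t1 <- table(factor(sample_ids[known], levels = samples))
        per_sample[, st] <<- per_sample[, st] + as.integer(t1)
      }
      unassigned[st] <<- unassigned[st] + sum(sel & is.na(sample_ids))
    }
    if (any(okv)) {
      t2 <- table(factor(guide[okv], levels = lib$guide_id),
                  factor(sample_ids[okv], levels = samples))
      counts <<- counts + matrix(as.integer(t2), nrow = nrow(lib),
                                 dimnames = dimnames(counts))
    }
  }

  if (mode == "per_file") {
    for (s in names(fastq_inputs)) {
      seqs <- read_fastq_sequences(fastq_inputs[[s]])
      process_one(seqs, rep(s, length(seqs)))
    }
  } else {
    for (f in fastq_inputs) {
      seqs <- read_fastq_sequences(f)
      dm <- demultiplex(seqs, sheet, mode = "inline_prefix")
      process_one(dm$rest, dm$sample_id)
    }
  }

  total <- colSums(per_sample) + unassigned
  n_reads <- sum(total)
  stats <- structure(list(
    per_sample = per_sample,
    unassigned = unassigned,
    total = total,
    n_reads = n_reads,
    fraction_ok = if (n_reads > 0) unname(total["ok"]) / n_reads else NA_real_),
    class = "extraction_stats")
  stopifnot(sum(counts) == total[["ok"]])
  structure(list(counts = counts, stats = stats), class = "screen_counts")
}

# extract_spacer but tolerant of rows already failed upstream
#' @noRd
extract_spacer_safe <- function(seqs, skip, anchor, spacer_length) {
  res <- data.frame(spacer = rep(NA_character_, length(seqs)),
                    status = rep(NA_character_, length(seqs)),
                    stringsAsFactors = FALSE)
  todo <- !skip & !is.na(seqs) & nzchar(seqs)
  if (any(todo)) res[todo, ] <- extract_spacer(seqs[todo], anchor, spacer_length)
  res$status[!skip & (is.na(seqs) | !nzchar(seqs))] <- "no_anchor"
  res
}

#' @export
print.extraction_stats <- function(x, ...) {
  cat(sprintf("Extraction: %d reads, %.2f%% ok\n",
              x$n_reads, 100 * x$fraction_ok))
  print(x$total)
  invisible(x)
}

#' Write a guide x sample counts matrix as TSV
#'
#' First column `guide_id`, remaining columns one per sample.
#' @param counts Integer matrix with guide rownames and sample colnames.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(guide_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a guide x sample counts matrix from TSV
#' @param path Counts TSV as written by [write_counts()].
#' @return Integer matrix with guide rownames and sample colnames.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) sf_stop(sprintf("counts file not found: %s", path))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "guide_id")
    sf_stop("counts TSV must have 'guide_id' as its first column",
            class = "screenforge_format_error")
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "integer"
  rownames(m) <- df$guide_id
  m
}
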