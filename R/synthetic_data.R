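# Synthetic inputs with known ground truth: Brunello-like libraries
# (4 guides/gene), screen reads with the vector structure the extractor
# expects, qPCR Ct tables, and first-order decay series.
#
# Read layout (5' -> 3'):
#   [8-nt sample barcode, inline mode only]
#   [random stagger, 0..stagger_max nt]
#   [vector tail ending in the CACCG anchor]
#   [20-nt spacer]
#   [20-nt scaffold prefix]
# The vector tail is the U6 promoter end of lentiCRISPR-style vectors and
# the suffix is the start of the sgRNA scaffold, so synthetic reads carry
# the same anchor context as real ones.

SIM_VECTOR_TAIL <- "TTGTGGAAAGGACGAAACACCG"  # ends in the CACCG anchor
SIM_SCAFFOLD <- "GTTTTAGAGCTAGAAATAGC"       # tracrRNA scaffold start

#' Generate a Brunello-like sgRNA library
#'
#' Genes are named `G0001`, `G0002`, ...; spacers are uniform-random
#' unique 20-mers.  Deterministic for a fixed seed.
#'
#' @param n_genes Number of genes (>= 1).
#' @param guides_per_gene Guides per gene (default 4).
#' @param seed RNG seed.
#' @param spacer_length Spacer length (default 20).
#' @return A `guide_library` data.frame.
#' @export
generate_library <- function(n_genes, guides_per_gene = 4L, seed = NULL,
                             spacer_length = 20L) {
  if (n_genes < 1 || guides_per_gene < 1)
    sf_stop("n_genes and guides_per_gene must be positive")
  n <- n_genes * guides_per_gene
  if (n > 4^spacer_length) sf_stop("more guides requested than distinct spacers")
  spacers <- with_seed(seed, random_kmers(n, spacer_length))
  genes <- rep(sprintf("G%04d", seq_len(n_genes)), each = guides_per_gene)
  lib <- data.frame(
    guide_id = sprintf("%s_g%d", genes, rep(seq_len(guides_per_gene), n_genes)),
    gene = genes, spacer = spacers, stringsAsFactors = FALSE)
  validate_library(lib, spacer_length = spacer_length)
}

#' Generate a two-arm sample sheet
#'
#' @param n_control,n_treated Replicates per arm (default 1 each, the
#'   single NaOH-vs-sorted comparison of a typical screen).
#' @param seed RNG seed for the random unique 8-nt barcodes.
#' @return A `sample_sheet` data.frame.
#' @export
generate_sample_sheet <- function(n_control = 1L, n_treated = 1L, seed = NULL) {
  n <- n_control + n_treated
  bcs <- with_seed(seed, random_kmers(n, 8L))
  sheet <- data.frame(
    sample_id = c(sprintf("control_%d", seq_len(n_control)),
                  sprintf("treated_%d", seq_len(n_treated))),
    barcode = bcs,
    condition = c(rep("control", n_control), rep("treated", n_treated)),
    replicate = c(seq_len(n_control), seq_len(n_treated)),
    stringsAsFactors = FALSE)
  validate_sample_sheet(sheet, for_scoring = TRUE)
}

#' Simulate a pooled knockout screen
#'
#' Baseline guide abundances are log-normal (inequality of coverage, as
#' in real pooled libraries).  In the treated arm every guide of an
#' enriched gene has its weight multiplied by `2^effect_log2`; per-sample
#' counts are multinomial at fixed `depth`.  Reads are emitted with the
#' vector structure described above, optionally with per-base
#' substitution noise.
#'
#' @param lib A `guide_library`.
#' @param sheet A `sample_sheet` (default: one control + one treated).
#' @param enriched_genes Character vector of enriched genes, or a count
#'   (the first k genes).
#' @param effect_log2 log2 enrichment applied to enriched genes' guides
#'   in the treated arm (default 2); scalar or named per gene.
#' @param guide_effects Optional named per-guide log2 effect vector,
#'   overriding `effect_log2` for those guides (e.g. to give only 2 of 4
#'   guides an effect and test partial concordance).
#' @param depth Reads per sample (default 1e6).
#' @param abundance_sigma sdlog of the baseline log-normal (default 1).
#' @param stagger_max Maximum random stagger prefix length (default 7).
#' @param barcode_mode `"per_file"` (one FASTQ per sample) or
#'   `"inline_prefix"` (one mixed FASTQ, barcode as first 8 nt).
#' @param base_error_rate Per-base substitution probability (default 0).
#' @param seed RNG seed (controls everything: abundances, counts, reads).
#' @param out_dir Directory for FASTQ/truth output; NULL (default) skips
#'   file emission unless `emit_fastq = TRUE` requires it.
#' @param emit_fastq Write FASTQ reads (default TRUE when `out_dir`
#'   given).  FALSE gives a fast counts-only simulation.
#' @param gzip Gzip the FASTQ output (default TRUE).
#' @return List of class `screen_truth`: `lib`, `sheet`, `baseline`
#'   (named per-guide weights), `counts` (true guide x sample counts),
#'   `enriched_genes`, `effect_log2` (named per gene), `guide_effects`,
#'   `fastq` (named paths or NULL), `config` echo.
#' @export
simulate_screen <- function(lib, sheet = NULL, enriched_genes = 0,
                            effect_log2 = 2, guide_effects = NULL,
                            depth = 1e6, abundance_sigma = 1,
                            stagger_max = 7L,
                            barcode_mode = c("per_file", "inline_prefix"),
                            base_error_rate = 0, seed = NULL,
                            out_dir = NULL, emit_fastq = !is.null(out_dir),
                            gzip = TRUE) {
  barcode_mode <- match.arg(barcode_mode)
  lib <- validate_library(lib)
  if (depth <= 0) sf_stop("depth must be positive")
  if (base_error_rate < 0 || base_error_rate > 1)
    sf_stop("base_error_rate must lie in [0, 1]")
  if (emit_fastq && is.null(out_dir))
    sf_stop("emit_fastq requires out_dir")

  genes <- unique(lib$gene)
  if (is.numeric(enriched_genes) && length(enriched_genes) == 1)
    enriched_genes <- utils::head(genes, enriched_genes)
  if (!all(enriched_genes %in% genes))
    sf_stop(sprintf("enriched gene(s) not in library: %s",
                    paste(setdiff(enriched_genes, genes), collapse = ", ")))
  eff <- if (!is.null(names(effect_log2))) {
    missing <- setdiff(enriched_genes, names(effect_log2))
    if (length(missing) > 0)
      sf_stop("named effect_log2 must cover all enriched genes")
    effect_log2[enriched_genes]
  } else stats::setNames(rep(effect_log2[1], length(enriched_genes)),
                         enriched_genes)

  with_seed(seed, {
    if (is.null(sheet)) sheet <- generate_sample_sheet()
    sheet <- validate_sample_sheet(sheet, for_scoring = TRUE)

    n_guides <- nrow(lib)
    baseline <- stats::setNames(
      stats::rlnorm(n_guides, meanlog = 0, sdlog = abundance_sigma),
      lib$guide_id)

    per_guide_eff <- stats::setNames(rep(0, n_guides), lib$guide_id)
    enriched_guides <- lib$guide_id[lib$gene %in% enriched_genes]
    per_guide_eff[enriched_guides] <- eff[lib$gene[match(enriched_guides,
                                                         lib$guide_id)]]
    if (!is.null(guide_effects)) {
      unknown <- setdiff(names(guide_effects), lib$guide_id)
      if (length(unknown) > 0)
        sf_stop("guide_effects names absent from library")
      per_guide_eff[names(guide_effects)] <- guide_effects
    }

    counts <- matrix(0L, n_guides, nrow(sheet),
                     dimnames = list(lib$guide_id, sheet$sample_id))
    for (j in seq_len(nrow(sheet))) {
      w <- if (sheet$condition[j] == "treated")
        baseline * 2^per_guide_eff else baseline
      counts[, j] <- as.integer(stats::rmultinom(1, depth, w / sum(w)))
    }

    fastq <- NULL
    if (emit_fastq) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      ext <- if (gzip) ".fastq.gz" else ".fastq"
      if (barcode_mode == "per_file") {
        fastq <- stats::setNames(
          file.path(out_dir, paste0(sheet$sample_id, ext)), sheet$sample_id)
        for (j in seq_len(nrow(sheet)))
          emit_sample_fastq(fastq[[j]], lib$spacer, counts[, j],
                            barcode = NULL, sheet$sample_id[j],
                            stagger_max, base_error_rate, gzip)
        sheet$fastq_path <- unname(fastq)
      } else {
        fastq <- c(reads = file.path(out_dir, paste0("reads", ext)))
        emit_inline_fastq(fastq[["reads"]], lib$spacer, counts, sheet,
                          stagger_max, base_error_rate, gzip)
      }
      write_library(lib, file.path(out_dir, "library.csv"))
      write_sample_sheet(sheet, file.path(out_dir, "samples.csv"))
    }

    truth <- structure(list(
      lib = lib, sheet = sheet, baseline = baseline, counts = counts,
      enriched_genes = as.character(enriched_genes), effect_log2 = eff,
      guide_effects = per_guide_eff[per_guide_eff != 0],
      fastq = fastq,
      config = list(depth = depth, abundance_sigma = abundance_sigma,
                    stagger_max = stagger_max, barcode_mode = barcode_mode,
                    base_error_rate = base_error_rate, seed = seed)),
      class = "screen_truth")
    if (emit_fastq) write_truth_json(truth, file.path(out_dir, "truth.json"))
    truth
  })
}

# build the read sequences for one sample's count vector
#' @noRd
build_reads <- function(spacers, counts, stagger_max, base_error_rate,
                        barcode = NULL) {
  n <- sum(counts)
  seqs <- rep(spacers, counts)
  # random stagger prefix of length 0..stagger_max per read, built
  # column-wise so the whole batch is vectorized; staggers that would
  # create a CACCG occurrence upstream of the vector's own anchor are
  # rejection-sampled away (real stagger primers are fixed sequences
  # chosen not to clash with the anchor)
  lens <- sample.int(stagger_max + 1L, n, replace = TRUE) - 1L
  if (stagger_max > 0) {
    draw <- function(m) {
      cols <- replicate(stagger_max, sample(DNA_ALPHABET, m, replace = TRUE),
                        simplify = FALSE)
      do.call(paste0, cols)
    }
    full <- draw(n)
    stag <- substr(full, 1L, lens)
    anchor_at <- function(s) regexpr("CACCG", paste0(s, SIM_VECTOR_TAIL),
                                     fixed = TRUE)
    true_pos <- nchar(stag) + nchar(SIM_VECTOR_TAIL) - 4L
    bad <- which(as.integer(anchor_at(stag)) != true_pos)
    while (length(bad) > 0) {
      stag[bad] <- substr(draw(length(bad)), 1L, lens[bad])
      true_pos <- nchar(stag) + nchar(SIM_VECTOR_TAIL) - 4L
      bad <- bad[as.integer(anchor_at(stag[bad])) != true_pos[bad]]
    }
  } else stag <- ""
  reads <- paste0(stag, SIM_VECTOR_TAIL, seqs, SIM_SCAFFOLD)
  if (!is.null(barcode)) reads <- paste0(barcode, reads)
  if (base_error_rate > 0) reads <- mutate_reads(reads, base_error_rate)
  reads
}

# independent per-base substitutions at the given rate
#' @noRd
mutate_reads <- function(reads, rate) {
  L <- nchar(reads)
  n_err <- stats::rbinom(length(reads), L, rate)
  for (i in which(n_err > 0)) {
    pos <- sample.int(L[i], n_err[i])
    for (p in pos) {
      old <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(DNA_ALPHABET, old), 1)
    }
  }
  reads
}

#' @noRd
write_fastq <- function(path, reads, id_prefix, gzip) {
  n <- length(reads)
  con <- if (gzip) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  qual <- strrep("I", nchar(reads))
  lines <- as.vector(rbind(sprintf("@%s_%d", id_prefix, seq_len(n)),
                           reads, rep("+", n), qual))
  writeLines(lines, con)
  invisible(path)
}

#' @noRd
emit_sample_fastq <- function(path, spacers, counts, barcode, sample_id,
                              stagger_max, base_error_rate, gzip) {
  reads <- build_reads(spacers, counts, stagger_max, base_error_rate, barcode)
  write_fastq(path, reads, sample_id, gzip)
}

#' @noRd
emit_inline_fastq <- function(path, spacers, counts, sheet, stagger_max,
                              base_error_rate, gzip) {
  all_reads <- unlist(lapply(seq_len(nrow(sheet)), function(j)
    build_reads(spacers, counts[, j], stagger_max, base_error_rate,
                barcode = sheet$barcode[j])), use.names = FALSE)
  all_reads <- sample(all_reads)  # shuffle samples together
  write_fastq(path, all_reads, "mixed", gzip)
}

#' @noRd
write_truth_json <- function(truth, path) {
  out <- list(
    enriched_genes = truth$enriched_genes,
    effect_log2 = as.list(truth$effect_log2),
    baseline = as.list(truth$baseline),
    counts = stats::setNames(
      lapply(seq_len(ncol(truth$counts)), function(j) truth$counts[, j]),
      colnames(truth$counts)),
    guide_ids = rownames(truth$counts),
    config = truth$config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Inverse of the 2^-ddCt arithmetic: the control sample's target Ct is
#' fixed at 25, the treated sample's at `25 - log2(fold)`, and the
#' reference gene at 20 in both samples.  Gaussian noise of sd
#' `ct_noise_sd` is added to every replicate reaction.
#'
#' @param true_fold_changes Named numeric vector, target -> fold change
#'   (> 0) of the treated sample relative to control.
#' @param reference_gene Reference gene name (default `"ACTB"`).
#' @param ct_noise_sd Per-replicate Gaussian Ct noise (default 0).
#' @param n_replicates Replicates per reaction (default 3).
#' @param seed RNG seed.
#' @return Long data.frame `sample_id,target,ct` with samples
#'   `"control"` and `"treated"`.
#' @export
simulate_qpcr <- function(true_fold_changes, reference_gene = "ACTB",
                          ct_noise_sd = 0, n_replicates = 3L, seed = NULL) {
  if (any(true_fold_changes <= 0)) sf_stop("fold changes must be positive")
  if (is.null(names(true_fold_changes)))
    sf_stop("true_fold_changes must be named by target")
  with_seed(seed, {
    rows <- list()
    add <- function(s, t, mu) {
      cts <- mu + stats::rnorm(n_replicates, 0, ct_noise_sd)
      rows[[length(rows) + 1]] <<- data.frame(
        sample_id = s, target = t, ct = cts, stringsAsFactors = FALSE)
    }
    for (t in names(true_fold_changes)) {
      add("control", t, 25)
      add("treated", t, 25 - log2(true_fold_changes[[t]]))
    }
    add("control", reference_gene, 20)
    add("treated", reference_gene, 20)
    do.call(rbind, rows)
  })
}

#' Simulate a cycloheximide-chase decay series
#'
#' `intensity(t) = exp(-(ln 2 / half_life) t)` times multiplicative
#' log-normal noise with coefficient of variation `noise_cv` (mean 1).
#'
#' @param half_life_h True half-life in hours (> 0).
#' @param times Chase time grid in hours (default `c(0, 2, 4, 6, 8)`,
#'   the usual harvest schedule).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (default 0).
#' @param seed RNG seed.
#' @return data.frame `time_h, intensity`.
#' @export
simulate_decay <- function(half_life_h, times = c(0, 2, 4, 6, 8),
                           noise_cv = 0, seed = NULL) {
  if (half_life_h <= 0) sf_stop("half_life_h must be positive")
  with_seed(seed, {
    mu <- exp(-(log(2) / half_life_h) * times)
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      mu <- mu * stats::rlnorm(length(times), meanlog = -sdlog^2 / 2,
                               sdlog = sdlog)
    }
    data.frame(time_h = times, intensity = mu)
  })
}
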