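# End-to-end orchestration: count -> normalize -> score -> call -> rank,
# with a plain-text config file, stage outputs as TSV, and a JSON run
# report that fully determines reproduction.

#' Read a run-config file
#'
#' Plain text, one `key = value` per line, `#` comments allowed.  Keys
#' mirror the CLI flags: `library`, `samples`, `fastq_dir`, `mode`,
#' `anchor`, `spacer_length`, `max_mismatch`, `tau`, `min_concordant`,
#' `out_dir`.
#'
#' @param path Config file path.
#' @return Named list of character values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) sf_stop(sprintf("config file not found: %s", path))
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  stats::setNames(lapply(kv, function(x) paste(x[-1], collapse = "=")),
                  vapply(kv, `[[`, character(1), 1))
}

#' Default pipeline parameters
#' @noRd
default_config <- function() {
  list(mode = "per_file", anchor = "CACCG", spacer_length = 20L,
       max_mismatch = 0L, tau = 0.5, min_concordant = 3L)
}

#' Run the full screen pipeline
#'
#' Validates the configuration, counts reads, normalizes (RPM then
#' log2(x+1)), scores guides (treated vs control as labelled in the
#' sample sheet), calls concordance hits, ranks both directions, writes
#' every stage table as TSV plus a JSON run report, and returns the
#' report.  Any stage failure aborts with a stage-tagged message before
#' outputs of later stages are written.
#'
#' @param config Named list (or path to a config file): `library` and
#'   `samples` paths are required; `fastq_dir` (with `<sample>.fastq[.gz]`
#'   files) or a `fastq_path` sample-sheet column supplies the reads;
#'   optional `mode`, `anchor`, `spacer_length`, `max_mismatch`, `tau`,
#'   `min_concordant`, `out_dir`.
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return The run report (list), invisibly; written as `report.json`.
#' @export
run_screen_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1)
    config <- read_run_config(config)
  cfg <- utils::modifyList(default_config(), config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  for (k in c("spacer_length", "max_mismatch", "min_concordant"))
    cfg[[k]] <- as.integer(cfg[[k]])
  cfg$tau <- as.numeric(cfg$tau)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      sf_stop(sprintf("[%s] %s", name, conditionMessage(e))))
  }

  # -- validation ------------------------------------------------------
  if (is.null(cfg$library) || is.null(cfg$samples))
    sf_stop("[config] 'library' and 'samples' paths are required")
  lib <- stage("config", load_library(cfg$library,
                                      spacer_length = cfg$spacer_length))
  sheet <- stage("config", load_sample_sheet(cfg$samples, for_scoring = TRUE))
  fastq_inputs <- NULL
  if (cfg$mode == "per_file") {
    if (!is.null(cfg$fastq_dir)) {
      cand <- file.path(cfg$fastq_dir, paste0(sheet$sample_id, ".fastq.gz"))
      miss <- !file.exists(cand)
      cand[miss] <- file.path(cfg$fastq_dir,
                              paste0(sheet$sample_id[miss], ".fastq"))
      if (any(!file.exists(cand)))
        sf_stop(sprintf("[config] FASTQ not found for sample(s): %s",
                        paste(sheet$sample_id[!file.exists(cand)],
                              collapse = ", ")))
      fastq_inputs <- stats::setNames(cand, sheet$sample_id)
    }
  } else {
    if (is.null(cfg$fastq)) sf_stop("[config] inline mode requires 'fastq'")
    fastq_inputs <- cfg$fastq
  }
  if (is.null(cfg$out_dir)) sf_stop("[config] out_dir is required")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  # -- stages ----------------------------------------------------------
  res <- stage("count", process_fastq(fastq_inputs, lib, sheet,
                                      mode = cfg$mode, anchor = cfg$anchor,
                                      spacer_length = cfg$spacer_length,
                                      max_mismatch = cfg$max_mismatch))
  write_counts(res$counts, file.path(cfg$out_dir, "counts.tsv"))

  rpm <- stage("normalize", rpm_normalize(res$counts))
  logm <- stage("normalize", log2_transform(rpm))
  write_normalized(logm, file.path(cfg$out_dir, "normalized_log2.tsv"))

  treated <- sheet$sample_id[sheet$condition == "treated"]
  control <- sheet$sample_id[sheet$condition == "control"]
  gsc <- stage("score", guide_scores(logm, treated, control, lib = lib))
  write_scores(gsc, file.path(cfg$out_dir, "guide_scores.tsv"))

  gene <- stage("call", gene_scores(gsc, lib, tau = cfg$tau,
                                    min_concordant = cfg$min_concordant))
  write_scores(gene, file.path(cfg$out_dir, "gene_scores.tsv"))
  write_scores(rank_genes(gene, "up"),
               file.path(cfg$out_dir, "ranked_up.tsv"))
  write_scores(rank_genes(gene, "down"),
               file.path(cfg$out_dir, "ranked_down.tsv"))

  report <- list(
    tool = "screenforge",
    version = as.character(utils::packageVersion("screenforge")),
    config = cfg[order(names(cfg))],
    stages = list(
      extraction = list(n_reads = res$stats$n_reads,
                        fraction_ok = res$stats$fraction_ok,
                        total = as.list(res$stats$total)),
      normalization = list(column_totals = as.list(colSums(res$counts))),
      scoring = list(n_guides = nrow(gsc),
                     treated = treated, control = control,
                     median_lfc_raw = stats::median(gsc$lfc_raw)),
      hits = list(n_genes = nrow(gene),
                  n_up_hits = sum(gene$hit & gene$direction == "up"),
                  n_down_hits = sum(gene$hit & gene$direction == "down"))))
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
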