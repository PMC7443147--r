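# Shared fixtures: tiny libraries built in code, plus independent
# straight-line oracle implementations used to cross-check the package.
# The oracles deliberately share no code with R/: plain loops only.

tiny_library <- function(n_genes = 3, guides_per_gene = 4, seed = 101) {
  generate_library(n_genes, guides_per_gene, seed = seed)
}

# deterministic distinct 20-mers for hand-built libraries
random_spacers <- function(n, seed = 555) {
  lib <- generate_library(n, 1, seed = seed)
  lib$spacer
}

two_sample_sheet <- function() {
  validate_sample_sheet(data.frame(
    sample_id = c("S_ctrl", "S_trt"),
    barcode = c("ACGTACGT", "TGCATGCA"),
    condition = c("control", "treated"),
    replicate = c(1L, 1L),
    stringsAsFactors = FALSE))
}

# write a FASTQ file from raw sequence strings
write_raw_fastq <- function(seqs, path = tempfile(fileext = ".fastq")) {
  lines <- as.vector(rbind(sprintf("@r%d", seq_along(seqs)), seqs,
                           rep("+", length(seqs)),
                           strrep("I", nchar(seqs))))
  writeLines(lines, path)
  path
}

# ---- oracles -------------------------------------------------------------

# leftmost-anchor oracle: enumerate every anchor occurrence by scanning
# all positions, then take the smallest
oracle_anchor_positions <- function(seq, anchor) {
  k <- nchar(anchor)
  hits <- integer(0)
  for (i in seq_len(max(0, nchar(seq) - k + 1)))
    if (substr(seq, i, i + k - 1) == anchor) hits <- c(hits, i)
  hits
}

# full pairwise Hamming scan of a spacer against every library spacer
oracle_hamming_map <- function(spacer, lib, max_mismatch) {
  dists <- vapply(lib$spacer, function(s) {
    a <- strsplit(spacer, "")[[1]]; b <- strsplit(s, "")[[1]]
    sum(a != b)
  }, integer(1))
  dmin <- min(dists)
  if (dmin > max_mismatch) return(NA_character_)
  cand <- lib$guide_id[dists == dmin]
  if (length(cand) == 1) cand else NA_character_
}

# straight-line reimplementation of counts -> hits (criterion: exact
# equality with the package pipeline on small libraries)
oracle_pipeline <- function(counts, lib, treated, control,
                            tau = 0.5, min_concordant = 3) {
  rpm <- counts
  for (j in seq_len(ncol(counts)))
    rpm[, j] <- counts[, j] / sum(counts[, j]) * 1e6
  lg <- log2(rpm + 1)
  lfc <- numeric(nrow(lg))
  for (i in seq_len(nrow(lg)))
    lfc[i] <- mean(lg[i, treated]) - mean(lg[i, control])
  lfc_c <- lfc - median(lfc)
  genes <- unique(lib$gene)
  out <- data.frame(gene = genes, score = NA_real_, n_up = NA_integer_,
                    n_down = NA_integer_, hit = NA, direction = "none",
                    stringsAsFactors = FALSE)
  for (g in seq_along(genes)) {
    idx <- which(lib$gene[match(rownames(counts), lib$guide_id)] == genes[g])
    v <- lfc_c[idx]
    n_up <- 0L; n_down <- 0L
    for (x in v) {
      if (x > tau) n_up <- n_up + 1L
      if (x < -tau) n_down <- n_down + 1L
    }
    out$score[g] <- mean(v)
    out$n_up[g] <- n_up
    out$n_down[g] <- n_down
    hit_up <- length(v) >= min_concordant && n_up >= min_concordant
    hit_down <- length(v) >= min_concordant && n_down >= min_concordant
    out$hit[g] <- hit_up || hit_down
    out$direction[g] <- if (hit_up) "up" else if (hit_down) "down" else "none"
  }
  out
}

# hypergeometric upper tail by direct point-mass summation
oracle_hyper_tail <- function(k, n_a, n_b, universe) {
  total <- 0
  for (x in k:min(n_a, n_b))
    total <- total + choose(n_a, x) * choose(universe - n_a, n_b - x) /
      choose(universe, n_b)
  total
}
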