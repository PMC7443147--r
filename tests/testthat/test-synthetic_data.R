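test_that("generate_library builds unique spacers deterministically", {
  lib <- generate_library(1000, 4, seed = 7)
  expect_equal(nrow(lib), 4000)
  expect_equal(anyDuplicated(lib$spacer), 0)
  expect_true(all(table(lib$gene) == 4))

  # same seed -> byte-identical library file
  p1 <- tempfile(); p2 <- tempfile()
  write_library(generate_library(50, 4, seed = 3), p1)
  write_library(generate_library(50, 4, seed = 3), p2)
  expect_identical(readLines(p1), readLines(p2))

  expect_equal(nrow(generate_library(2, 1, seed = 1)), 2)
  expect_error(generate_library(0, 4), "positive")
})

test_that("simulate_screen truth is internally consistent", {
  lib <- generate_library(100, 4, seed = 5)
  truth <- simulate_screen(lib, enriched_genes = c("G0003", "G0010"),
                           effect_log2 = 2, depth = 5e4, seed = 11,
                           emit_fastq = FALSE)
  expect_equal(unname(colSums(truth$counts)), rep(5e4, 2))
  expect_setequal(truth$enriched_genes, c("G0003", "G0010"))
  expect_equal(unname(truth$effect_log2), rep(2, 2))
  # enrichment applied to all 8 guides of the two genes
  expect_length(truth$guide_effects, 8)

  expect_error(simulate_screen(lib, enriched_genes = "NOPE",
                               emit_fastq = FALSE), "not in library")

  # full determinism under a fixed seed, including FASTQ bytes
  d1 <- tempfile(); d2 <- tempfile()
  t1 <- simulate_screen(lib, enriched_genes = 2, depth = 3000, seed = 77,
                        out_dir = d1, gzip = FALSE)
  t2 <- simulate_screen(lib, enriched_genes = 2, depth = 3000, seed = 77,
                        out_dir = d2, gzip = FALSE)
  expect_identical(t1$counts, t2$counts)
  expect_identical(readLines(t1$fastq[[1]]), readLines(t2$fastq[[1]]))
  expect_identical(readLines(t1$fastq[[2]]), readLines(t2$fastq[[2]]))
})

test_that("emitted FASTQ matches truth counts by brute-force spacer tally", {
  lib <- generate_library(10, 4, seed = 2)
  truth <- simulate_screen(lib, enriched_genes = 1, depth = 2000, seed = 4,
                           out_dir = tempfile(), gzip = FALSE)
  for (s in names(truth$fastq)) {
    lines <- readLines(truth$fastq[[s]])
    seqs <- lines[seq(2, length(lines), by = 4)]
    expect_length(seqs, sum(truth$counts[, s]))
    tally <- vapply(lib$spacer, function(sp)
      sum(grepl(paste0("CACCG", sp), seqs, fixed = TRUE)), integer(1))
    expect_equal(unname(tally), unname(truth$counts[, s]))
  }
})

test_that("per-guide effects support partial concordance (2-of-4 is not a hit)", {
  lib <- generate_library(50, 4, seed = 6)
  gids <- lib$guide_id[lib$gene == "G0001"]
  truth <- simulate_screen(lib,
                           guide_effects = setNames(c(2, 2), gids[1:2]),
                           depth = 2e5, seed = 8, emit_fastq = FALSE)
  lg <- log2_transform(rpm_normalize(truth$counts))
  gn <- gene_scores(guide_scores(lg, "treated_1", "control_1", lib = lib), lib)
  row <- gn[gn$gene == "G0001", ]
  expect_equal(row$n_up, 2)
  expect_false(row$hit)
})

test_that("base_error_rate degrades fraction_ok as expected", {
  lib <- generate_library(20, 4, seed = 12)
  sheet <- two_sample_sheet()
  truth <- simulate_screen(lib, sheet = sheet, depth = 4000, seed = 5,
                           out_dir = tempfile(), base_error_rate = 0.01,
                           gzip = FALSE)
  res <- process_fastq(truth$fastq, lib, sheet)
  # ~67 bases/read at 1% error: a sizable minority of reads damaged
  expect_lt(res$stats$fraction_ok, 1)
  expect_gt(res$stats$fraction_ok, 0.3)
  expect_equal(sum(res$stats$total), res$stats$n_reads)
})

test_that("simulate_qpcr inverts the ddCt arithmetic", {
  ct <- simulate_qpcr(c(GENE = 4), ct_noise_sd = 0)
  res <- qpcr_fold_changes(ct, "ACTB", "control")
  expect_equal(res$fold_change[res$sample_id == "treated"], 4)

  ct1 <- simulate_qpcr(c(GENE = 1), ct_noise_sd = 0)
  res1 <- qpcr_fold_changes(ct1, "ACTB", "control")
  expect_equal(res1$fold_change[res1$sample_id == "treated"], 1)

  # noisy recovery: median over 200 seeds within 5% of truth
  folds <- vapply(1:200, function(s) {
    ct <- simulate_qpcr(c(GENE = 2.5), ct_noise_sd = 0.05, seed = s)
    res <- qpcr_fold_changes(ct, "ACTB", "control")
    res$fold_change[res$sample_id == "treated"]
  }, numeric(1))
  expect_lt(abs(median(folds) - 2.5) / 2.5, 0.05)
})

test_that("simulate_decay produces exact halving without noise", {
  d <- simulate_decay(4, times = c(0, 4, 8))
  expect_equal(d$intensity, c(1, 0.5, 0.25))
  f <- fit_half_life(simulate_decay(8))
  expect_equal(f$half_life, 8, tolerance = 1e-12)
})

test_that("null screens are centred and rarely called at default tau", {
  lib <- generate_library(200, 4, seed = 1)
  hit_rates <- vapply(1:20, function(s) {
    truth <- simulate_screen(lib, enriched_genes = 0, depth = 1e6,
                             seed = s, emit_fastq = FALSE)
    lg <- log2_transform(rpm_normalize(truth$counts))
    gn <- gene_scores(guide_scores(lg, "treated_1", "control_1", lib = lib), lib)
    expect_lt(abs(median(gn$score)), 0.05)
    mean(gn$hit)
  }, numeric(1))
  expect_lt(mean(hit_rates), 0.05)
})
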