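test_that("extract_spacer finds the leftmost anchor and handles failures", {
  res <- extract_spacer("TTACACCGACGTACGTACGTACGTACGTTTTT")
  expect_equal(res$status, "ok")
  expect_equal(res$spacer, "ACGTACGTACGTACGTACGT")

  expect_equal(extract_spacer("AAAATTTTGGGG")$status, "no_anchor")
  expect_equal(extract_spacer(paste0("CACCG", strrep("A", 10)))$status,
               "insufficient_length")
  expect_error(extract_spacer(""), "empty")
  # anchor longer than read
  expect_equal(extract_spacer("CAC", anchor = "CACCG")$status, "no_anchor")
})

test_that("leftmost occurrence wins when the anchor recurs (enumeration oracle)", {
  set.seed(11)
  for (i in 1:20) {
    sp1 <- paste(sample(c("A", "G", "T"), 20, replace = TRUE), collapse = "")
    sp2 <- paste(sample(c("A", "G", "T"), 20, replace = TRUE), collapse = "")
    read <- paste0("TT", "CACCG", sp1, "CACCG", sp2, "AAAA")
    pos <- oracle_anchor_positions(read, "CACCG")
    expect_gte(length(pos), 2)
    expected <- substr(read, min(pos) + 5, min(pos) + 24)
    expect_equal(extract_spacer(read)$spacer, expected)
  }
})

test_that("map_spacer: exact, 1-mismatch unique-best, and ambiguity", {
  lib <- tiny_library()
  expect_equal(map_spacer(lib$spacer[3], lib), lib$guide_id[3])
  expect_true(is.na(map_spacer(strrep("A", 20), lib)))

  # mutate one base: unmapped at mm=0, mapped at mm=1; cross-check with a
  # full pairwise Hamming scan
  set.seed(22)
  for (i in sample(nrow(lib), 5)) {
    sp <- lib$spacer[i]
    pos <- sample(20, 1)
    old <- substr(sp, pos, pos)
    substr(sp, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    expect_true(is.na(map_spacer(sp, lib, max_mismatch = 0)))
    expect_equal(map_spacer(sp, lib, max_mismatch = 1),
                 oracle_hamming_map(sp, lib, 1))
  }

  # ambiguity: a spacer at distance 1 from two library spacers stays unmapped
  base <- strrep("A", 20)
  amb <- data.frame(
    guide_id = c("g1", "g2"), gene = c("X", "X"),
    spacer = c(paste0("C", substr(base, 2, 20)),
               paste0("G", substr(base, 2, 20))),
    stringsAsFactors = FALSE)
  expect_true(is.na(map_spacer(base, amb, max_mismatch = 1)))
  expect_true(is.na(oracle_hamming_map(base, amb, 1)))
})

test_that("demultiplex: inline prefix lookup and per-file assignment", {
  sheet <- two_sample_sheet()
  dm <- demultiplex(c("ACGTACGTAAAA", "TGCATGCAGGGG", "NNNNNNNNTTTT", "ACG"),
                    sheet, mode = "inline_prefix")
  expect_equal(dm$sample_id, c("S_ctrl", "S_trt", NA, NA))
  expect_equal(dm$rest[1], "AAAA")

  pf <- demultiplex(c("AAAA", "CCCC"), sheet, mode = "per_file",
                    file_sample = "S_trt")
  expect_equal(pf$sample_id, c("S_trt", "S_trt"))
  expect_error(demultiplex("AAAA", sheet, mode = "per_file",
                           file_sample = "nope"), "registered")
})

test_that("process_fastq counts statuses with fixed precedence and conserves reads", {
  lib <- tiny_library()
  sheet <- two_sample_sheet()
  mk <- function(spacer) paste0("TTGTGGAAAGGACGAAACACCG", spacer,
                                "GTTTTAGAGCTAGAAATAGC")
  seqs <- c(
    paste0(sheet$barcode[1], mk(lib$spacer[1])),   # ok -> S_ctrl
    paste0(sheet$barcode[2], mk(lib$spacer[2])),   # ok -> S_trt
    paste0(sheet$barcode[2], mk(strrep("A", 20))), # unmapped_spacer
    paste0(sheet$barcode[1], "TTTTTTTTTTTTTTTTTTTTTT"),  # no_anchor
    paste0(sheet$barcode[1], "CACCGAAAA"),         # insufficient_length
    paste0("GGGGGGGG", mk(lib$spacer[1])))         # unknown_barcode
  fq <- write_raw_fastq(seqs)
  res <- process_fastq(fq, lib, sheet, mode = "inline_prefix")

  expect_equal(unname(res$stats$total[c("ok", "unmapped_spacer", "no_anchor",
                                        "insufficient_length",
                                        "unknown_barcode")]),
               c(2, 1, 1, 1, 1))
  expect_equal(res$stats$n_reads, 6)
  expect_equal(sum(res$stats$total), res$stats$n_reads)
  expect_equal(sum(res$counts), 2)
  expect_equal(res$counts[lib$guide_id[1], "S_ctrl"], 1L)
  expect_equal(res$counts[lib$guide_id[2], "S_trt"], 1L)
  # all library guides present as zero-filled rows
  expect_equal(rownames(res$counts), lib$guide_id)
})

test_that("counting is order-independent and corruption is tallied exactly", {
  lib <- tiny_library(5, 4, seed = 3)
  sheet <- two_sample_sheet()
  truth <- simulate_screen(lib, sheet = sheet, enriched_genes = 1,
                           depth = 2000, seed = 13, out_dir = tempfile(),
                           barcode_mode = "inline_prefix", gzip = FALSE)
  res <- process_fastq(truth$fastq, lib, sheet, mode = "inline_prefix")
  expect_identical(res$counts, truth$counts)
  expect_equal(res$stats$fraction_ok, 1.0)

  # shuffle read order: identical matrix
  lines <- readLines(truth$fastq[["reads"]])
  rec <- matrix(lines, nrow = 4)
  set.seed(1)
  shuf <- write_raw_fastq(character(0))
  writeLines(as.vector(rec[, sample(ncol(rec))]), shuf)
  res2 <- process_fastq(shuf, lib, sheet, mode = "inline_prefix")
  expect_identical(res2$counts, res$counts)

  # corrupt 10 anchors: ok drops by exactly 10, no_anchor = 10
  corrupt <- rec
  corrupt[2, 1:10] <- sub("CACCG", "CAGGG", corrupt[2, 1:10], fixed = TRUE)
  fq3 <- write_raw_fastq(character(0))
  writeLines(as.vector(corrupt), fq3)
  res3 <- process_fastq(fq3, lib, sheet, mode = "inline_prefix")
  expect_equal(unname(res3$stats$total[["no_anchor"]]), 10)
  expect_equal(sum(res3$counts), sum(res$counts) - 10)
})

test_that("per-sample column sums match an independent barcode tally", {
  lib <- tiny_library(4, 4, seed = 9)
  sheet <- two_sample_sheet()
  truth <- simulate_screen(lib, sheet = sheet, depth = 1500, seed = 21,
                           out_dir = tempfile(),
                           barcode_mode = "inline_prefix", gzip = FALSE)
  res <- process_fastq(truth$fastq, lib, sheet, mode = "inline_prefix")
  lines <- readLines(truth$fastq[["reads"]])
  seqs <- lines[seq(2, length(lines), by = 4)]
  for (j in seq_len(nrow(sheet))) {
    tally <- sum(startsWith(seqs, sheet$barcode[j]))
    expect_equal(unname(colSums(res$counts)[sheet$sample_id[j]]), tally)
  }
})

test_that("malformed FASTQ errors name the file", {
  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+"), bad)  # truncated record
  lib <- tiny_library()
  err <- expect_error(
    process_fastq(bad, lib, two_sample_sheet(), mode = "inline_prefix"),
    class = "screenforge_format_error")
  expect_match(conditionMessage(err), basename(bad), fixed = TRUE)
})
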