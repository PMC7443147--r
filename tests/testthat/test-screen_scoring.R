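log2_mat <- function(m) {
  structure(log2(m + 1), scale = "log2",
            class = c("normalized_matrix", "matrix"))
}

test_that("guide_scores: lfc arithmetic, median centering, input checks", {
  rpm <- matrix(100, nrow = 5, ncol = 2,
                dimnames = list(paste0("g", 1:5), c("ctrl", "trt")))
  # identical arms -> all zero
  gs0 <- guide_scores(log2_mat(rpm), "trt", "ctrl")
  expect_equal(gs0$lfc_raw, rep(0, 5))
  expect_equal(gs0$lfc_corrected, rep(0, 5))

  # one guide 100 -> 400 RPM against an unchanged background
  rpm["g1", "trt"] <- 400
  gs <- guide_scores(log2_mat(rpm), "trt", "ctrl")
  expect_equal(gs$lfc_raw[1], log2(401) - log2(101))  # hand arithmetic
  expect_equal(median(gs$lfc_corrected), 0)

  expect_error(guide_scores(log2_mat(rpm), "nope", "ctrl"), "unknown sample")
  expect_error(guide_scores(log2_mat(rpm), "trt", "trt"), "overlap")
  expect_error(guide_scores(log2_mat(rpm), character(0), "ctrl"), "non-empty")
  expect_error(guide_scores(rpm, "trt", "ctrl"), "log2")
})

test_that("guide_scores matches a brute-force per-guide loop on random input", {
  set.seed(77)
  m <- matrix(runif(200 * 4, 0, 12), nrow = 200,
              dimnames = list(paste0("g", 1:200),
                              c("c1", "c2", "t1", "t2")))
  lm2 <- structure(m, scale = "log2", class = c("normalized_matrix", "matrix"))
  gs <- guide_scores(lm2, c("t1", "t2"), c("c1", "c2"))
  raw <- numeric(200)
  for (i in 1:200) raw[i] <- mean(m[i, c("t1", "t2")]) - mean(m[i, c("c1", "c2")])
  expect_equal(gs$lfc_raw, raw)
  expect_equal(gs$lfc_corrected, raw - median(raw))
  expect_equal(median(gs$lfc_corrected), 0, tolerance = 1e-12)

  # median-correction idempotence and shift invariance
  gs2 <- guide_scores(lm2, c("t1", "t2"), c("c1", "c2"), median_correct = FALSE)
  expect_equal(gs$lfc_corrected - median(gs$lfc_corrected), gs$lfc_corrected)
  shifted <- lm2
  shifted[, c("t1", "t2")] <- shifted[, c("t1", "t2")] + 1.7
  gs3 <- guide_scores(shifted, c("t1", "t2"), c("c1", "c2"))
  expect_equal(gs3$lfc_raw, gs$lfc_raw + 1.7)
  expect_equal(gs3$lfc_corrected, gs$lfc_corrected)
  expect_equal(gs2$lfc_raw, gs2$lfc_corrected)
})

fake_gscores <- function(values, lib) {
  data.frame(guide_id = lib$guide_id, gene = lib$gene,
             lfc_raw = values, lfc_corrected = values,
             stringsAsFactors = FALSE)
}

test_that("gene_scores: concordance counting, ties, and hit calls", {
  lib <- data.frame(guide_id = paste0("q", 1:4), gene = "X",
                    spacer = random_spacers(4), stringsAsFactors = FALSE)

  # sign-enumeration oracle at tau = 0: (+1.2, +0.8, +0.5, -0.1)
  g <- gene_scores(fake_gscores(c(1.2, 0.8, 0.5, -0.1), lib),
                   lib, tau = 0, min_concordant = 3)
  expect_equal(g$n_up, sum(c(1.2, 0.8, 0.5, -0.1) > 0))
  expect_equal(g$n_up, 3)
  expect_true(g$hit)
  expect_equal(g$direction, "up")
  expect_equal(g$score, mean(c(1.2, 0.8, 0.5, -0.1)))

  # ties at tau are neutral
  g0 <- gene_scores(fake_gscores(rep(0, 4), lib), lib, tau = 0)
  expect_equal(g0$n_up + g0$n_down, 0)
  expect_false(g0$hit)

  # 2 up / 2 down: no side reaches 3
  g2 <- gene_scores(fake_gscores(c(2, 2, -2, -2), lib), lib,
                    tau = 0, min_concordant = 3)
  expect_false(g2$hit)
  expect_equal(g2$direction, "none")

  # default tau = 0.5 requires a meaningful shift
  gt <- gene_scores(fake_gscores(c(0.4, 0.3, 0.2, 0.1), lib), lib)
  expect_equal(gt$n_up, 0)
  expect_false(gt$hit)

  # not-callable genes warn
  lib1 <- lib[1:2, ]
  expect_warning(
    gnc <- gene_scores(fake_gscores(c(3, 3), lib1), lib1, min_concordant = 3),
    "not callable")
  expect_false(gnc$hit)

  expect_error(gene_scores(fake_gscores(rep(1, 4),
                                        transform(lib, guide_id = paste0("z", 1:4))),
                           lib), "absent")
})

test_that("rank_genes orders hits first by |score| with lexicographic ties", {
  genes <- data.frame(
    gene = c("C", "B", "A", "D"),
    score = c(2.0, 1.0, 1.0, 5.0),
    n_guides = 4, n_up = c(4, 4, 4, 0), n_down = c(0, 0, 0, 1),
    hit = c(TRUE, TRUE, TRUE, FALSE),
    direction = c("up", "up", "up", "none"),
    stringsAsFactors = FALSE)
  r <- rank_genes(genes, "up")
  expect_equal(r$gene, c("C", "A", "B", "D"))
  expect_equal(r$rank, 1:4)
  expect_error(rank_genes(genes[0, ], "up"), "empty")
})

test_that("full pipeline equals the straight-line oracle on small libraries", {
  for (seed in c(3, 14, 15)) {
    lib <- generate_library(sample(5:20, 1), 4, seed = seed)
    truth <- simulate_screen(lib, enriched_genes = 2, effect_log2 = 2,
                             depth = 5e4, seed = seed, emit_fastq = FALSE)
    lg <- log2_transform(rpm_normalize(truth$counts))
    gs <- guide_scores(lg, "treated_1", "control_1", lib = lib)
    gn <- gene_scores(gs, lib)
    orc <- oracle_pipeline(truth$counts, lib, "treated_1", "control_1")
    expect_equal(gn$score, orc$score)
    expect_equal(gn$n_up, orc$n_up)
    expect_equal(gn$n_down, orc$n_down)
    expect_identical(gn$hit, orc$hit)
    expect_identical(gn$direction, orc$direction)
  }
})

test_that("gene score is monotone in the simulated effect size", {
  lib <- generate_library(50, 4, seed = 8)
  score_at <- function(eff) {
    truth <- simulate_screen(lib, enriched_genes = "G0001", effect_log2 = eff,
                             depth = 1e5, seed = 99, emit_fastq = FALSE)
    lg <- log2_transform(rpm_normalize(truth$counts))
    gn <- gene_scores(guide_scores(lg, "treated_1", "control_1", lib = lib), lib)
    gn$score[gn$gene == "G0001"]
  }
  s <- vapply(c(0.5, 1, 2, 3), score_at, numeric(1))
  expect_true(all(diff(s) > 0))
})
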