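test_that("barcode resolution follows the 1-mismatch unique-owner rule", {
  wl <- c("AAAA", "CCCC", "GGGG", "ACCC")
  idx <- barcode_index(wl)
  m <- match_barcodes(idx, c("AAAA", "AAAT", "ACCC", "CCCA", "TTTT",
                             "GCCC"))
  expect_identical(as.integer(m), c(1L, 1L, 4L, 2L, NA, NA))
  # ACCC is exact even though it is 1 mismatch from CCCC (exact wins);
  # GCCC is 1 mismatch from both CCCC and ACCC -> ambiguous
  expect_identical(attr(m, "n_ambiguous"), 1L)
  expect_identical(attr(m, "n_unmatched"), 1L)
  expect_error(barcode_index(c("AA", "AAA")), "same length")
})

test_that("1-mismatch resolution agrees with an exhaustive Hamming scan", {
  withr::with_seed(42, {
    bases <- c("A", "C", "G", "T")
    wl <- unique(replicate(60, paste(sample(bases, 6, TRUE), collapse = "")))
    idx <- barcode_index(wl)
    queries <- c(wl[1:10],
                 replicate(200, paste(sample(bases, 6, TRUE),
                                      collapse = "")))
    got <- as.integer(match_barcodes(idx, queries))
    want <- vapply(queries, function(q) hamming_scan(wl, q), integer(1),
                   USE.NAMES = FALSE)
    expect_identical(got, want)
  })
})

test_that("spacer matching is anchored with optional scan and mismatch modes", {
  lib <- tiny_library()
  reads <- c(lib$spacer[1],                       # exact at offset 0
             paste0("G", lib$spacer[2]),          # offset 1
             sub("^A", "T", lib$spacer[1]),       # 1 mismatch
             "NNNNNNNNNNNNNNNNNNNNNNNN")
  expect_identical(match_spacers(lib, reads), c(1L, NA, NA, NA))
  expect_identical(match_spacers(lib, reads, scan_window = 1),
                   c(1L, 2L, NA, NA))
  expect_identical(match_spacers(lib, reads, max_mismatch = 1),
                   c(1L, NA, 1L, NA))
})

test_that("count matrix accumulates matched reads with a faithful report", {
  tmp <- withr::local_tempdir()
  lib <- tiny_library()
  wl <- c("AAAACCCC", "GGGGTTTT", "ACGTACGT")
  idx <- barcode_index(wl)
  sp <- lib$spacer[c(1, 1, 1, 2, 3, 1, 1, 1, 1, 1)]
  bc <- c(rep("AAAACCCC", 3), "AAAACCCC", "GGGGTTTT",
          "TTTTTTTT", "TTTTTTTT", "CCCCCCCC", "CCCCCCCC", "GGGGTTTA")
  f1 <- file.path(tmp, "r1.fastq"); f2 <- file.path(tmp, "i1.fastq")
  write_fastq_pair(sp, bc, f1, f2)
  res <- build_count_matrix(f1, f2, idx, lib)
  expect_identical(unname(res$report["reads"]), 10)
  # last barcode is 1 mismatch from GGGGTTTT -> matched
  expect_identical(unname(res$report["barcode_matched"]), 6)
  expect_identical(unname(res$report["both_matched"]), 6)
  expect_identical(sum(res$counts), unname(res$report["both_matched"]))
  expect_identical(as.numeric(res$counts["AAAACCCC", c("sgA-1", "sgA-2")]),
                   c(3, 1))
  expect_identical(as.numeric(res$counts["GGGGTTTT", "sgB-1"]), 1)
})

test_that("empty read stream yields an empty matrix and zeroed report", {
  tmp <- withr::local_tempdir()
  f1 <- file.path(tmp, "r1.fastq"); file.create(f1)
  res <- build_count_matrix(f1, f1, barcode_index("AAAA"), tiny_library())
  expect_identical(nrow(res$counts), 0L)
  expect_true(all(res$report == 0))
})

test_that("assignment thresholds, specificity and tie handling", {
  lib <- tiny_library()
  cm <- Matrix::Matrix(rbind(
    c(18, 2, 0, 0),    # total 20, s = 0.9 -> assigned
    c(16, 3, 0, 0),    # total 19 -> low_counts
    c(15, 5, 0, 0),    # s = 0.75 -> low_specificity
    c(10, 10, 0, 0)    # tie
  ), sparse = TRUE)
  dimnames(cm) <- list(paste0("c", 1:4), lib$sgrna)
  at <- assign_cells(cm, lib)
  expect_identical(at$reason,
                   c("assigned", "low_counts", "low_specificity", "tie"))
  expect_identical(at$sgrna[1], "sgA-1")
  expect_identical(at$target[1], "A")
  expect_equal(at$specificity[1], 0.9)

  # target-level aggregation: sgA-1 + sgA-2 = 20/25 = 0.8 passes
  cm2 <- Matrix::Matrix(rbind(c(12, 8, 5, 0)), sparse = TRUE)
  dimnames(cm2) <- list("c1", lib$sgrna)
  expect_false(assign_cells(cm2, lib)$assigned)
  at2 <- assign_cells(cm2, lib, level = "target")
  expect_true(at2$assigned)
  expect_identical(at2$target, "A")
  expect_identical(at2$sgrna, "sgA-1")
})

test_that("raising thresholds never enlarges the assigned set", {
  lib <- tiny_library()
  withr::with_seed(11, {
    cm <- Matrix::Matrix(matrix(rpois(200 * 4, 6), ncol = 4), sparse = TRUE)
    dimnames(cm) <- list(paste0("c", 1:200), lib$sgrna)
    base <- assign_cells(cm, lib, min_counts = 10, min_specificity = 0.5)
    for (mc in c(15, 25)) {
      for (ms in c(0.6, 0.9)) {
        sub <- assign_cells(cm, lib, min_counts = mc, min_specificity = ms)
        expect_true(all(sub$cell[sub$assigned] %in%
                          base$cell[base$assigned]))
      }
    }
  })
})

test_that("assignment summary reports the captured fraction", {
  tab <- make_assignment(paste0("c", 1:15),
                         rep(c("A", "B"), c(10, 5)))
  s <- assignment_summary(tab, n_captured = 30)
  expect_identical(s$n_assigned, 15L)
  expect_equal(s$fraction, 0.5)
  expect_identical(as.integer(s$per_target[c("A", "B")]), c(10L, 5L))

  big <- make_assignment(paste0("c", 1:3045), rep("GATA1", 3045))
  expect_identical(assignment_summary(big, 6390)$percent, 48)

  none <- tab; none$assigned <- FALSE
  expect_equal(assignment_summary(none, 10)$fraction, 0)
  expect_error(assignment_summary(tab, 0), "positive")
})

test_that("cost per cell is the rounded sample-cost quotient", {
  expect_identical(cost_per_cell(1400, 3045), 0.46)
  expect_identical(cost_per_cell(750, 750), 1)
  expect_identical(cost_per_cell(100, 3), 33.33)
  expect_error(cost_per_cell(100, 0), "positive")
})

test_that("clean simulated fastqs are assigned with perfect accuracy", {
  cfg <- sim_config(n_targets = 3, sgrnas_per_target = 2, n_nt = 1,
                    cells_per_sgrna = 12, contamination = 0,
                    error_rate = 0, barcode_length = 10, seed = 5)
  fq <- simulate_sgrna_fastq(cfg)
  idx <- barcode_index(fq$whitelist)
  res <- build_count_matrix(fq$spacer_fastq, fq$index_fastq, idx,
                            fq$library)
  at <- assign_cells(res, fq$library)
  got <- at[at$assigned, ]
  truth <- fq$truth$sgrna[match(got$cell, fq$truth$cell)]
  expect_gt(nrow(got), 0)
  expect_identical(got$sgrna, truth)
  expect_true(all(got$specificity == 1))
})

test_that("moderate contamination keeps specificity above threshold and truth", {
  cfg <- sim_config(n_targets = 3, sgrnas_per_target = 2, n_nt = 1,
                    cells_per_sgrna = 15, contamination = 0.15,
                    error_rate = 0, barcode_length = 10,
                    reads_meanlog = log(120), seed = 6)
  fq <- simulate_sgrna_fastq(cfg)
  idx <- barcode_index(fq$whitelist)
  res <- build_count_matrix(fq$spacer_fastq, fq$index_fastq, idx,
                            fq$library)
  at <- assign_cells(res, fq$library)
  got <- at[at$assigned, ]
  truth <- fq$truth$sgrna[match(got$cell, fq$truth$cell)]
  expect_gt(nrow(got), 0.9 * nrow(fq$truth))
  expect_identical(got$sgrna, truth)
  expect_true(all(got$specificity >= 0.8))
})
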