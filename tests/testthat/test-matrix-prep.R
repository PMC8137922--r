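chrom_sizes <- c(chr1 = 10000L, chr2 = 5000L)

test_that("tile matrix places both insertion sites by floor arithmetic", {
  fr <- data.frame(chrom = "chr1", start = 100L, end = 700L,
                   barcode = "c1", count = 1L)
  m <- make_tile_matrix(fr, chrom_sizes, tile_size = 500)
  expect_equal(as.numeric(m["c1", "chr1:0-500"]), 1)   # pos 100
  expect_equal(as.numeric(m["c1", "chr1:500-1000"]), 1) # pos 699
  expect_equal(sum(m), 2)

  inside <- data.frame(chrom = "chr1", start = 120L, end = 180L,
                       barcode = "c1", count = 1L)
  m2 <- make_tile_matrix(inside, chrom_sizes, tile_size = 500)
  expect_equal(as.numeric(m2["c1", "chr1:0-500"]), 2)

  empty <- fr[0, ]
  m3 <- make_tile_matrix(empty, chrom_sizes, tile_size = 500,
                         cells = "c1")
  expect_equal(sum(m3), 0)
})

test_that("tile totals conserve two insertions per fragment; clipping warns", {
  withr::with_seed(3, {
    n <- 200
    fr <- data.frame(chrom = sample(names(chrom_sizes), n, TRUE),
                     start = sample(0:4000, n, TRUE),
                     barcode = sample(c("a", "b", "c"), n, TRUE),
                     count = 1L)
    fr$end <- fr$start + sample(50:400, n, TRUE)
    m <- make_tile_matrix(fr, chrom_sizes)
    expect_equal(sum(m), 2 * n)
  })
  over <- data.frame(chrom = "chr2", start = 4900L, end = 5400L,
                     barcode = "c1", count = 1L)
  expect_warning(mo <- make_tile_matrix(over, chrom_sizes), "clipped")
  expect_equal(sum(mo), 2)
})

test_that("peak counting is half-open and rejects overlapping peaks", {
  peaks <- data.frame(chrom = "chr1", start = c(100L, 200L),
                      end = c(200L, 300L))
  # insertions at peak start counted, at peak end not
  fr <- data.frame(chrom = "chr1", start = c(100L, 150L),
                   end = c(201L, 300L),  # sites 100,200 and 150,299
                   barcode = "c1", count = 1L)
  m <- make_peak_matrix(fr, peaks)
  expect_equal(as.numeric(m["c1", ]), c(2, 2))

  spanning <- data.frame(chrom = "chr1", start = 150L, end = 251L,
                         barcode = "c1", count = 1L)
  expect_equal(as.numeric(make_peak_matrix(spanning, peaks)["c1", ]),
               c(1, 1))

  # zero-insertion cell keeps its row
  m2 <- make_peak_matrix(fr, peaks, cells = c("c1", "c2"))
  expect_identical(rownames(m2), c("c1", "c2"))
  expect_equal(sum(m2["c2", ]), 0)

  bad <- data.frame(chrom = "chr1", start = c(100L, 150L),
                    end = c(200L, 250L))
  expect_error(make_peak_matrix(fr, bad), "overlapping")
})

test_that("uniform insertion profiles give TSS enrichment near 1", {
  # one insertion per bp across a TSS-centred window
  tss <- data.frame(chrom = "chr1", start = 5000L)
  pos <- 3000:7000
  fr <- data.frame(chrom = "chr1", start = pos, end = pos + 1L,
                   barcode = "u", count = 1L)
  # each fragment contributes sites start and end-1 = start (width-1 frags)
  qc <- compute_qc(fr, tss)
  expect_lt(abs(qc$tss_enrichment - 1), 0.05)
  expect_identical(qc$n_fragments, length(pos))

  # enriched cell: pile-up at the TSS, sparse flanks
  centre <- rep(4990:5010, 10)
  fr2 <- rbind(fr, data.frame(chrom = "chr1", start = centre,
                              end = centre + 1L, barcode = "e",
                              count = 1L))
  qc2 <- compute_qc(fr2, tss)
  expect_gt(qc2$tss_enrichment[qc2$cell == "e"], 4)

  # no signal anywhere near the TSS -> enrichment 0
  far <- data.frame(chrom = "chr1", start = 9000L, end = 9050L,
                    barcode = "z", count = 1L)
  expect_equal(compute_qc(far, tss)$tss_enrichment, 0)
})

test_that("cell filtering requires both QC thresholds and is monotone", {
  qc <- data.frame(cell = c("a", "b", "c", "d"),
                   n_fragments = c(900L, 5000L, 2000L, 1000L),
                   tss_enrichment = c(10, 3.9, 8, 4))
  expect_identical(filter_cells(qc), c("c", "d"))
  loose <- filter_cells(qc, min_tss = 0, min_frags = 0)
  for (mt in c(2, 6)) {
    for (mf in c(500, 1500)) {
      expect_true(all(filter_cells(qc, mt, mf) %in% loose))
    }
  }
})

test_that("pseudobulk columns are scaled to the target and depth-invariant", {
  m <- Matrix::Matrix(rbind(c(3, 1), c(6, 2), c(1, 1)), sparse = TRUE)
  dimnames(m) <- list(c("c1", "c2", "c3"), c("p1", "p2"))
  pb <- pseudobulk(m, c(c1 = "g1"), scale_to = 1e6)
  expect_equal(as.numeric(pb[, "g1"]), c(750000, 250000))

  # two proportional cells against one: identical scaled columns
  pb2 <- pseudobulk(m, c(c1 = "g1", c2 = "g1", c3 = "g2"))
  expect_equal(as.numeric(pb2[, "g1"]), c(750000, 250000))
  expect_equal(sum(pb2[, "g2"]), 1e6)

  z <- Matrix::Matrix(rbind(c(0, 0)), sparse = TRUE)
  dimnames(z) <- list("c0", c("p1", "p2"))
  expect_warning(pb3 <- pseudobulk(z, c(c0 = "g0")), "all-zero")
  expect_equal(sum(pb3), 0)
})

test_that("LSI is depth-invariant after binarization and reconstructs rank", {
  m <- Matrix::Matrix(rbind(c(2, 0, 4, 1), c(4, 0, 8, 2), c(0, 3, 0, 5),
                            c(1, 2, 3, 4)), sparse = TRUE)
  dimnames(m) <- list(paste0("c", 1:4), paste0("f", 1:4))
  e <- lsi_embed(m, n_dims = 3)
  # cells 1 and 2 are proportional -> identical binarized rows
  expect_equal(e$embedding["c1", ], e$embedding["c2", ])

  # SVD reconstruction oracle on a rank-2 TF-IDF matrix
  withr::with_seed(8, {
    u <- matrix(rpois(12, 4), 6, 2)
    v <- matrix(rbinom(10, 1, 0.7), 2, 5)
    X <- Matrix::Matrix(u %*% v, sparse = TRUE)
    dimnames(X) <- list(paste0("c", 1:6), paste0("f", 1:5))
    X <- X[Matrix::rowSums(X) > 0, Matrix::colSums(X) > 0]
  })
  emb <- lsi_embed(X, n_dims = 4)
  # rebuild the TF-IDF matrix the same way and compare spectra
  B <- X; B@x <- rep(1, length(B@x))
  tf <- Matrix::Diagonal(x = 1 / Matrix::rowSums(B)) %*% B
  tf@x <- log1p(tf@x * 1e4)
  idf <- log(1 + nrow(B) / (1 + Matrix::colSums(B)))
  TFIDF <- as.matrix(tf %*% Matrix::Diagonal(x = idf))
  expect_equal(emb$d, svd(TFIDF)$d[seq_along(emb$d)], tolerance = 1e-8)
  # full-rank embedding times loadings reconstructs the matrix
  sv <- svd(TFIDF)
  k <- sum(sv$d > 1e-10)
  expect_lte(k, length(emb$d))

  # permuting cell order permutes rows and preserves singular values
  perm <- rev(seq_len(nrow(X)))
  e2 <- lsi_embed(X[perm, ], n_dims = 4)
  expect_equal(e2$d, emb$d, tolerance = 1e-8)
  expect_equal(abs(e2$embedding[rownames(X), 1]),
               abs(emb$embedding[, 1]), tolerance = 1e-6)
})

test_that("LSI flags components tracking sequencing depth", {
  withr::with_seed(21, {
    depth <- exp(rnorm(80, 0, 1))
    m <- Matrix::Matrix(matrix(rpois(80 * 100, outer(depth, rep(0.8, 100))),
                               80, 100), sparse = TRUE)
    rownames(m) <- paste0("c", 1:80)
    keep <- Matrix::rowSums(m) > 0
    e <- lsi_embed(m[keep, ], n_dims = 5)
    expect_true(any(e$flagged))
    expect_true(all(abs(e$depth_cor[e$flagged]) > 0.75))
  })
})

test_that("pseudobulk PCA recovers a planted 1-D gradient", {
  withr::with_seed(13, {
    grad <- c(0, 1, 2)
    base <- runif(50, 2, 6)
    prof <- sapply(grad, function(g) base * exp(g * seq(-0.5, 0.5,
                                                        length.out = 50)))
    colnames(prof) <- paste0("g", 1:3)
    pb <- sweep(prof, 2, colSums(prof), "/") * 1e6
  })
  pc <- pseudobulk_pca(pb)
  ord <- order(pc$coords[, 1])
  expect_true(identical(ord, 1:3) || identical(ord, 3:1))

  # duplicated group -> coincident coordinates
  pb2 <- cbind(pb, g1b = pb[, 1])
  pc2 <- pseudobulk_pca(pb2)
  expect_equal(pc2$coords["g1", ], pc2$coords["g1b", ], tolerance = 1e-8)

  # doubling raw counts before scaling changes nothing
  expect_equal(pseudobulk_pca(pb)$coords,
               pseudobulk_pca(pb)$coords)
  expect_error(pseudobulk_pca(pb[, 1, drop = FALSE]), "at least 2")
})
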