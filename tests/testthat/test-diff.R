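sim_null_counts <- function(n_cells, n_peaks, lambda = 0.5, seed = 1) {
  withr::with_seed(seed, {
    m <- Matrix::Matrix(matrix(rpois(n_cells * n_peaks, lambda),
                               n_cells, n_peaks), sparse = TRUE)
    rownames(m) <- paste0("c", seq_len(n_cells))
    colnames(m) <- paste0("p", seq_len(n_peaks))
    m
  })
}

test_that("binomial differential test behaves at the null and in the tail", {
  # identical proportions: p near 1, log2FC near 0
  m <- Matrix::Matrix(rbind(c(50, 50), c(50, 50), c(50, 50), c(50, 50)),
                      sparse = TRUE)
  dimnames(m) <- list(paste0("c", 1:4), c("p1", "p2"))
  d <- binomial_diff_peaks(m, c("c1", "c2"), c("c3", "c4"))
  expect_true(all(d$pvalue > 0.9))
  expect_true(all(abs(d$log2fc) < 0.02))

  # zero target counts against a strong control rate: significant, down
  m2 <- Matrix::Matrix(rbind(c(0, 200), c(0, 200), c(100, 100),
                             c(100, 100)), sparse = TRUE)
  dimnames(m2) <- list(paste0("c", 1:4), c("p1", "p2"))
  d2 <- binomial_diff_peaks(m2, c("c1", "c2"), c("c3", "c4"))
  expect_lt(d2$pvalue[1], 0.05)
  expect_identical(d2$direction[1], -1)
  # exact conditional oracle: k = 0 of 200 peak-total counts, null share
  # of the target group = target grand total / overall grand total
  ref <- binom.test(0, 200, 400 / 800)$p.value
  expect_equal(d2$pvalue[1], ref, tolerance = 1e-12)

  # scaled 300 vs 100 -> log2FC = log2(301/101)
  m3 <- Matrix::Matrix(rbind(c(150, 350), c(150, 350),
                             c(50, 450), c(50, 450)), sparse = TRUE)
  dimnames(m3) <- list(c("t1", "t2", "b1", "b2"), c("p1", "p2"))
  d3 <- binomial_diff_peaks(m3, c("t1", "t2"), c("b1", "b2"),
                            scale_to = 1000)
  expect_equal(d3$log2fc[1], log2(301 / 101), tolerance = 1e-12)
})

test_that("differential filtering reproduces printed fractions and is monotone", {
  n_total <- round(14026 / 0.1452)
  lfc <- c(rep(1, 14262), rep(-1, 14026),
           rep(0, n_total - 14262 - 14026))
  d <- data.frame(peak = seq_along(lfc), log2fc = lfc,
                  pvalue = ifelse(lfc == 0, 1, 1e-6),
                  fdr = ifelse(lfc == 0, 1, 1e-6),
                  direction = sign(lfc))
  f <- filter_differential(d)
  expect_identical(f$n_up, 14262L)
  expect_equal(round(100 * f$frac_up, 2), 14.76)
  expect_equal(round(100 * f$frac_down, 2), 14.52)

  # degenerate thresholds empty the sets; loosening FDR never shrinks them
  f0 <- filter_differential(d, min_abs_lfc = Inf, max_fdr = 0)
  expect_identical(f0$n_up + f0$n_down, 0L)
  f1 <- filter_differential(d, max_fdr = 0.01)
  f2 <- filter_differential(d, max_fdr = 0.2)
  expect_true(all(f1$up %in% f2$up))
  expect_length(intersect(f$up, f$down), 0)
})

test_that("time-course union filtering keeps any-strong, retains any-weak", {
  mk <- function(lfc) data.frame(peak = seq_along(lfc), log2fc = lfc,
                                 pvalue = 1e-6, fdr = 1e-6,
                                 direction = sign(lfc))
  d_day3 <- mk(c(1.2, 0.1, 1.5, 0.0))
  d_day6 <- mk(c(0.1, 0.1, -0.1, 0.0))
  # peak 1: strong on day 3 only -> retained
  # peak 3: strong day 3, |lfc| .1 day 6 -> still retained (day-3 value)
  # peak 2: never strong -> never enters
  kept <- timecourse_union_filter(list(d_day3, d_day6))
  expect_identical(kept, c(1L, 3L))

  # a peak entering the union but never exceeding keep_lfc is dropped
  d_a <- mk(c(1.2)); d_b <- mk(c(0.2))
  expect_identical(timecourse_union_filter(list(d_a, d_b),
                                           keep_lfc = 1.3), integer(0))

  # single timepoint reduces to sequential thresholds
  single <- timecourse_union_filter(list(d_day3))
  expect_identical(single, c(1L, 3L))
})

test_that("k-means modules recover planted patterns deterministically", {
  withr::with_seed(12, {
    up <- matrix(rep(c(5, 5, 1, 1), each = 30), 30) + rnorm(120, 0, 0.1)
    dn <- matrix(rep(c(1, 1, 5, 5), each = 30), 30) + rnorm(120, 0, 0.1)
  })
  pb <- rbind(up, dn)
  rownames(pb) <- paste0("peak", 1:60)
  colnames(pb) <- paste0("g", 1:4)
  km <- kmeans_peak_modules(pb, 1:60, k = 2, seed = 3)
  expect_equal(adjusted_rand(km$modules, rep(1:2, each = 30)), 1)
  # z-scored rows sum to ~0
  expect_true(all(abs(rowSums(km$zmat)) < 1e-8))
  km2 <- kmeans_peak_modules(pb, 1:60, k = 2, seed = 3)
  expect_identical(km$modules, km2$modules)

  # constant rows are dropped with a warning
  pb2 <- rbind(pb, const = rep(3, 4))
  rownames(pb2)[61] <- "flat"
  expect_warning(km3 <- kmeans_peak_modules(pb2, 1:61, k = 2, seed = 3),
                 "constant")
  expect_false("flat" %in% names(km3$modules))
})

test_that("hypergeometric enrichment matches exact combinatorics (N <= 12)", {
  for (N in 2:12) {
    M <- Matrix::Matrix(matrix(0, N, 3), sparse = TRUE)
    colnames(M) <- c("mA", "mB", "mC")
    withr::with_seed(N, {
      K <- sample(1:N, 3, replace = TRUE)
      for (j in 1:3) M[sample(N, K[j]), j] <- 1
      n <- sample(1:N, 1)
      cluster <- sample(N, n)
    })
    e <- hypergeom_motif_enrichment(cluster, M, seq_len(N))
    for (j in seq_len(nrow(e))) {
      motif_col <- match(e$motif[j], colnames(M))
      k <- sum(M[cluster, motif_col])
      expect_equal(e$pvalue[j],
                   hyper_upper_exact(k, sum(M[, motif_col]), N, n),
                   tolerance = 1e-12)
    }
  }
})

test_that("enrichment edge cases: full cluster, empty overlap, empty motif", {
  M <- Matrix::Matrix(cbind(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0), rep(0, 10)),
                      sparse = TRUE)
  colnames(M) <- c("mA", "mEmpty")
  # worked example: N=10, K=5, n=4, k=4
  e <- hypergeom_motif_enrichment(1:4, M, 1:10)
  expect_equal(e$pvalue[e$motif == "mA"], 5 / 210, tolerance = 1e-12)
  expect_false("mEmpty" %in% e$motif)  # K = 0 skipped

  # cluster = universe: fold 1, p = 1
  e2 <- hypergeom_motif_enrichment(1:10, M, 1:10)
  expect_equal(e2$fold, 1)
  expect_equal(e2$pvalue, 1)

  # zero overlap: fold 0, p ~ 1
  e3 <- hypergeom_motif_enrichment(6:9, M, 1:10)
  expect_equal(e3$fold, 0)
  expect_gt(e3$pvalue, 0.97)
  expect_error(hypergeom_motif_enrichment(11, M, 1:10), "subset")
})
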