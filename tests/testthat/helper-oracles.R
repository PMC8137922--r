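# Independent oracles and small fixture builders shared across tests.

# Exhaustive Hamming scan over a whitelist: the reference for 1-mismatch
# barcode resolution. Returns the whitelist index, NA if unmatched or
# ambiguous (exact matches always win).
hamming_scan <- function(whitelist, query) {
  qs <- strsplit(query, "")[[1]]
  d <- vapply(strsplit(whitelist, ""), function(w) {
    if (length(w) != length(qs)) return(Inf)
    sum(w != qs)
  }, numeric(1))
  if (any(d == 0)) return(which(d == 0)[1])
  hits <- which(d == 1)
  if (length(hits) == 1) hits else NA_integer_
}

# Brute-force motif deviations: explicit loops over cells, motifs and
# background iterations, straight from the definition.
brute_deviations <- function(counts, motifs, backgrounds) {
  X <- as.matrix(counts)
  M <- as.matrix(motifs) != 0
  Ti <- rowSums(X)
  f <- colSums(X) / sum(X)
  n_cells <- nrow(X); n_motifs <- ncol(M); n_iter <- ncol(backgrounds)
  dev <- z <- raw <- matrix(NA_real_, n_cells, n_motifs)
  for (m in seq_len(n_motifs)) {
    S <- which(M[, m])
    if (!length(S)) next
    for (i in seq_len(n_cells)) {
      o <- sum(X[i, S]); e <- Ti[i] * sum(f[S])
      if (e == 0) next
      Y <- (o - e) / e
      Yb <- numeric(n_iter)
      for (b in seq_len(n_iter)) {
        Sb <- backgrounds[S, b]
        ob <- sum(X[i, Sb]); eb <- Ti[i] * sum(f[Sb])
        Yb[b] <- (ob - eb) / eb
      }
      raw[i, m] <- Y
      dev[i, m] <- Y - mean(Yb)
      z[i, m] <- if (stats::sd(Yb) == 0) NA_real_ else
        (Y - mean(Yb)) / stats::sd(Yb)
    }
  }
  list(raw = raw, deviations = dev, z = z)
}

# Exact hypergeometric upper tail from combinatorics only.
hyper_upper_exact <- function(k, K, N, n) {
  ks <- max(0, n - (N - K)):min(K, n)
  probs <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(probs[ks >= k])
}

# Tiny deterministic sgRNA fixture: whitelist, library, count matrix.
tiny_library <- function() {
  spacer_library(data.frame(
    spacer = c("ACGTACGTACGTACGTACGT", "TGCATGCATGCATGCATGCA",
               "GGGGCCCCAAAATTTTACGT", "AATTCCGGAATTCCGGAATT"),
    sgrna = c("sgA-1", "sgA-2", "sgB-1", "sgNT-1"),
    target = c("A", "A", "B", "NT"),
    stringsAsFactors = FALSE))
}

# Separated two-population tile counts for purity tests: target cells have
# a `1 + shift`-fold elevated rate on the first block of tiles. Baselines
# are sparse (0.2 per tile) so presence/absence carries the signal, as in
# real tile matrices.
sim_two_pop_tiles <- function(n_target, n_nt, n_tiles = 120,
                              shift_tiles = 40, shift = 5, seed = 1) {
  withr::with_seed(seed, {
    base <- 0.2
    lam_t <- c(rep(base * (1 + shift), shift_tiles),
               rep(base, n_tiles - shift_tiles))
    lam_n <- rep(base, n_tiles)
    Xt <- matrix(rpois(n_target * n_tiles, rep(lam_t, each = n_target)),
                 nrow = n_target, ncol = n_tiles)
    Xn <- matrix(rpois(n_nt * n_tiles, rep(lam_n, each = n_nt)),
                 nrow = n_nt, ncol = n_tiles)
    X <- rbind(Xt, Xn)
    rownames(X) <- c(if (n_target > 0) paste0("T", seq_len(n_target)),
                     if (n_nt > 0) paste0("N", seq_len(n_nt)))
    colnames(X) <- paste0("tile", seq_len(n_tiles))
    Matrix::Matrix(X, sparse = TRUE)
  })
}

# Assignment table for a set of cells with given targets/sgrnas.
make_assignment <- function(cells, targets, sgrnas = NULL) {
  if (is.null(sgrnas)) sgrnas <- paste0("sg", targets, "-1")
  out <- data.frame(cell = cells, sgrna = sgrnas, target = targets,
                    n_counts = 100, specificity = 1, assigned = TRUE,
                    reason = "assigned", stringsAsFactors = FALSE)
  class(out) <- c("assignment_table", "data.frame")
  out
}

adjusted_rand <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}
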