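#' Per-peak bias covariates
#'
#' The two covariates used to match background peaks: GC fraction and
#' log1p mean accessibility across cells.
#'
#' @param counts Sparse cells x peaks matrix.
#' @param gc Numeric vector of per-peak GC fractions in `[0, 1]`, one per
#'   peak.
#' @return A data.frame: `gc`, `log1p_mean`.
#' @export
compute_bias <- function(counts, gc) {
  if (length(gc) != ncol(counts)) {
    stop("gc must supply one value per peak (", ncol(counts), ")")
  }
  if (anyNA(gc) || any(gc < 0) || any(gc > 1)) {
    stop("gc fractions must lie in [0, 1]")
  }
  data.frame(gc = gc,
             log1p_mean = log1p(Matrix::colSums(counts) / nrow(counts)))
}

#' Sample bias-matched background peak sets
#'
#' Standardizes both bias covariates, grids peaks into an
#' `n_bins x n_bins` lattice, and for each peak draws `n_iterations`
#' background peaks uniformly (with replacement) from its own bin, so the
#' null shares the peak's GC content and mean accessibility. A covariate
#' with zero variance collapses to a single bin on that axis.
#'
#' @param bias Output of [compute_bias()].
#' @param n_iterations Background draws per peak (default 50).
#' @param n_bins Bins per covariate axis (default 25).
#' @param seed Integer seed; sampling is deterministic given the seed.
#' @return An integer peaks x n_iterations matrix of background peak
#'   indices.
#' @export
sample_background_peaks <- function(bias, n_iterations = 50L, n_bins = 25L,
                                    seed = 1L) {
  std_bin <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(rep(1L, length(x)))
    z <- (x - mean(x)) / s
    findInterval(z, seq(min(z), max(z), length.out = n_bins + 1L),
                 rightmost.closed = TRUE, all.inside = TRUE)
  }
  b1 <- std_bin(bias$gc)
  b2 <- std_bin(bias$log1p_mean)
  bin <- b1 + n_bins * (b2 - 1L)
  members <- split(seq_len(nrow(bias)), bin)
  withr::with_seed(seed, {
    out <- matrix(NA_integer_, nrow(bias), n_iterations)
    for (mem in members) {
      out[mem, ] <- sample(mem, length(mem) * n_iterations, replace = TRUE)
    }
    out
  })
}

#' Bias-corrected motif accessibility deviations
#'
#' For each cell *i* and motif *m* with peak set *S*: observed in-motif
#' counts `o = sum_{p in S} X[i, p]`, expectation `e = T_i * sum f_p` with
#' `f_p` the peak's fraction of all counts and `T_i` the cell total, and
#' raw deviation `Y = (o - e) / e`. Each background iteration evaluates the
#' same quantity on the bias-matched background peak set; the corrected
#' deviation subtracts the background mean and the z-score divides by the
#' background standard deviation.
#'
#' @param counts Sparse cells x peaks matrix (cells must have positive
#'   totals).
#' @param motifs Peaks x motifs 0/1 match matrix (or the list returned by
#'   [read_motif_matches()]).
#' @param backgrounds Output of [sample_background_peaks()].
#' @return A list of class `deviation_result`: `deviations` (corrected,
#'   cells x motifs), `z`, `raw`, `variability` (per-motif sd of z across
#'   cells), `flagged` (motifs with no matching peaks or degenerate
#'   background).
#' @export
compute_deviations <- function(counts, motifs, backgrounds) {
  if (is.list(motifs) && !is.null(motifs$matches)) motifs <- motifs$matches
  M <- methods::as(Matrix::Matrix(motifs, sparse = TRUE), "CsparseMatrix")
  M@x[M@x != 0] <- 1
  X <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  if (nrow(M) != ncol(X)) {
    stop("motif match matrix rows (", nrow(M),
         ") must equal count matrix peaks (", ncol(X), ")")
  }
  if (nrow(backgrounds) != ncol(X)) {
    stop("background sets must have one row per peak")
  }
  Ti <- Matrix::rowSums(X)
  if (any(Ti == 0)) stop("cell(s) with zero counts; filter before deviations")
  f <- Matrix::colSums(X) / sum(Ti)
  n_iter <- ncol(backgrounds)
  dev_of <- function(Mm) {
    fm <- as.vector(Matrix::crossprod(Mm, f))
    O <- as.matrix(X %*% Mm)
    E <- outer(Ti, fm)
    Y <- (O - E) / E                       # e = 0 -> NaN, flagged below
    Y[, fm == 0] <- NA_real_
    Y
  }
  Y <- dev_of(M)
  Tm <- methods::as(M, "TsparseMatrix")
  s1 <- matrix(0, nrow(X), ncol(M))
  s2 <- matrix(0, nrow(X), ncol(M))
  for (b in seq_len(n_iter)) {
    idx <- backgrounds[, b]
    Mb <- Matrix::sparseMatrix(i = idx[Tm@i + 1L], j = Tm@j + 1L, x = 1,
                               dims = dim(M))
    Yb <- dev_of(Mb)
    s1 <- s1 + Yb
    s2 <- s2 + Yb * Yb
  }
  mean_b <- s1 / n_iter
  var_b <- pmax(s2 - n_iter * mean_b^2, 0) / (n_iter - 1)
  sd_b <- sqrt(var_b)
  corrected <- Y - mean_b
  z <- corrected / sd_b
  z[sd_b == 0] <- NA_real_
  no_peak <- Matrix::colSums(M) == 0
  corrected[, no_peak] <- NA_real_
  z[, no_peak] <- NA_real_
  motif_ids <- colnames(M)
  if (is.null(motif_ids)) motif_ids <- paste0("motif", seq_len(ncol(M)))
  dimnames(corrected) <- dimnames(z) <- list(rownames(X), motif_ids)
  variability <- apply(z, 2L, stats::sd, na.rm = TRUE)
  flagged <- no_peak | apply(is.na(z), 2L, all)
  names(flagged) <- motif_ids
  structure(list(deviations = corrected, z = z, raw = Y,
                 variability = variability, flagged = flagged,
                 n_background = n_iter),
            class = "deviation_result")
}

#' @export
print.deviation_result <- function(x, ...) {
  cat("deviation_result:", nrow(x$deviations), "cells x",
      ncol(x$deviations), "motifs (", x$n_background,
      "background iterations;", sum(x$flagged), "motif(s) flagged )\n")
  invisible(x)
}

#' Mean deviations per perturbation group
#'
#' Arithmetic mean of per-cell deviations over the cells assigned to each
#' sgRNA or target. NA-flagged motifs propagate rather than being zeroed.
#'
#' @param dev A [compute_deviations()] result (or a bare cells x motifs
#'   matrix).
#' @param assignment An [assign_cells()] table (assigned rows are used).
#' @param level Group by `"target"` (default) or `"sgrna"`.
#' @param use Average `"deviations"` (corrected; default) or `"z"`.
#' @return A groups x motifs matrix of means.
#' @export
target_mean_deviations <- function(dev, assignment,
                                   level = c("target", "sgrna"),
                                   use = c("deviations", "z")) {
  level <- match.arg(level)
  use <- match.arg(use)
  mat <- if (inherits(dev, "deviation_result")) dev[[use]] else dev
  tab <- assignment[assignment$assigned, , drop = FALSE]
  miss <- setdiff(tab$cell, rownames(mat))
  if (length(miss)) {
    stop("assigned cell(s) absent from the deviation matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  grp <- tab[[level]]
  levs <- sort(unique(grp))
  sub <- mat[tab$cell, , drop = FALSE]
  out <- rowsum(sub, grp, na.rm = FALSE) / as.vector(table(factor(grp, levs)))
  out[levs, , drop = FALSE]
}
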