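#' Peak-level differential accessibility (binomial test)
#'
#' For each peak, the summed target counts `k` and control counts `m` are
#' compared with a two-sided exact binomial test conditional on the peak
#' total: `k ~ Binomial(k + m, n / (n + b))`, where `n` and `b` are the
#' target and control grand totals. Conditioning on the total is the
#' standard exact two-sample Poisson comparison and keeps the test
#' calibrated when both groups are estimated from data. Fold changes come
#' from pseudocount-1 pseudobulk profiles scaled to `scale_to`; p-values
#' are Benjamini-Hochberg corrected across peaks.
#'
#' @param counts Sparse cells x peaks matrix.
#' @param target_cells,background_cells Row-name vectors (>= 2 cells each,
#'   positive totals).
#' @param scale_to Pseudobulk scale (default 1e6).
#' @return A data.frame of class `diff_result`: `peak`, `log2fc`,
#'   `pvalue`, `fdr`, `direction`.
#' @export
binomial_diff_peaks <- function(counts, target_cells, background_cells,
                                scale_to = 1e6) {
  if (length(target_cells) < 2L || length(background_cells) < 2L) {
    stop("need at least 2 cells per group")
  }
  kv <- Matrix::colSums(counts[target_cells, , drop = FALSE])
  bg <- Matrix::colSums(counts[background_cells, , drop = FALSE])
  n <- sum(kv)
  bg_tot <- sum(bg)
  if (bg_tot == 0) stop("background group has zero total counts")
  if (n == 0) stop("target group has zero total counts")
  n_peaks <- ncol(counts)
  p_null <- n / (n + bg_tot)
  pv <- vapply(seq_len(n_peaks), function(p) {
    tot <- kv[p] + bg[p]
    if (tot == 0) return(1)
    stats::binom.test(kv[p], tot, p_null)$p.value
  }, numeric(1))
  st <- kv * scale_to / n
  sb <- bg * scale_to / bg_tot
  lfc <- log2((st + 1) / (sb + 1))
  peak_ids <- colnames(counts)
  if (is.null(peak_ids)) peak_ids <- paste0("peak", seq_len(n_peaks))
  out <- data.frame(peak = peak_ids, log2fc = unname(lfc),
                    pvalue = pv, fdr = stats::p.adjust(pv, method = "BH"),
                    direction = sign(unname(lfc)),
                    stringsAsFactors = FALSE)
  class(out) <- c("diff_result", "data.frame")
  out
}

#' Threshold a differential result into up/down peak sets
#'
#' @param diff A `diff_result` (see [binomial_diff_peaks()]).
#' @param min_abs_lfc Fold-change floor (default 0.5).
#' @param max_fdr FDR ceiling, strict (default 0.1 per the pipeline
#'   default; 0.05 reproduces the stricter figure threshold).
#' @return A list: `up`, `down` (peak index vectors), `n_up`, `n_down`,
#'   `n_tested`, `frac_up`, `frac_down`.
#' @export
filter_differential <- function(diff, min_abs_lfc = 0.5, max_fdr = 0.1) {
  up <- which(diff$log2fc > min_abs_lfc & diff$fdr < max_fdr)
  down <- which(diff$log2fc < -min_abs_lfc & diff$fdr < max_fdr)
  n <- nrow(diff)
  list(up = up, down = down, n_up = length(up), n_down = length(down),
       n_tested = n, frac_up = length(up) / n, frac_down = length(down) / n)
}

#' Union filter for a time-course of differential results
#'
#' Takes the union of peaks strongly differential
#' (`|log2FC| > union_lfc`, FDR below `max_fdr`) at any timepoint, then
#' keeps those with `|log2FC| > keep_lfc` in at least one timepoint.
#'
#' @param diffs List of `diff_result` objects over the same peak universe,
#'   one per timepoint.
#' @param union_lfc Entry threshold (default 1).
#' @param keep_lfc Retention threshold (default 0.25).
#' @param max_fdr FDR ceiling at the union stage (default 0.1).
#' @return Sorted integer vector of retained peak indices.
#' @export
timecourse_union_filter <- function(diffs, union_lfc = 1, keep_lfc = 0.25,
                                    max_fdr = 0.1) {
  stopifnot(length(diffs) >= 1L)
  lfc <- vapply(diffs, `[[`, numeric(nrow(diffs[[1L]])), "log2fc")
  lfc <- matrix(lfc, nrow = nrow(diffs[[1L]]))
  fdr <- matrix(vapply(diffs, `[[`, numeric(nrow(diffs[[1L]])), "fdr"),
                nrow = nrow(diffs[[1L]]))
  entered <- which(rowSums(abs(lfc) > union_lfc & fdr < max_fdr) > 0L)
  kept <- entered[rowSums(abs(lfc[entered, , drop = FALSE]) > keep_lfc) > 0L]
  sort(kept)
}

#' k-means modules of differential peaks
#'
#' Rows are `log2(scaled pseudobulk + 1)` peak profiles z-scored across
#' groups; constant rows (z undefined) are dropped with a warning. k-means
#' runs with 10 restarts under a fixed seed and the best within-cluster
#' sum of squares is kept.
#'
#' @param pb Features x groups pseudobulk matrix.
#' @param peak_idx Peak (row) indices to cluster.
#' @param k Number of modules.
#' @param seed Seed for the restarts.
#' @return A list: `modules` (named integer vector over retained peaks),
#'   `zmat` (z-scored matrix), `dropped` (constant rows removed).
#' @export
kmeans_peak_modules <- function(pb, peak_idx, k, seed = 1L) {
  if (length(peak_idx) < k) stop("fewer peaks than modules requested")
  X <- log2(pb[peak_idx, , drop = FALSE] + 1)
  mu <- rowMeans(X)
  s <- apply(X, 1L, stats::sd)
  const <- s == 0
  if (any(const)) {
    warning("dropped ", sum(const), " constant peak row(s) before z-scoring")
  }
  Z <- (X[!const, , drop = FALSE] - mu[!const]) / s[!const]
  if (nrow(Z) < k) stop("too few non-constant peaks for k = ", k)
  km <- withr::with_seed(seed,
                         stats::kmeans(Z, centers = k, nstart = 10L,
                                       iter.max = 100L))
  modules <- km$cluster
  names(modules) <- rownames(Z)
  list(modules = modules, zmat = Z, dropped = which(const))
}

#' Hypergeometric motif enrichment in a peak cluster
#'
#' Upper-tail hypergeometric test of the overlap between a peak cluster
#' and each motif's peak set against the full tested-peak universe;
#' Benjamini-Hochberg corrected across motifs. Motifs with no peaks in the
#' universe are skipped.
#'
#' @param cluster_peaks Peak indices of the cluster (subset of
#'   `universe`).
#' @param motifs Peaks x motifs 0/1 match matrix (rows indexed like the
#'   peak universe coordinates).
#' @param universe Peak indices of the background set (all tested peaks).
#' @return A data.frame: `motif`, `overlap`, `cluster_size`,
#'   `motif_size`, `universe_size`, `fold`, `pvalue`, `fdr`.
#' @export
hypergeom_motif_enrichment <- function(cluster_peaks, motifs, universe) {
  if (!all(cluster_peaks %in% universe)) {
    stop("cluster peaks must be a subset of the universe")
  }
  if (is.list(motifs) && !is.null(motifs$matches)) motifs <- motifs$matches
  M <- methods::as(Matrix::Matrix(motifs, sparse = TRUE), "CsparseMatrix")
  M@x[M@x != 0] <- 1
  N <- length(universe)
  n <- length(cluster_peaks)
  Ku <- Matrix::colSums(M[universe, , drop = FALSE])
  kc <- Matrix::colSums(M[cluster_peaks, , drop = FALSE])
  keep <- which(Ku > 0)
  p <- stats::phyper(kc[keep] - 1, Ku[keep], N - Ku[keep], n,
                     lower.tail = FALSE)
  fold <- (kc[keep] / n) / (Ku[keep] / N)
  ids <- colnames(M)
  if (is.null(ids)) ids <- paste0("motif", seq_len(ncol(M)))
  out <- data.frame(motif = ids[keep], overlap = unname(kc[keep]),
                    cluster_size = n, motif_size = unname(Ku[keep]),
                    universe_size = N, fold = unname(fold),
                    pvalue = unname(p),
                    fdr = stats::p.adjust(unname(p), method = "BH"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
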