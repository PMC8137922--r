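#' TF-TF deviation-score correlation matrix
#'
#' Pairwise correlation of motif deviations across a cell set. Motifs
#' without variance across the cells have undefined correlations and are
#' flagged (their rows/columns are NA except the unit diagonal).
#'
#' @param dev A `deviation_result` or a cells x motifs matrix of
#'   (corrected) deviations.
#' @param cells Row names of the cells to use (>= 3).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A symmetric motifs x motifs correlation matrix with attribute
#'   `flagged` (logical per motif).
#' @export
tf_tf_correlation <- function(dev, cells, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  mat <- if (inherits(dev, "deviation_result")) dev$deviations else dev
  if (length(cells) < 3L) stop("need at least 3 cells for correlations")
  sub <- mat[cells, , drop = FALSE]
  r <- suppressWarnings(stats::cor(sub, method = method))
  flagged <- apply(sub, 2L, function(x) {
    !all(is.finite(x)) || stats::sd(x) == 0
  })
  diag(r) <- 1
  attr(r, "flagged") <- flagged
  r
}

#' Differential TF-TF correlation matrix
#'
#' Elementwise difference of the TF-TF correlation matrices computed over
#' targeting and over non-targeting cells: positive entries are motif
#' pairs co-varying more strongly under the perturbation. Symmetric, zero
#' diagonal, entries in [-2, 2].
#'
#' @param dev A `deviation_result` or deviations matrix.
#' @param target_cells,nt_cells Cell sets (>= 3 each).
#' @param method Correlation estimator, passed through.
#' @return Motifs x motifs matrix of class `diff_correlation` with
#'   attribute `flagged`.
#' @export
diff_correlation <- function(dev, target_cells, nt_cells,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  rt <- tf_tf_correlation(dev, target_cells, method)
  rn <- tf_tf_correlation(dev, nt_cells, method)
  delta <- rt - rn
  diag(delta) <- 0
  attr(delta, "flagged") <- attr(rt, "flagged") | attr(rn, "flagged")
  class(delta) <- c("diff_correlation", class(delta))
  delta
}

#' Cluster a differential correlation matrix into modules
#'
#' Complete-linkage hierarchical clustering on Euclidean distances between
#' the rows of the differential correlation matrix, cut into `k` modules.
#' Motifs with undefined entries are excluded and reported.
#'
#' @param delta A [diff_correlation()] matrix.
#' @param k Number of modules (default 5).
#' @return Named integer vector of module labels (1..k) over the retained
#'   motifs, with attribute `excluded` (motif names dropped for undefined
#'   values) and attribute `hclust` (the tree).
#' @export
cluster_modules <- function(delta, k = 5L) {
  d <- unclass(delta)
  ok <- apply(is.finite(d), 1L, all)
  if (sum(ok) < k) stop("fewer than k motifs with defined values")
  sub <- d[ok, ok, drop = FALSE]
  hc <- stats::hclust(stats::dist(sub), method = "complete")
  labels <- stats::cutree(hc, k = k)
  attr(labels, "excluded") <- rownames(d)[!ok]
  attr(labels, "hclust") <- hc
  labels
}
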