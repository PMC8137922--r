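# Tn5 insertion sites of a fragment are its two ends: positions start and
# end - 1 (coordinates already offset-corrected upstream).
.insertion_sites <- function(fragments) {
  data.frame(chrom = rep(fragments$chrom, 2L),
             pos = c(fragments$start, fragments$end - 1L),
             barcode = rep(fragments$barcode, 2L),
             stringsAsFactors = FALSE)
}

#' Build a genome-wide tile insertion-count matrix
#'
#' Counts Tn5 insertion sites (two per fragment) into fixed-width genome
#' tiles; tile index within a chromosome is `floor(position / tile_size)`.
#' Insertions beyond the chromosome end are clipped to the last base with a
#' warning.
#'
#' @param fragments Fragment data.frame (see [read_fragments()]).
#' @param chrom_sizes Named integer vector (or two-column data.frame) of
#'   chromosome sizes covering every fragment chromosome.
#' @param tile_size Tile width in bp (default 500).
#' @param cells Optional fixed cell ordering; defaults to the sorted
#'   barcodes present.
#' @return A sparse cells x tiles `dgCMatrix`; attribute `tiles` holds the
#'   tile coordinates (`chrom`, `start`, `end`).
#' @export
make_tile_matrix <- function(fragments, chrom_sizes, tile_size = 500L,
                             cells = NULL) {
  if (is.data.frame(chrom_sizes)) {
    chrom_sizes <- stats::setNames(as.integer(chrom_sizes[[2L]]),
                                   chrom_sizes[[1L]])
  }
  missing <- setdiff(unique(fragments$chrom), names(chrom_sizes))
  if (length(missing)) {
    stop("chrom sizes missing for: ", paste(missing, collapse = ", "))
  }
  ins <- .insertion_sites(fragments)
  sizes <- chrom_sizes[ins$chrom]
  over <- ins$pos >= sizes
  if (any(over)) {
    warning("clipped ", sum(over), " insertion(s) beyond chromosome end")
    ins$pos[over] <- sizes[over] - 1L
  }
  ins$pos[ins$pos < 0L] <- 0L
  n_tiles <- ceiling(chrom_sizes / tile_size)
  offset <- stats::setNames(c(0L, cumsum(n_tiles))[seq_along(n_tiles)],
                            names(n_tiles))
  tile <- offset[ins$chrom] + ins$pos %/% tile_size + 1L
  if (is.null(cells)) cells <- sort(unique(fragments$barcode))
  ci <- match(ins$barcode, cells)
  keep <- !is.na(ci)
  tile_chrom <- rep(names(n_tiles), n_tiles)
  tile_start <- unlist(lapply(n_tiles, function(k) (seq_len(k) - 1L)),
                       use.names = FALSE) * tile_size
  tile_names <- paste0(tile_chrom, ":", tile_start, "-",
                       tile_start + tile_size)
  m <- Matrix::sparseMatrix(i = ci[keep], j = tile[keep], x = 1,
                            dims = c(length(cells), sum(n_tiles)),
                            dimnames = list(cells, tile_names))
  attr(m, "tiles") <- data.frame(chrom = tile_chrom, start = tile_start,
                                 end = tile_start + as.integer(tile_size),
                                 stringsAsFactors = FALSE)
  m
}

.check_disjoint_sorted <- function(peaks) {
  for (ch in unique(peaks$chrom)) {
    p <- peaks[peaks$chrom == ch, , drop = FALSE]
    if (is.unsorted(p$start)) stop("peaks must be sorted by start within ",
                                   ch)
    if (nrow(p) > 1L && any(p$start[-1L] < p$end[-nrow(p)])) {
      stop("overlapping peaks on ", ch,
           "; a non-overlapping peak set is required")
    }
  }
  invisible(TRUE)
}

#' Build a peak insertion-count matrix
#'
#' Entry (cell, peak) is the number of Tn5 insertion sites of that cell
#' falling inside the half-open peak interval `[start, end)`.
#'
#' @param fragments Fragment data.frame.
#' @param peaks Interval data.frame (`chrom`, `start`, `end`), sorted and
#'   non-overlapping within each chromosome (error otherwise).
#' @param cells Optional fixed cell ordering.
#' @return A sparse cells x peaks `dgCMatrix` with peak names
#'   `chrom:start-end`.
#' @export
make_peak_matrix <- function(fragments, peaks, cells = NULL) {
  .check_disjoint_sorted(peaks)
  ins <- .insertion_sites(fragments)
  if (is.null(cells)) cells <- sort(unique(fragments$barcode))
  peak_id <- rep(NA_integer_, nrow(ins))
  peaks$.row <- seq_len(nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    p <- peaks[peaks$chrom == ch, , drop = FALSE]
    sel <- which(ins$chrom == ch)
    if (!length(sel)) next
    fi <- findInterval(ins$pos[sel], p$start)
    hit <- fi >= 1L & ins$pos[sel] < p$end[pmax(fi, 1L)]
    peak_id[sel[hit]] <- p$.row[fi[hit]]
  }
  ci <- match(ins$barcode, cells)
  keep <- !is.na(peak_id) & !is.na(ci)
  Matrix::sparseMatrix(i = ci[keep], j = peak_id[keep], x = 1,
                       dims = c(length(cells), nrow(peaks)),
                       dimnames = list(cells,
                                       paste0(peaks$chrom, ":", peaks$start,
                                              "-", peaks$end)))
}

#' Per-cell quality-control metrics
#'
#' Computes, per cell barcode, the fragment count and a flank-normalized
#' TSS enrichment: mean per-bp insertion density within +/- 50 bp of the
#' nearest transcription start site, divided by the mean per-bp density in
#' the two distal flanks 1901-2000 bp away (one pseudocount added to the
#' flank sum so the ratio is defined for empty flanks).
#'
#' @param fragments Fragment data.frame.
#' @param tss Data.frame of TSS sites (`chrom`, `start`; single-bp
#'   positions, strand-independent).
#' @return A data.frame: `cell`, `n_fragments`, `tss_enrichment`.
#' @export
compute_qc <- function(fragments, tss) {
  cells <- sort(unique(fragments$barcode))
  n_frag <- as.integer(table(factor(fragments$barcode, levels = cells)))
  ins <- .insertion_sites(fragments)
  ci <- match(ins$barcode, cells)
  center <- flank <- integer(length(cells))
  for (ch in unique(tss$chrom)) {
    sites <- sort(tss$start[tss$chrom == ch])
    sel <- which(ins$chrom == ch)
    if (!length(sel) || !length(sites)) next
    pos <- ins$pos[sel]
    j <- findInterval(pos, sites)
    d_lo <- ifelse(j >= 1L, pos - sites[pmax(j, 1L)], Inf)
    d_hi <- ifelse(j < length(sites), sites[pmin(j + 1L, length(sites))] - pos,
                   Inf)
    d <- pmin(d_lo, d_hi)
    in_center <- d <= 50
    in_flank <- d >= 1901 & d <= 2000
    center <- center + as.integer(
      tabulate(ci[sel][in_center], nbins = length(cells)))
    flank <- flank + as.integer(
      tabulate(ci[sel][in_flank], nbins = length(cells)))
  }
  enr <- (center / 101) / ((flank + 1) / 200)
  data.frame(cell = cells, n_fragments = n_frag, tss_enrichment = enr,
             stringsAsFactors = FALSE)
}

#' Filter cells on QC thresholds
#'
#' Keeps cells meeting both the TSS-enrichment and fragment-count floors.
#'
#' @param qc Output of [compute_qc()].
#' @param min_tss Minimum TSS enrichment (default 4).
#' @param min_frags Minimum fragments per cell (default 1000).
#' @return Character vector of kept cell barcodes.
#' @export
filter_cells <- function(qc, min_tss = 4, min_frags = 1000L) {
  qc$cell[qc$tss_enrichment >= min_tss & qc$n_fragments >= min_frags]
}

#' Pseudobulk group profiles
#'
#' Sums counts over the cells of each group and rescales each group column
#' to a fixed total, so profiles are comparable across groups of different
#' size and depth.
#'
#' @param counts Sparse cells x features matrix.
#' @param groups Named character vector mapping cell id to group (every
#'   named cell must exist in `counts`).
#' @param scale_to Column target sum (default 1e6).
#' @return A dense features x groups matrix; each non-empty group column
#'   sums to `scale_to`.
#' @export
pseudobulk <- function(counts, groups, scale_to = 1e6) {
  if (is.null(names(groups))) stop("groups must be a named vector (by cell)")
  miss <- setdiff(names(groups), rownames(counts))
  if (length(miss)) {
    stop("grouped cell(s) absent from the count matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  levs <- sort(unique(groups))
  ci <- match(names(groups), rownames(counts))
  G <- Matrix::sparseMatrix(i = match(groups, levs), j = ci, x = 1,
                            dims = c(length(levs), nrow(counts)))
  sums <- as.matrix(G %*% counts)          # groups x features
  tot <- rowSums(sums)
  if (any(tot == 0)) {
    warning("empty/all-zero group(s): ",
            paste(levs[tot == 0], collapse = ", "))
  }
  scaled <- sums * ifelse(tot > 0, scale_to / tot, 0)
  out <- t(scaled)
  dimnames(out) <- list(colnames(counts), levs)
  out
}

#' Latent semantic indexing of an accessibility matrix
#'
#' Binarizes the counts, applies TF-IDF weighting (term frequency scaled as
#' `log(1 + tf * 1e4)`; inverse document frequency
#' `log(1 + n_cells / (1 + feature frequency))`), and embeds cells with a
#' rank-`n_dims` truncated SVD. Components whose absolute correlation with
#' log10 cell depth exceeds `depth_cor_threshold` are flagged (and
#' optionally dropped). Features never observed are removed before IDF.
#'
#' @param counts Sparse cells x features matrix (>= 2 cells with signal).
#' @param n_dims Embedding dimensionality (default 30; reduced when the
#'   matrix cannot support it).
#' @param depth_cor_threshold Flagging threshold (default 0.75).
#' @param drop_flagged Drop depth-correlated components (default `FALSE`;
#'   flagging alone keeps the decision reproducible).
#' @return A list of class `lsi_embedding`: `embedding` (cells x d),
#'   `d` (singular values), `features` (ids used), `depth_cor`, `flagged`.
#' @export
lsi_embed <- function(counts, n_dims = 30L, depth_cor_threshold = 0.75,
                      drop_flagged = FALSE) {
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  if (nrow(m) < 2L) stop("LSI needs at least 2 cells")
  depth <- Matrix::rowSums(m)
  if (any(depth == 0)) stop("cell(s) with zero counts cannot be embedded")
  b <- m
  b@x <- rep(1, length(b@x))
  ff <- Matrix::colSums(b)
  keep <- which(ff > 0)
  b <- b[, keep, drop = FALSE]
  ff <- ff[keep]
  tf <- Matrix::Diagonal(x = 1 / Matrix::rowSums(b)) %*% b
  tf@x <- log1p(tf@x * 1e4)
  idf <- log(1 + nrow(b) / (1 + ff))
  X <- tf %*% Matrix::Diagonal(x = idf)
  k <- min(n_dims, nrow(X) - 1L, ncol(X) - 1L)
  if (k < 1L) stop("matrix too small for any LSI component")
  if (as.double(nrow(X)) * ncol(X) <= 4e6) {
    sv <- svd(as.matrix(X), nu = k, nv = k)
    u <- sv$u; d <- sv$d[seq_len(k)]; v <- sv$v
  } else {
    # deterministic start vector: no RNG dependence across reruns
    init <- sin(seq_len(ncol(X)))
    sv <- irlba::irlba(X, nv = k, v = init / sqrt(sum(init^2)))
    u <- sv$u; d <- sv$d; v <- sv$v
  }
  # standardize component signs on the feature loadings
  sgn <- vapply(seq_len(k), function(j) {
    s <- sign(v[which.max(abs(v[, j])), j]); if (s == 0) 1 else s
  }, numeric(1))
  emb <- u %*% diag(d * sgn, nrow = k)
  rownames(emb) <- rownames(m)
  colnames(emb) <- paste0("LSI", seq_len(k))
  dc <- suppressWarnings(as.vector(stats::cor(emb, log10(depth))))
  dc[is.na(dc)] <- 0
  flagged <- abs(dc) > depth_cor_threshold
  if (drop_flagged && any(flagged) && !all(flagged)) {
    emb <- emb[, !flagged, drop = FALSE]
    d <- d[!flagged]
  }
  structure(list(embedding = emb, d = d,
                 features = colnames(m)[keep],
                 depth_cor = dc, flagged = flagged),
            class = "lsi_embedding")
}

#' @export
print.lsi_embedding <- function(x, ...) {
  cat("lsi_embedding:", nrow(x$embedding), "cells x", ncol(x$embedding),
      "dims;", sum(x$flagged), "depth-correlated component(s) flagged\n")
  invisible(x)
}

#' Principal components of pseudobulk profiles
#'
#' PCA of log2(scaled + 1) pseudobulk profiles, centred per feature; used
#' to review non-targeting guides for outliers (any exclusion itself is a
#' configuration decision, not automatic).
#'
#' @param pb Features x groups pseudobulk matrix (see [pseudobulk()]).
#' @param n_dims Number of components (default all).
#' @return A list: `coords` (groups x components), `sdev`.
#' @export
pseudobulk_pca <- function(pb, n_dims = NULL) {
  if (ncol(pb) < 2L) stop("pseudobulk PCA needs at least 2 groups")
  X <- log2(pb + 1)
  Xc <- X - rowMeans(X)
  sv <- svd(t(Xc))
  k <- min(if (is.null(n_dims)) ncol(pb) else n_dims, length(sv$d))
  coords <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], nrow = k)
  rownames(coords) <- colnames(pb)
  colnames(coords) <- paste0("PC", seq_len(k))
  list(coords = coords, sdev = sv$d / sqrt(max(1, ncol(pb) - 1)))
}
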