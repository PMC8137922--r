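#' Read a sparse count matrix from MatrixMarket files
#'
#' Loads a MatrixMarket coordinate matrix plus sidecar row/column id files
#' (one id per line). Indices on disk are 1-based per the format; entries
#' outside the declared dimensions are a hard error.
#'
#' @param matrix_path Path to the `.mtx` file.
#' @param row_path,col_path Paths to row/column id text files.
#' @return A `dgCMatrix` with dimnames set from the id files.
#' @export
read_mtx <- function(matrix_path, row_path, col_path) {
  m <- Matrix::readMM(matrix_path)
  # normalize pattern/symmetric variants to general numeric storage
  m <- methods::as(methods::as(methods::as(m, "dMatrix"),
                               "generalMatrix"), "CsparseMatrix")
  rows <- readLines(row_path)
  cols <- readLines(col_path)
  if (length(rows) != nrow(m) || length(cols) != ncol(m)) {
    stop("id file lengths (", length(rows), " x ", length(cols),
         ") do not match declared matrix dimensions (",
         nrow(m), " x ", ncol(m), ")")
  }
  dimnames(m) <- list(rows, cols)
  m
}

#' Write a sparse count matrix to MatrixMarket files
#'
#' Inverse of [read_mtx()]: a round trip reproduces the matrix exactly.
#'
#' @param m A matrix or sparse Matrix with dimnames.
#' @param matrix_path,row_path,col_path Output paths.
#' @return Invisibly, `matrix_path`.
#' @export
write_mtx <- function(m, matrix_path, row_path, col_path) {
  sm <- methods::as(methods::as(methods::as(
    Matrix::Matrix(m, sparse = TRUE), "dMatrix"),
    "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(sm, matrix_path)
  writeLines(if (is.null(rownames(m))) as.character(seq_len(nrow(m)))
             else rownames(m), row_path)
  writeLines(if (is.null(colnames(m))) as.character(seq_len(ncol(m)))
             else colnames(m), col_path)
  invisible(matrix_path)
}

#' Read a BED interval file
#'
#' Intervals are returned exactly as stored: 0-based half-open, the
#' package-wide convention, so no coordinate shifting occurs.
#'
#' @param path Path to a BED3+ file (optionally gzipped).
#' @return A data.frame with columns `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(gzfile(path), sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  extra <- c("name", "score", "strand")
  names(df) <- c("chrom", "start", "end", extra)[seq_len(ncol(df))]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (anyNA(df$start) || anyNA(df$end)) {
    stop("non-integer coordinate in BED file ", path)
  }
  if (any(df$start < 0) || any(df$start >= df$end)) {
    stop("invalid interval (start < 0 or start >= end) in BED file ", path)
  }
  df
}

#' Write a BED interval file
#'
#' @param intervals Data.frame with `chrom`, `start`, `end` and optional
#'   further BED columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  utils::write.table(intervals[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an sgRNA spacer library table
#'
#' Expects a TSV with a header naming (at least) columns `spacer`, `sgrna`
#' and `target`. Non-targeting controls carry target `NT`.
#'
#' @param path Path to the TSV.
#' @return A validated spacer library data.frame (see [spacer_library()]).
#' @export
read_spacer_library <- function(path) {
  df <- utils::read.table(gzfile(path), sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  spacer_library(df)
}

#' Read a peak x motif match matrix
#'
#' Combines a MatrixMarket boolean match matrix (peaks x motifs) with a
#' motif table (TSV with header columns `motif` and `cluster`).
#'
#' @param matrix_path,peak_path,motif_path MTX plus row (peak id) and
#'   column (motif id) sidecar files.
#' @param motif_table_path TSV mapping motif id to family/cluster id.
#' @return A list with elements `matches` (sparse 0/1 `dgCMatrix`) and
#'   `motif_table` (data.frame `motif`, `cluster`).
#' @export
read_motif_matches <- function(matrix_path, peak_path, motif_path,
                               motif_table_path) {
  matches <- read_mtx(matrix_path, peak_path, motif_path)
  matches@x[matches@x != 0] <- 1
  tab <- utils::read.table(gzfile(motif_table_path), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("motif", "cluster") %in% names(tab))) {
    stop("motif table must have columns 'motif' and 'cluster'")
  }
  missing <- setdiff(colnames(matches), tab$motif)
  if (length(missing)) {
    stop("motif id(s) absent from motif table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  if (any(!nzchar(tab$cluster))) stop("empty cluster id in motif table")
  list(matches = matches, motif_table = tab)
}
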