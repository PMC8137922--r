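#' Read a 10x-style fragments file
#'
#' Parses a tab-separated fragments file (chrom, start, end, barcode, count)
#' as emitted by droplet scATAC-seq pipelines. Coordinates are kept exactly
#' as stored: 0-based, half-open, already Tn5-offset corrected upstream, so
#' no shifting is applied. The two insertion sites of a fragment are
#' positions `start` and `end - 1`.
#'
#' Lines starting with `#` are skipped. Rows with `start >= end` violate the
#' fragment invariant and are skipped with a single summary warning; the
#' number skipped is returned in attribute `n_skipped`. Non-integer
#' coordinates are a hard error.
#'
#' @param path Path to the fragments TSV, optionally gzip/bgzip-compressed.
#' @param strip_suffix Strip trailing `-<digits>` gem-group suffixes from
#'   barcodes (whitelists omit them); default `TRUE`.
#' @param callback Optional function called per chunk (a data.frame of
#'   fragments) for constant-memory streaming; when supplied, the return
#'   value is the total row count instead of a data.frame.
#' @param chunk_size Lines per chunk when streaming (default 500000).
#' @return A data.frame with columns `chrom`, `start`, `end`, `barcode`,
#'   `count` (attribute `n_skipped`), or the row total in callback mode.
#' @export
read_fragments <- function(path, strip_suffix = TRUE, callback = NULL,
                           chunk_size = 500000L) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con), add = TRUE)
  out <- list()
  n_skipped <- 0L
  total <- 0L
  line_no <- 0L
  repeat {
    lines <- readLines(con, n = chunk_size)
    if (!length(lines)) break
    keep <- !startsWith(lines, "#")
    lines <- lines[keep]
    if (length(lines)) {
      parts <- strsplit(lines, "\t", fixed = TRUE)
      ncols <- lengths(parts)
      if (any(ncols < 5L)) {
        stop("fragments line ", line_no + which(ncols < 5L)[1L],
             ": expected >= 5 tab-separated fields")
      }
      m <- matrix(unlist(lapply(parts, `[`, 1:5)), ncol = 5L, byrow = TRUE)
      start <- suppressWarnings(as.integer(m[, 2L]))
      end <- suppressWarnings(as.integer(m[, 3L]))
      cnt <- suppressWarnings(as.integer(m[, 5L]))
      bad <- which(is.na(start) | is.na(end))
      if (length(bad)) {
        stop("non-integer coordinate in fragments file at data row ",
             total + n_skipped + bad[1L])
      }
      if (anyNA(cnt)) {
        stop("non-integer count in fragments file at data row ",
             total + n_skipped + which(is.na(cnt))[1L])
      }
      bc <- m[, 4L]
      if (strip_suffix) bc <- sub("-[0-9]+$", "", bc)
      drop <- start >= end
      n_skipped <- n_skipped + sum(drop)
      df <- data.frame(chrom = m[!drop, 1L], start = start[!drop],
                       end = end[!drop], barcode = bc[!drop],
                       count = cnt[!drop], stringsAsFactors = FALSE)
      total <- total + nrow(df)
      if (is.null(callback)) {
        out[[length(out) + 1L]] <- df
      } else if (nrow(df)) {
        callback(df)
      }
    }
    line_no <- line_no + sum(keep)
  }
  if (n_skipped > 0L) {
    warning("skipped ", n_skipped, " fragment(s) with start >= end")
  }
  if (!is.null(callback)) return(invisible(total))
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               barcode = character(), count = integer(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Write a fragments file
#'
#' Inverse of [read_fragments()]; coordinates are written as stored
#' (0-based half-open). Paths ending in `.gz` are gzip-compressed.
#'
#' @param fragments A data.frame with columns `chrom`, `start`, `end`,
#'   `barcode`, `count`.
#' @param path Output path.
#' @return Invisibly, the number of rows written.
#' @export
write_fragments <- function(fragments, path) {
  stopifnot(all(c("chrom", "start", "end", "barcode", "count") %in%
                  names(fragments)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con), add = TRUE)
  writeLines(paste(fragments$chrom, fragments$start, fragments$end,
                   fragments$barcode, fragments$count, sep = "\t"), con)
  invisible(nrow(fragments))
}
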