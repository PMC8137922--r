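#' Stream a paired set of FASTQ files in chunks
#'
#' Reads a spacer FASTQ (the sgRNA read) and a barcode FASTQ (the cell index
#' read) in lockstep, in chunks of at most `chunk_size` read pairs, calling
#' `callback` once per chunk. Pairing is positional: record *i* of the spacer
#' file is paired with record *i* of the index file, the ordering droplet
#' pipelines emit. Files may be gzip-compressed.
#'
#' @param spacer_path Path to the spacer (Read1) FASTQ, optionally gzipped.
#' @param index_path Path to the barcode (Index1) FASTQ, optionally gzipped.
#' @param chunk_size Maximum read pairs per chunk (default 500000).
#' @param callback Function called as `callback(chunk)` for each chunk, where
#'   `chunk` is a data.frame with columns `spacer` and `barcode`.
#' @param check_names If `TRUE`, additionally verify that read names agree
#'   between the two files (strict mode); default `FALSE` for speed.
#' @return Invisibly, the total number of read pairs streamed.
#' @export
fastq_pair_chunks <- function(spacer_path, index_path, chunk_size = 500000L,
                              callback, check_names = FALSE) {
  stopifnot(is.function(callback), chunk_size >= 1L)
  con1 <- gzfile(spacer_path, open = "rt")
  con2 <- gzfile(index_path, open = "rt")
  on.exit({ close(con1); close(con2) }, add = TRUE)
  total <- 0L
  repeat {
    l1 <- readLines(con1, n = 4L * chunk_size)
    l2 <- readLines(con2, n = 4L * chunk_size)
    n1 <- length(l1); n2 <- length(l2)
    if (n1 %% 4L != 0L) {
      stop("malformed FASTQ record at record ", total + n1 %/% 4L + 1L,
           " in ", spacer_path, " (truncated record)")
    }
    if (n2 %% 4L != 0L) {
      stop("malformed FASTQ record at record ", total + n2 %/% 4L + 1L,
           " in ", index_path, " (truncated record)")
    }
    r1 <- n1 %/% 4L; r2 <- n2 %/% 4L
    if (r1 != r2) {
      shorter <- if (r1 < r2) spacer_path else index_path
      stop("record count mismatch between FASTQ files: '", shorter,
           "' has fewer records (", total + min(r1, r2),
           " vs at least ", total + max(r1, r2), ")")
    }
    if (r1 == 0L) break
    .check_fastq_records(l1, spacer_path, total)
    .check_fastq_records(l2, index_path, total)
    if (check_names) {
      nm1 <- sub("[ /].*$", "", substring(l1[seq(1L, n1, by = 4L)], 2L))
      nm2 <- sub("[ /].*$", "", substring(l2[seq(1L, n2, by = 4L)], 2L))
      bad <- which(nm1 != nm2)
      if (length(bad)) {
        stop("read name mismatch at record ", total + bad[1L])
      }
    }
    chunk <- data.frame(
      spacer = l1[seq(2L, n1, by = 4L)],
      barcode = l2[seq(2L, n2, by = 4L)],
      stringsAsFactors = FALSE
    )
    callback(chunk)
    total <- total + r1
    if (r1 < chunk_size) break
  }
  invisible(total)
}

.check_fastq_records <- function(lines, path, offset) {
  heads <- lines[seq(1L, length(lines), by = 4L)]
  seps <- lines[seq(3L, length(lines), by = 4L)]
  bad <- which(!startsWith(heads, "@") | !startsWith(seps, "+"))
  if (length(bad)) {
    stop("malformed FASTQ record at record ", offset + bad[1L], " in ", path)
  }
  invisible(NULL)
}

#' Read a paired set of FASTQ files into memory
#'
#' Convenience wrapper around [fastq_pair_chunks()] collecting all read pairs.
#'
#' @inheritParams fastq_pair_chunks
#' @return A data.frame with columns `spacer` and `barcode`, one row per read
#'   pair, with attribute `n_chunks`.
#' @export
read_fastq_pair <- function(spacer_path, index_path, chunk_size = 500000L,
                            check_names = FALSE) {
  chunks <- list()
  fastq_pair_chunks(spacer_path, index_path, chunk_size,
                    callback = function(ch) chunks[[length(chunks) + 1L]] <<- ch,
                    check_names = check_names)
  out <- if (length(chunks)) {
    do.call(rbind, chunks)
  } else {
    data.frame(spacer = character(), barcode = character(),
               stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "n_chunks") <- length(chunks)
  out
}

#' Write a paired set of FASTQ files
#'
#' Emits positionally paired spacer/barcode FASTQ records with constant
#' quality strings. Paths ending in `.gz` are gzip-compressed.
#'
#' @param spacer,barcode Character vectors of equal length.
#' @param spacer_path,index_path Output paths.
#' @param ids Optional read names (without `@`); defaults to `read-<i>`.
#' @return Invisibly, the number of records written.
#' @export
write_fastq_pair <- function(spacer, barcode, spacer_path, index_path,
                             ids = NULL) {
  stopifnot(length(spacer) == length(barcode))
  if (is.null(ids)) ids <- paste0("read-", seq_along(spacer))
  .write_fastq(ids, spacer, spacer_path)
  .write_fastq(ids, barcode, index_path)
  invisible(length(spacer))
}

.write_fastq <- function(ids, seqs, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con), add = TRUE)
  qual <- strrep("I", nchar(seqs))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), con)
  invisible(NULL)
}
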