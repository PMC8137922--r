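#' Build a 1-mismatch cell-barcode index
#'
#' Compiles a lookup resolving any query barcode within Hamming distance 1
#' of exactly one whitelist entry. Every single-base substitution variant of
#' every whitelist barcode is enumerated once; variants reachable from two
#' or more whitelist entries are marked ambiguous. Exact whitelist strings
#' always resolve to themselves, even when they lie within distance 1 of
#' another entry.
#'
#' @param whitelist Character vector of cell barcodes, all the same length.
#' @return An object of class `barcode_index`.
#' @export
barcode_index <- function(whitelist) {
  whitelist <- as.character(whitelist)
  if (!length(whitelist)) stop("empty whitelist")
  if (anyDuplicated(whitelist)) stop("duplicate barcodes in whitelist")
  L <- unique(nchar(whitelist))
  if (length(L) != 1L) stop("whitelist barcodes must all have the same length")
  n <- length(whitelist)
  keys <- vector("list", 4L * L)
  owners <- vector("list", 4L * L)
  slot <- 0L
  for (p in seq_len(L)) {
    orig <- substring(whitelist, p, p)
    pre <- substring(whitelist, 1L, p - 1L)
    post <- substring(whitelist, p + 1L, L)
    for (b in c("A", "C", "G", "T")) {
      keep <- orig != b
      if (!any(keep)) next
      slot <- slot + 1L
      keys[[slot]] <- paste0(pre[keep], b, post[keep])
      owners[[slot]] <- which(keep)
    }
  }
  keys <- unlist(keys[seq_len(slot)], use.names = FALSE)
  owners <- unlist(owners[seq_len(slot)], use.names = FALSE)
  # a variant reachable from >1 whitelist entry is ambiguous (-1); a variant
  # that is itself a whitelist barcode resolves exactly
  ord <- order(keys, method = "radix")
  keys <- keys[ord]; owners <- owners[ord]
  first <- !duplicated(keys)
  dup_key <- keys[!first]
  owners[keys %in% dup_key] <- -1L
  keys <- keys[first]
  owners <- owners[first]
  exact <- match(keys, whitelist)
  owners[!is.na(exact)] <- exact[!is.na(exact)]
  miss <- is.na(match(whitelist, keys))
  if (any(miss)) {
    keys <- c(keys, whitelist[miss])
    owners <- c(owners, which(miss))
  }
  structure(list(keys = keys, owners = owners, barcodes = whitelist,
                 width = L),
            class = "barcode_index")
}

#' @export
print.barcode_index <- function(x, ...) {
  cat("barcode_index:", length(x$barcodes), "barcodes of width", x$width,
      "(", length(x$keys), "lookup keys )\n")
  invisible(x)
}

#' Resolve query barcodes against a 1-mismatch index
#'
#' @param index A [barcode_index()].
#' @param queries Character vector of observed barcode sequences.
#' @return Integer vector of whitelist positions (`NA` where unresolved),
#'   with attributes `n_exact`, `n_mismatch`, `n_ambiguous`, `n_unmatched`.
#' @export
match_barcodes <- function(index, queries) {
  stopifnot(inherits(index, "barcode_index"))
  hit <- match(queries, index$keys)
  owner <- index$owners[hit]
  amb <- !is.na(owner) & owner == -1L
  res <- owner
  res[amb] <- NA_integer_
  exact <- !is.na(res) & queries == index$barcodes[res]
  structure(res,
            n_exact = sum(exact),
            n_mismatch = sum(!is.na(res)) - sum(exact),
            n_ambiguous = sum(amb),
            n_unmatched = sum(is.na(owner)))
}

#' Validate an sgRNA spacer library
#'
#' @param library A data.frame with columns `spacer` (DNA, fixed length),
#'   `sgrna` (unique guide id) and `target` (gene symbol; `NT` for
#'   non-targeting controls).
#' @return The validated data.frame with class `spacer_library`.
#' @export
spacer_library <- function(library) {
  stopifnot(is.data.frame(library),
            all(c("spacer", "sgrna", "target") %in% names(library)))
  if (anyDuplicated(library$spacer)) stop("spacer sequences must be unique")
  if (anyDuplicated(library$sgrna)) stop("sgRNA ids must be unique")
  if (length(unique(nchar(library$spacer))) != 1L) {
    stop("spacers must all have the same length")
  }
  class(library) <- c("spacer_library", "data.frame")
  library
}

#' Match spacer reads to the library
#'
#' Spacer matching is exact and anchored at read position 0 by default; a
#' small leading scan window accommodates primer slippage, and an optional
#' 1-mismatch mode reuses the unique-resolution rule used for barcodes.
#'
#' @param library A [spacer_library()].
#' @param reads Character vector of spacer read sequences.
#' @param scan_window Leading offsets (bp) to try, `0:scan_window`
#'   (default 0 = anchored).
#' @param max_mismatch 0 (default) or 1 substitution.
#' @return Integer vector of library row positions (`NA` where unresolved).
#' @export
match_spacers <- function(library, reads, scan_window = 0L,
                          max_mismatch = 0L) {
  stopifnot(inherits(library, "spacer_library"), max_mismatch %in% 0:1)
  S <- nchar(library$spacer[1L])
  res <- rep(NA_integer_, length(reads))
  mm_index <- if (max_mismatch == 1L) barcode_index(library$spacer) else NULL
  for (off in 0:scan_window) {
    todo <- which(is.na(res))
    if (!length(todo)) break
    sub <- substr(reads[todo], off + 1L, off + S)
    hit <- if (is.null(mm_index)) {
      match(sub, library$spacer)
    } else {
      as.integer(match_barcodes(mm_index, sub))
    }
    res[todo] <- hit
  }
  res
}

#' Match one or more read pairs to cell and sgRNA
#'
#' @param spacer_read,barcode_read Character vectors (paired positionally).
#' @param index A [barcode_index()].
#' @param library A [spacer_library()].
#' @param ... Passed to [match_spacers()].
#' @return A data.frame with columns `cell` and `sgrna` (NA where
#'   unresolved).
#' @export
match_read <- function(spacer_read, barcode_read, index, library, ...) {
  ci <- match_barcodes(index, barcode_read)
  gi <- match_spacers(library, spacer_read, ...)
  data.frame(cell = ifelse(is.na(ci), NA_character_,
                           index$barcodes[ifelse(is.na(ci), 1L, ci)]),
             sgrna = ifelse(is.na(gi), NA_character_,
                            library$sgrna[ifelse(is.na(gi), 1L, gi)]),
             stringsAsFactors = FALSE)
}

#' Build the cell x sgRNA count matrix from enrichment FASTQs
#'
#' Streams the paired FASTQs in chunks, resolves each read pair against the
#' barcode index and spacer library, and accumulates read counts per
#' (cell, sgRNA). Entry (c, g) is the number of read pairs whose barcode
#' resolved to cell c and whose spacer matched guide g.
#'
#' @param spacer_path,index_path Paired FASTQ paths (see
#'   [fastq_pair_chunks()]).
#' @param index A [barcode_index()].
#' @param library A [spacer_library()].
#' @param chunk_size Read pairs per streamed chunk.
#' @param scan_window,max_mismatch Passed to [match_spacers()].
#' @return A list of class `sgrna_counts`: `counts` (sparse cells x sgRNAs,
#'   rows restricted to barcodes with at least one fully matched read) and
#'   `report` (reads seen / barcode-matched / spacer-matched / both, plus
#'   ambiguity counters).
#' @export
build_count_matrix <- function(spacer_path, index_path, index, library,
                               chunk_size = 500000L, scan_window = 0L,
                               max_mismatch = 0L) {
  stopifnot(inherits(index, "barcode_index"),
            inherits(library, "spacer_library"))
  ci_all <- list(); gi_all <- list()
  rep_ <- c(reads = 0, barcode_matched = 0, barcode_ambiguous = 0,
            spacer_matched = 0, both_matched = 0)
  fastq_pair_chunks(spacer_path, index_path, chunk_size, function(ch) {
    ci <- match_barcodes(index, ch$barcode)
    gi <- match_spacers(library, ch$spacer, scan_window, max_mismatch)
    both <- !is.na(ci) & !is.na(gi)
    rep_["reads"] <<- rep_["reads"] + nrow(ch)
    rep_["barcode_matched"] <<- rep_["barcode_matched"] + sum(!is.na(ci))
    rep_["barcode_ambiguous"] <<- rep_["barcode_ambiguous"] +
      attr(ci, "n_ambiguous")
    rep_["spacer_matched"] <<- rep_["spacer_matched"] + sum(!is.na(gi))
    rep_["both_matched"] <<- rep_["both_matched"] + sum(both)
    if (any(both)) {
      ci_all[[length(ci_all) + 1L]] <<- ci[both]
      gi_all[[length(gi_all) + 1L]] <<- gi[both]
    }
  })
  ci <- unlist(ci_all, use.names = FALSE)
  gi <- unlist(gi_all, use.names = FALSE)
  if (length(ci)) {
    cells <- sort(unique(ci))
    m <- Matrix::sparseMatrix(i = match(ci, cells), j = gi, x = 1,
                              dims = c(length(cells), nrow(library)),
                              dimnames = list(index$barcodes[cells],
                                              library$sgrna))
  } else {
    m <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(0L, nrow(library)),
                              dimnames = list(character(), library$sgrna))
  }
  structure(list(counts = m, report = rep_), class = "sgrna_counts")
}

#' @export
print.sgrna_counts <- function(x, ...) {
  cat("sgrna_counts:", nrow(x$counts), "cells x", ncol(x$counts),
      "sgRNAs;", x$report["both_matched"], "of", x$report["reads"],
      "reads fully matched\n")
  invisible(x)
}

#' Call high-fidelity per-cell sgRNA assignments
#'
#' A cell is assigned to its top-count sgRNA when its total sgRNA read
#' count reaches `min_counts` and the specificity (top count / total)
#' reaches `min_specificity`; otherwise it is left unassigned with a reason
#' (`low_counts`, `tie`, or `low_specificity`). With
#' `level = "target"`, counts are first summed across guides sharing a
#' target gene before the specificity ratio, the more permissive reading.
#'
#' @param counts An `sgrna_counts` object or a cells x sgRNAs matrix.
#' @param library A [spacer_library()] mapping sgRNA to target (required if
#'   `counts` is a bare matrix).
#' @param min_counts Minimum total sgRNA reads per cell (default 20).
#' @param min_specificity Minimum top fraction (default 0.8).
#' @param level Specificity computed per individual `"sgrna"` (default,
#'   stricter) or per `"target"` gene.
#' @return A data.frame of class `assignment_table`: `cell`, `sgrna`,
#'   `target`, `n_counts`, `specificity`, `assigned`, `reason`.
#' @export
assign_cells <- function(counts, library = NULL, min_counts = 20L,
                         min_specificity = 0.8,
                         level = c("sgrna", "target")) {
  level <- match.arg(level)
  if (inherits(counts, "sgrna_counts")) counts <- counts$counts
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  if (is.null(library)) {
    stop("a spacer_library is required to map sgRNAs to targets")
  }
  tgt_of <- stats::setNames(library$target, library$sgrna)
  sg_ids <- colnames(m)
  if (is.null(sg_ids)) sg_ids <- library$sgrna[seq_len(ncol(m))]
  if (!all(sg_ids %in% names(tgt_of))) {
    stop("count matrix columns not all present in the spacer library")
  }
  dm <- as.matrix(m)
  total <- rowSums(dm)
  if (level == "target") {
    grp <- tgt_of[sg_ids]
    agg <- t(rowsum(t(dm), grp))      # cells x targets
    top_val <- apply(agg, 1L, max)
    n_top <- rowSums(agg == top_val)
    top_tgt <- colnames(agg)[max.col(agg, ties.method = "first")]
    # top sgRNA within the winning target
    top_sg <- vapply(seq_len(nrow(dm)), function(i) {
      j <- which(grp == top_tgt[i])
      sg_ids[j[which.max(dm[i, j])]]
    }, character(1))
  } else {
    top_val <- apply(dm, 1L, max)
    n_top <- rowSums(dm == top_val)
    top_sg <- sg_ids[max.col(dm, ties.method = "first")]
    top_tgt <- unname(tgt_of[top_sg])
  }
  spec <- ifelse(total > 0, top_val / total, 0)
  reason <- rep("assigned", nrow(dm))
  reason[spec < min_specificity] <- "low_specificity"
  reason[n_top > 1L] <- "tie"
  reason[total < min_counts] <- "low_counts"
  assigned <- reason == "assigned"
  out <- data.frame(
    cell = if (is.null(rownames(dm))) as.character(seq_len(nrow(dm)))
           else rownames(dm),
    sgrna = ifelse(assigned, top_sg, NA_character_),
    target = ifelse(assigned, top_tgt, NA_character_),
    n_counts = unname(total),
    specificity = unname(spec),
    assigned = assigned,
    reason = reason,
    stringsAsFactors = FALSE
  )
  class(out) <- c("assignment_table", "data.frame")
  out
}

#' Summarize an assignment table
#'
#' @param table An [assign_cells()] result.
#' @param n_captured Total nuclei captured in the run (>= number assigned).
#' @return A list: `n_assigned`, `n_captured`, `fraction`, `percent`
#'   (integer precision, as reported), and `per_target` cell counts.
#' @export
assignment_summary <- function(table, n_captured) {
  if (n_captured <= 0) stop("n_captured must be positive")
  n_assigned <- sum(table$assigned)
  if (n_captured < n_assigned) {
    stop("n_captured (", n_captured, ") < cells assigned (", n_assigned, ")")
  }
  per_target <- if (n_assigned) table(table$target[table$assigned]) else
    table(character())
  list(n_assigned = n_assigned,
       n_captured = n_captured,
       fraction = n_assigned / n_captured,
       percent = round(100 * n_assigned / n_captured),
       per_target = per_target)
}

#' Cost per dual-readout cell
#'
#' Sample cost divided by the number of cells carrying both an
#' accessibility profile and an sgRNA assignment, rounded to cents.
#'
#' @param cost_per_sample Run cost in currency units.
#' @param n_dual_readout_cells Cells with both read-outs (> 0).
#' @return Cost per cell, rounded to 2 decimals.
#' @export
cost_per_cell <- function(cost_per_sample, n_dual_readout_cells) {
  if (n_dual_readout_cells <= 0) {
    stop("n_dual_readout_cells must be positive")
  }
  round(cost_per_sample / n_dual_readout_cells, 2)
}
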