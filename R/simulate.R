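#' Configuration for a synthetic CRISPR accessibility screen
#'
#' Defines the ground-truthed study conditions the generator emulates: a
#' pooled CRISPRi screen read out by droplet scATAC-seq, with a targeted
#' sgRNA enrichment library (spacer read + cell-barcode read) and a peaks
#' x cells insertion-count matrix carrying injected motif-level effects.
#'
#' Defaults mirror a desk-scale screen: 12 targets at two guides each plus
#' three non-targeting guides, 100 cells per guide (200 cells per target
#' arm), log-normal sgRNA read depth (median ~80 reads/cell), 5% barcode
#' contamination, 0.2% sequencing error, 2000 peaks with Gamma-distributed
#' baseline rates, 20 motifs of 50 peaks, and a two-fold accessibility
#' effect of each target on its own motif.
#'
#' @param n_targets Number of perturbed genes.
#' @param sgrnas_per_target Guides per gene.
#' @param n_nt Non-targeting guides.
#' @param cells_per_sgrna Cells per guide.
#' @param reads_meanlog,reads_sdlog Log-normal sgRNA reads per cell.
#' @param barcode_length,spacer_length Sequence lengths (bp).
#' @param contamination Fraction of a cell's sgRNA reads drawn from a
#'   random other guide (must be < 0.5).
#' @param error_rate Per-base substitution rate applied to both reads.
#' @param n_peaks Accessibility peaks.
#' @param n_motifs Motifs (default `n_targets + 8`).
#' @param peaks_per_motif Peaks per motif.
#' @param baseline_shape,baseline_mean Gamma parameters of per-peak
#'   baseline rates (mean counts per unit depth).
#' @param depth_sdlog Log-normal sd of per-cell depth factors.
#' @param effect_fold Fold change injected on the effect motif's peaks in
#'   cells of the matching target (default 2; target *i* perturbs motif
#'   *i*).
#' @param effects Optional explicit effect map: data.frame
#'   `target`, `motif` (index), `fold`. Overrides `effect_fold`.
#' @param doublet_rate Fraction of barcodes receiving a second cell's
#'   counts.
#' @param overdispersion Gamma-Poisson overdispersion (0 = pure Poisson).
#' @param gc_confounded If `TRUE`, perturbed peaks get shifted GC so bias
#'   matching is stressed; default independent GC.
#' @param seed Mandatory integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_targets = 12L, sgrnas_per_target = 2L, n_nt = 3L,
                       cells_per_sgrna = 100L, reads_meanlog = log(80),
                       reads_sdlog = 0.3, barcode_length = 16L,
                       spacer_length = 20L, contamination = 0.05,
                       error_rate = 0.002, n_peaks = 2000L,
                       n_motifs = NULL, peaks_per_motif = 50L,
                       baseline_shape = 2, baseline_mean = 0.1,
                       depth_sdlog = 0.5, effect_fold = 2,
                       effects = NULL, doublet_rate = 0,
                       overdispersion = 0, gc_confounded = FALSE,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (contamination >= 0.5) {
    stop("contamination >= 0.5 voids the assignment guarantee; refusing")
  }
  stopifnot(contamination >= 0, error_rate >= 0, error_rate <= 1,
            doublet_rate >= 0, doublet_rate <= 1, effect_fold > 0)
  if (is.null(n_motifs)) n_motifs <- n_targets + 8L
  if (is.null(effects)) {
    effects <- data.frame(target = paste0("GENE", seq_len(n_targets)),
                          motif = seq_len(n_targets),
                          fold = effect_fold,
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(effects$fold > 0), all(effects$motif <= n_motifs))
  structure(list(n_targets = n_targets,
                 sgrnas_per_target = sgrnas_per_target, n_nt = n_nt,
                 cells_per_sgrna = cells_per_sgrna,
                 reads_meanlog = reads_meanlog, reads_sdlog = reads_sdlog,
                 barcode_length = barcode_length,
                 spacer_length = spacer_length,
                 contamination = contamination, error_rate = error_rate,
                 n_peaks = n_peaks, n_motifs = n_motifs,
                 peaks_per_motif = peaks_per_motif,
                 baseline_shape = baseline_shape,
                 baseline_mean = baseline_mean, depth_sdlog = depth_sdlog,
                 effects = effects, doublet_rate = doublet_rate,
                 overdispersion = overdispersion,
                 gc_confounded = gc_confounded, seed = as.integer(seed)),
            class = "sim_config")
}

.rand_seq <- function(n, width) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
              nrow = n)
  apply(m, 1L, paste0, collapse = "")
}

.rand_seq_unique <- function(n, width) {
  out <- unique(.rand_seq(ceiling(n * 1.2) + 8L, width))
  while (length(out) < n) {
    out <- unique(c(out, .rand_seq(n, width)))
  }
  out[seq_len(n)]
}

.mutate_seqs <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  width <- nchar(seqs[1L])
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)),
                  nrow = length(seqs), byrow = TRUE)
  hit <- matrix(stats::runif(length(chars)) < rate, nrow = nrow(chars))
  if (any(hit)) {
    chars[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
  }
  apply(chars, 1L, paste0, collapse = "")
}

# Shared cell-level truth: whitelist barcodes, guide library, per-cell
# guide assignment. Deterministic given the config seed.
.sim_truth <- function(config) {
  n_sg <- config$n_targets * config$sgrnas_per_target + config$n_nt
  targets <- c(rep(paste0("GENE", seq_len(config$n_targets)),
                   each = config$sgrnas_per_target),
               rep("NT", config$n_nt))
  sg_suffix <- c(rep(seq_len(config$sgrnas_per_target), config$n_targets),
                 seq_len(config$n_nt))
  sgrna <- paste0("sg", targets, "-", sg_suffix)
  library <- spacer_library(data.frame(
    spacer = .rand_seq_unique(n_sg, config$spacer_length),
    sgrna = sgrna, target = targets, stringsAsFactors = FALSE))
  n_cells <- n_sg * config$cells_per_sgrna
  whitelist <- .rand_seq_unique(n_cells, config$barcode_length)
  truth <- data.frame(cell = whitelist,
                      sgrna = rep(library$sgrna,
                                  each = config$cells_per_sgrna),
                      target = rep(library$target,
                                   each = config$cells_per_sgrna),
                      stringsAsFactors = FALSE)
  list(library = library, whitelist = whitelist, truth = truth)
}

#' Simulate sgRNA-enrichment FASTQ files
#'
#' Emits a positionally paired spacer/barcode FASTQ pair with known
#' per-cell truth: each cell's reads carry its true spacer with
#' probability `1 - contamination` and a random other guide's spacer
#' otherwise, with per-base substitution errors applied to both reads.
#' Byte-identical output given the same config.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param gzip Compress the FASTQs (default `FALSE`).
#' @return A list: `spacer_fastq`, `index_fastq`, `whitelist_file`,
#'   `library_file`, `whitelist`, `library`, `truth` (with per-cell read
#'   and contamination counts).
#' @export
simulate_sgrna_fastq <- function(config, dir = tempfile("simfq"),
                                 gzip = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(config$seed, {
    parts <- .sim_truth(config)
    truth <- parts$truth
    n_cells <- nrow(truth)
    n_reads <- as.integer(pmax(1, round(stats::rlnorm(
      n_cells, config$reads_meanlog, config$reads_sdlog))))
    cell_of_read <- rep.int(seq_len(n_cells), n_reads)
    total <- length(cell_of_read)
    true_sg <- match(truth$sgrna, parts$library$sgrna)[cell_of_read]
    contam <- stats::runif(total) < config$contamination
    sg_read <- true_sg
    if (any(contam)) {
      n_sg <- nrow(parts$library)
      other <- sample.int(n_sg - 1L, sum(contam), replace = TRUE)
      sg_read[contam] <- ifelse(other >= true_sg[contam], other + 1L, other)
    }
    spacer <- .mutate_seqs(parts$library$spacer[sg_read], config$error_rate)
    barcode <- .mutate_seqs(truth$cell[cell_of_read], config$error_rate)
    truth$n_reads <- n_reads
    truth$n_contaminated <- as.integer(
      tabulate(cell_of_read[contam], nbins = n_cells))
    ext <- if (gzip) ".fastq.gz" else ".fastq"
    spacer_fastq <- file.path(dir, paste0("sgrna_R1", ext))
    index_fastq <- file.path(dir, paste0("sgrna_I1", ext))
    write_fastq_pair(spacer, barcode, spacer_fastq, index_fastq)
    whitelist_file <- file.path(dir, "whitelist.txt")
    writeLines(parts$whitelist, whitelist_file)
    library_file <- file.path(dir, "sgrna_library.tsv")
    utils::write.table(parts$library, library_file, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(spacer_fastq = spacer_fastq, index_fastq = index_fastq,
         whitelist_file = whitelist_file, library_file = library_file,
         whitelist = parts$whitelist, library = parts$library,
         truth = truth)
  })
}

#' Simulate an accessibility count matrix with injected effects
#'
#' Draws `X[i, p] ~ Poisson(d_i * lambda_p * e_ip)` with per-cell depth
#' factors `d_i` (log-normal), Gamma-distributed per-peak baselines
#' `lambda_p`, and `e_ip` the configured fold change when cell *i*'s
#' target perturbs a motif containing peak *p* (1 otherwise). Peak GC is
#' drawn Uniform(0.3, 0.7) independently of the effects (unless
#' `gc_confounded`), and doublet barcodes receive a second cell's
#' independent draw. The seed is offset from the FASTQ stage so the two
#' stages are independent but jointly reproducible.
#'
#' @param config A [sim_config()].
#' @param truth Optional truth table from [simulate_sgrna_fastq()] (the
#'   shared cell universe is regenerated from the config when omitted).
#' @return A list: `counts` (sparse cells x peaks), `motifs` (peaks x
#'   motifs 0/1 `dgCMatrix`), `motif_table` (`motif`, `cluster`), `gc`,
#'   `peaks` (interval data.frame), `depth`, `doublets`, `truth`,
#'   `effects`.
#' @export
simulate_counts <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth)) {
    truth <- withr::with_seed(config$seed, .sim_truth(config))$truth
  }
  withr::with_seed(config$seed + 1000L, {
    n_cells <- nrow(truth)
    n_peaks <- config$n_peaks
    lambda <- stats::rgamma(n_peaks, shape = config$baseline_shape,
                            scale = config$baseline_mean /
                              config$baseline_shape)
    depth <- stats::rlnorm(n_cells, 0, config$depth_sdlog)
    motif_ids <- paste0("MOTIF", seq_len(config$n_motifs))
    motif_peaks <- lapply(seq_len(config$n_motifs), function(m) {
      sort(sample.int(n_peaks, min(config$peaks_per_motif, n_peaks)))
    })
    M <- Matrix::sparseMatrix(
      i = unlist(motif_peaks), j = rep(seq_len(config$n_motifs),
                                       lengths(motif_peaks)),
      x = 1, dims = c(n_peaks, config$n_motifs),
      dimnames = list(paste0("peak", seq_len(n_peaks)), motif_ids))
    rate <- outer(depth, lambda)            # cells x peaks
    for (r in seq_len(nrow(config$effects))) {
      rows <- which(truth$target == config$effects$target[r])
      cols <- motif_peaks[[config$effects$motif[r]]]
      if (length(rows) && length(cols)) {
        rate[rows, cols] <- rate[rows, cols] * config$effects$fold[r]
      }
    }
    if (config$overdispersion > 0) {
      od <- config$overdispersion
      rate <- rate * matrix(stats::rgamma(length(rate), shape = 1 / od,
                                          scale = od), nrow = n_cells)
    }
    X <- matrix(stats::rpois(length(rate), rate), nrow = n_cells)
    doublets <- integer(0)
    if (config$doublet_rate > 0) {
      doublets <- sample.int(n_cells, round(config$doublet_rate * n_cells))
      for (i in doublets) {
        j <- sample.int(n_cells, 1L)
        X[i, ] <- X[i, ] + stats::rpois(n_peaks, depth[j] * lambda)
      }
    }
    gc <- stats::runif(n_peaks, 0.3, 0.7)
    if (config$gc_confounded) {
      hit <- unique(unlist(motif_peaks[config$effects$motif]))
      gc[hit] <- pmin(0.95, gc[hit] + 0.2)
    }
    peaks <- data.frame(chrom = "chrS",
                        start = (seq_len(n_peaks) - 1L) * 1000L,
                        end = (seq_len(n_peaks) - 1L) * 1000L + 500L,
                        stringsAsFactors = FALSE)
    counts <- methods::as(Matrix::Matrix(X, sparse = TRUE), "CsparseMatrix")
    dimnames(counts) <- list(truth$cell, rownames(M))
    list(counts = counts, motifs = M,
         motif_table = data.frame(motif = motif_ids,
                                  cluster = paste0("C", seq_along(motif_ids)),
                                  stringsAsFactors = FALSE),
         gc = gc, peaks = peaks, depth = depth, doublets = doublets,
         truth = truth, effects = config$effects)
  })
}
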