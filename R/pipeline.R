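#' Run the full screen analysis pipeline
#'
#' Wires the stages in dependency order — sgRNA assignment, motif
#' deviations, purity refinement, perturbation scoring, differential
#' accessibility, and differential correlation networks — over file-based
#' inputs, writing every stage's outputs plus a manifest with checksums,
#' seeds and per-stage counters. A failing stage raises an error naming
#' the stage; outputs of completed stages are retained.
#'
#' @param config A named list or path to a YAML file with elements:
#'   `spacer_fastq`, `index_fastq`, `whitelist`, `library` (sgRNA TSV),
#'   `counts_mtx`/`counts_rows`/`counts_cols` (cells x peaks),
#'   `motifs_mtx`/`motifs_rows`/`motifs_cols`, `motif_table`, `gc_tsv`,
#'   `out_dir`, and optional parameters `min_counts`, `min_specificity`,
#'   `nt_label`, `exclude_sgrnas`, `n_background`, `purity_k`,
#'   `purity_threshold`, `purity_n_each`, `network_k`, `seed`.
#' @return Invisibly, the manifest (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(min_counts = 20L, min_specificity = 0.8,
                   nt_label = "NT", exclude_sgrnas = character(),
                   n_background = 50L, purity_k = 20L,
                   purity_threshold = 0.9, purity_n_each = 5000L,
                   network_k = 5L, seed = 1L)
  cfg <- utils::modifyList(defaults, config)
  out_dir <- cfg$out_dir
  if (is.null(out_dir)) stop("config must set out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  counters <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(path) { outputs[length(outputs) + 1L] <<- path; path }

  ## --- assign -------------------------------------------------------
  assignment <- stage("assign", {
    for (f in c("spacer_fastq", "index_fastq", "whitelist", "library")) {
      if (is.null(cfg[[f]]) || !file.exists(cfg[[f]])) {
        stop("missing input file for '", f, "'",
             if (!is.null(cfg[[f]])) paste0(": ", cfg[[f]]))
      }
    }
    lib <- read_spacer_library(cfg$library)
    idx <- barcode_index(readLines(cfg$whitelist))
    sc <- build_count_matrix(cfg$spacer_fastq, cfg$index_fastq, idx, lib)
    counters$assign <- as.list(sc$report)
    write_mtx(sc$counts, emit(file.path(out_dir, "sgrna_counts.mtx")),
              emit(file.path(out_dir, "sgrna_counts.cells.txt")),
              emit(file.path(out_dir, "sgrna_counts.sgrnas.txt")))
    at <- assign_cells(sc, lib, min_counts = cfg$min_counts,
                       min_specificity = cfg$min_specificity)
    if (length(cfg$exclude_sgrnas)) {
      drop <- at$assigned & at$sgrna %in% cfg$exclude_sgrnas
      at$assigned[drop] <- FALSE
      at$reason[drop] <- "excluded"
    }
    utils::write.table(at, emit(file.path(out_dir, "assignments.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counters$assign$n_assigned <- sum(at$assigned)
    at
  })

  ## --- deviations ---------------------------------------------------
  dev_parts <- stage("deviations", {
    counts <- read_mtx(cfg$counts_mtx, cfg$counts_rows, cfg$counts_cols)
    motifs <- read_motif_matches(cfg$motifs_mtx, cfg$motifs_rows,
                                 cfg$motifs_cols, cfg$motif_table)
    gc <- utils::read.table(cfg$gc_tsv, sep = "\t", header = TRUE)$gc
    keep <- intersect(rownames(counts),
                      assignment$cell[assignment$assigned])
    counts <- counts[keep, , drop = FALSE]
    counts <- counts[Matrix::rowSums(counts) > 0, , drop = FALSE]
    bias <- compute_bias(counts, gc)
    bg <- sample_background_peaks(bias, n_iterations = cfg$n_background,
                                  seed = cfg$seed)
    dev <- compute_deviations(counts, motifs$matches, bg)
    write_mtx(dev$deviations,
              emit(file.path(out_dir, "deviations.mtx")),
              emit(file.path(out_dir, "deviations.cells.txt")),
              emit(file.path(out_dir, "deviations.motifs.txt")))
    write_mtx(ifelse(is.na(dev$z), 0, dev$z),
              emit(file.path(out_dir, "deviations_z.mtx")),
              emit(file.path(out_dir, "deviations_z.cells.txt")),
              emit(file.path(out_dir, "deviations_z.motifs.txt")))
    utils::write.table(
      data.frame(motif = names(dev$variability),
                 variability = dev$variability),
      emit(file.path(out_dir, "motif_variability.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    list(counts = counts, motifs = motifs, dev = dev)
  })
  counts <- dev_parts$counts
  dev <- dev_parts$dev

  ## --- purity -------------------------------------------------------
  refined <- stage("purity", {
    at <- assignment
    gone <- at$assigned & !(at$cell %in% rownames(counts))
    at$assigned[gone] <- FALSE
    at$reason[gone] <- "no_accessibility_profile"
    ref <- refine_assignments(counts, at, n_each = cfg$purity_n_each,
                              k = cfg$purity_k,
                              threshold = cfg$purity_threshold,
                              nt_label = cfg$nt_label)
    utils::write.table(ref,
                       emit(file.path(out_dir, "assignments_refined.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counters$purity <- list(n_kept = sum(ref$assigned),
                             n_dropped = sum(ref$reason == "low_purity"))
    ref
  })

  ## --- score --------------------------------------------------------
  scores <- stage("score", {
    means <- target_mean_deviations(dev, refined, level = "target")
    ps <- sgrna_tf_scores(means, nt_group = cfg$nt_label)
    utils::write.table(ps$ranking,
                       emit(file.path(out_dir, "sgrna_tf_scores.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ps
  })

  ## --- diff ---------------------------------------------------------
  stage("diff", {
    ok <- refined[refined$assigned, , drop = FALSE]
    nt_cells <- ok$cell[ok$target == cfg$nt_label]
    n_tested <- 0L
    for (tg in setdiff(unique(ok$target), cfg$nt_label)) {
      t_cells <- ok$cell[ok$target == tg]
      if (length(t_cells) < 2L || length(nt_cells) < 2L) next
      dr <- binomial_diff_peaks(counts, t_cells, nt_cells)
      utils::write.table(
        dr, emit(file.path(out_dir, paste0("diff_", tg, ".tsv"))),
        sep = "\t", quote = FALSE, row.names = FALSE)
      n_tested <- n_tested + nrow(dr)
    }
    counters$diff <- list(peaks_tested = n_tested)
  })

  ## --- network ------------------------------------------------------
  stage("network", {
    ok <- refined[refined$assigned, , drop = FALSE]
    nt_cells <- ok$cell[ok$target == cfg$nt_label]
    dd <- dedup_motifs(dev$variability[!dev$flagged],
                       stats::setNames(dev_parts$motifs$motif_table$cluster,
                                       dev_parts$motifs$motif_table$motif))
    keep_m <- dd$motif[dd$retained]
    for (tg in setdiff(unique(ok$target), cfg$nt_label)) {
      t_cells <- ok$cell[ok$target == tg]
      if (length(t_cells) < 3L || length(nt_cells) < 3L) next
      delta <- diff_correlation(dev$deviations[, keep_m, drop = FALSE],
                                t_cells, nt_cells)
      utils::write.table(
        as.data.frame(unclass(delta)),
        emit(file.path(out_dir, paste0("diffcor_", tg, ".tsv"))),
        sep = "\t", quote = FALSE, row.names = TRUE)
      if (length(keep_m) >= cfg$network_k) {
        mods <- cluster_modules(delta, k = cfg$network_k)
        utils::write.table(
          data.frame(motif = names(mods), module = as.integer(mods)),
          emit(file.path(out_dir, paste0("modules_", tg, ".tsv"))),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  })

  manifest <- list(
    outputs = lapply(outputs, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    }),
    seed = cfg$seed,
    counters = counters,
    config = cfg[setdiff(names(cfg), "out_dir")]
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
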