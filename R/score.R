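#' sgRNA-to-TF perturbation scores
#'
#' Subtracts the non-targeting group's mean motif deviation from every
#' group's mean, yielding the perturbation score `delta` per
#' (group, motif), and ranks all non-control (group, motif) pairs by
#' absolute score.
#'
#' @param means Groups x motifs matrix of mean deviations (see
#'   [target_mean_deviations()]).
#' @param nt_group Row name of the non-targeting group.
#' @return A list of class `perturb_scores`: `delta` (groups x motifs;
#'   the `nt_group` row is identically 0), `ranking` (long data.frame
#'   `group`, `motif`, `delta`, `rank` by |delta| descending), and
#'   `top_per_group`.
#' @export
sgrna_tf_scores <- function(means, nt_group = "NT") {
  if (!nt_group %in% rownames(means)) {
    stop("non-targeting group '", nt_group, "' missing from means")
  }
  delta <- sweep(means, 2L, means[nt_group, ], "-")
  if (is.null(colnames(delta))) {
    colnames(delta) <- paste0("motif", seq_len(ncol(delta)))
  }
  rows <- setdiff(rownames(delta), nt_group)
  long <- data.frame(
    group = rep(rows, times = ncol(delta)),
    motif = rep(colnames(delta), each = length(rows)),
    delta = as.vector(delta[rows, , drop = FALSE]),
    stringsAsFactors = FALSE
  )
  long <- long[order(-abs(long$delta), long$group, long$motif), ]
  long$rank <- seq_len(nrow(long))
  rownames(long) <- NULL
  top <- long[!duplicated(long$group), c("group", "motif", "delta", "rank")]
  structure(list(delta = delta, ranking = long, top_per_group = top),
            class = "perturb_scores")
}

#' @export
print.perturb_scores <- function(x, ...) {
  cat("perturb_scores:", nrow(x$delta) - 1L, "perturbation group(s) x",
      ncol(x$delta), "motifs; top hit:",
      x$ranking$group[1L], "->", x$ranking$motif[1L],
      sprintf("(delta = %.3f)\n", x$ranking$delta[1L]))
  invisible(x)
}

#' De-duplicate motifs by family, keeping the most variable
#'
#' Position-weight motif collections contain near-identical motifs; within
#' each family/cluster only the member with the highest deviation
#' variability is retained. Ties break to the lexicographically first
#' motif id.
#'
#' @param variability Named numeric vector of per-motif variability (sd of
#'   deviation z across cells; see [compute_deviations()]).
#' @param clusters Named character vector mapping motif id to cluster id
#'   (every motif must be mapped).
#' @return A data.frame: `motif`, `cluster`, `variability`, `retained`.
#' @export
dedup_motifs <- function(variability, clusters) {
  motifs <- names(variability)
  if (is.null(motifs)) stop("variability must be named by motif")
  miss <- setdiff(motifs, names(clusters))
  if (length(miss)) {
    stop("motif(s) without a cluster: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  cl <- unname(clusters[motifs])
  ord <- order(cl, -variability, motifs, method = "radix")
  retained_motifs <- motifs[ord][!duplicated(cl[ord])]
  data.frame(motif = motifs, cluster = cl,
             variability = unname(variability),
             retained = motifs %in% retained_motifs,
             stringsAsFactors = FALSE)
}

#' Rank motifs across screens
#'
#' Within each screen, a motif's score is the maximum absolute
#' perturbation score over all targets; the final score averages those
#' per-screen maxima and motifs are ranked descending.
#'
#' @param tables A list of `perturb_scores` objects (or delta matrices),
#'   one per screen, over a shared de-duplicated motif universe.
#' @param nt_group Non-targeting row to exclude from the maxima.
#' @return A data.frame: `motif`, per-screen maxima, `score`, `rank`.
#' @export
cross_screen_rank <- function(tables, nt_group = "NT") {
  deltas <- lapply(tables, function(t) {
    d <- if (inherits(t, "perturb_scores")) t$delta else t
    d[setdiff(rownames(d), nt_group), , drop = FALSE]
  })
  common <- Reduce(intersect, lapply(deltas, colnames))
  all_m <- unique(unlist(lapply(deltas, colnames)))
  if (length(common) < length(all_m)) {
    warning("excluded ", length(all_m) - length(common),
            " motif(s) missing from at least one screen")
  }
  maxima <- vapply(deltas, function(d) {
    apply(abs(d[, common, drop = FALSE]), 2L, max)
  }, numeric(length(common)))
  maxima <- matrix(maxima, nrow = length(common),
                   dimnames = list(common, names(tables)))
  score <- rowMeans(maxima)
  ord <- order(-score, common)
  out <- data.frame(motif = common, maxima, score = score,
                    stringsAsFactors = FALSE, check.names = FALSE)[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# Rank-sum test, normal approximation with tie correction (no continuity
# correction). Degenerate all-tied data sits at the null centre with p = 1.
.ranksum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  nt <- table(r)
  N <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(nt^3 - nt) / (N * (N - 1)))
  if (sigma2 <= 0) return(c(statistic = W, z = 0, p = 1))
  z <- (W - mu) / sqrt(sigma2)
  c(statistic = W, z = z, p = 2 * stats::pnorm(-abs(z)))
}

# Greedy depth matching: pair each target cell with an unused control cell
# whose depth ratio lies within [buffer_ratio, 1/buffer_ratio].
.depth_match <- function(t_depth, bg_depth, buffer_ratio) {
  ord_t <- order(t_depth)
  ord_b <- order(bg_depth)
  used <- logical(length(bg_depth))
  picked <- integer(0)
  j <- 1L
  for (i in ord_t) {
    d <- t_depth[i]
    while (j <= length(ord_b) && bg_depth[ord_b[j]] < d * buffer_ratio) {
      j <- j + 1L
    }
    jj <- j
    while (jj <= length(ord_b) &&
           bg_depth[ord_b[jj]] <= d / buffer_ratio) {
      if (!used[ord_b[jj]]) {
        used[ord_b[jj]] <- TRUE
        picked <- c(picked, ord_b[jj])
        break
      }
      jj <- jj + 1L
    }
  }
  picked
}

#' Differential motif accessibility by rank-sum test
#'
#' Two-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction) on per-cell deviation z-scores, target versus depth-matched
#' non-targeting cells, with Benjamini-Hochberg correction across motifs.
#' Each side is first subsampled to at most `max_cells` cells (seeded);
#' when per-cell depths are supplied, control cells are greedily paired to
#' target cells within a `[buffer_ratio, 1/buffer_ratio]` depth-ratio
#' window, falling back to all controls (with a warning) when no control
#' can be matched.
#'
#' @param z Cells x motifs matrix of deviation z-scores (or a
#'   `deviation_result`).
#' @param target_cells,background_cells Row-name vectors.
#' @param depth Optional named per-cell fragment totals used for matching.
#' @param max_cells Per-side subsample cap (default 250).
#' @param buffer_ratio Depth-ratio window (default 0.95).
#' @param seed Seed for the subsample (default 1).
#' @return A data.frame: `motif`, `statistic`, `z`, `pvalue`, `fdr`,
#'   `delta_mean`.
#' @export
wilcoxon_diff_motifs <- function(z, target_cells, background_cells,
                                 depth = NULL, max_cells = 250L,
                                 buffer_ratio = 0.95, seed = 1L) {
  if (inherits(z, "deviation_result")) z <- z$z
  if (length(target_cells) < 2L || length(background_cells) < 2L) {
    stop("need at least 2 cells per side")
  }
  if (!is.null(depth)) {
    picked <- .depth_match(depth[target_cells], depth[background_cells],
                           buffer_ratio)
    if (length(picked) < 2L) {
      warning("no depth-matchable control cells; using all controls")
    } else {
      background_cells <- background_cells[picked]
    }
  }
  withr::with_seed(seed, {
    if (length(target_cells) > max_cells) {
      target_cells <- sample(target_cells, max_cells)
    }
    if (length(background_cells) > max_cells) {
      background_cells <- sample(background_cells, max_cells)
    }
  })
  xt <- z[target_cells, , drop = FALSE]
  xb <- z[background_cells, , drop = FALSE]
  res <- vapply(seq_len(ncol(z)), function(m) {
    x <- xt[, m]; y <- xb[, m]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2L || length(y) < 2L) {
      return(c(statistic = NA_real_, z = NA_real_, p = NA_real_,
               d = NA_real_))
    }
    c(.ranksum(x, y), d = mean(x) - mean(y))
  }, numeric(4))
  out <- data.frame(motif = colnames(z),
                    statistic = res[1L, ], z = res[2L, ],
                    pvalue = res[3L, ],
                    fdr = stats::p.adjust(res[3L, ], method = "BH"),
                    delta_mean = res[4L, ],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
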