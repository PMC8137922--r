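#' Reproducibly differential tiles for one target
#'
#' Ranks tiles by pseudobulk log2 fold change (pseudocount 1 on profiles
#' scaled to `scale_to`) of the target's cells versus non-targeting cells,
#' keeping only tiles whose fold-change sign is reproduced by every
#' individual sgRNA of the target, then returns the top `n_each` increasing
#' and top `n_each` decreasing tiles. Ties are broken by absolute
#' scaled-count difference, then tile index, so the selection is
#' deterministic.
#'
#' @param tiles Sparse cells x tiles matrix.
#' @param assignment An [assign_cells()] table.
#' @param target Target gene to contrast against `nt_label` cells.
#' @param n_each Tiles to keep per direction (default 5000; fewer are
#'   taken, with a message, when fewer are reproducible).
#' @param nt_label Target label of non-targeting controls (default "NT").
#' @param scale_to Pseudobulk scale (default 1e6).
#' @return Integer vector of tile column indices (attributes `n_up`,
#'   `n_down`).
#' @export
reproducible_diff_tiles <- function(tiles, assignment, target,
                                    n_each = 5000L, nt_label = "NT",
                                    scale_to = 1e6) {
  tab <- assignment[assignment$assigned, , drop = FALSE]
  t_cells <- tab$cell[tab$target == target]
  nt_cells <- tab$cell[tab$target == nt_label]
  if (!length(t_cells)) stop("no assigned cells for target ", target)
  if (!length(nt_cells)) stop("no non-targeting cells present")
  sgs <- unique(tab$sgrna[tab$target == target])
  groups <- c(stats::setNames(tab$sgrna[tab$target == target], t_cells),
              stats::setNames(rep(nt_label, length(nt_cells)), nt_cells))
  pb <- pseudobulk(tiles, groups, scale_to = scale_to)
  nt_prof <- pb[, nt_label]
  groups_t <- c(stats::setNames(rep(target, length(t_cells)), t_cells),
                stats::setNames(rep(nt_label, length(nt_cells)), nt_cells))
  pb_t <- pseudobulk(tiles, groups_t, scale_to = scale_to)
  lfc <- log2((pb_t[, target] + 1) / (pb_t[, nt_label] + 1))
  sg_lfc <- log2((pb[, sgs, drop = FALSE] + 1) / (nt_prof + 1))
  s <- sign(lfc)
  reproducible <- s != 0 &
    rowSums(sign(sg_lfc) == s) == length(sgs)
  absdiff <- abs(pb_t[, target] - pb_t[, nt_label])
  idx <- seq_len(ncol(tiles))
  pick <- function(cand, decreasing) {
    ord <- order(if (decreasing) -lfc[cand] else lfc[cand],
                 -absdiff[cand], cand)
    cand[ord][seq_len(min(n_each, length(cand)))]
  }
  up <- pick(idx[reproducible & lfc > 0], decreasing = TRUE)
  down <- pick(idx[reproducible & lfc < 0], decreasing = FALSE)
  if (length(up) < n_each || length(down) < n_each) {
    message("reproducible tiles below request: ", length(up), " up, ",
            length(down), " down (asked ", n_each, " each)")
  }
  structure(sort(c(up, down)), n_up = length(up), n_down = length(down))
}

#' Neighbourhood purity of sgRNA assignments
#'
#' Embeds the target's cells together with the non-targeting cells by LSI
#' on the selected differential tiles, then computes for each target cell
#' the fraction of its `k` nearest neighbours (cosine distance, self
#' excluded, within the target-plus-NT cell set) that are themselves
#' assigned to the target. Cells keep their assignment when that
#' PurityRatio strictly exceeds `threshold`.
#'
#' @param tiles Sparse cells x tiles matrix.
#' @param assignment An [assign_cells()] table.
#' @param target Target gene.
#' @param selected Tile indices from [reproducible_diff_tiles()].
#' @param k Neighbours (default 20; reduced when fewer cells exist, noted
#'   in attribute `k_used`).
#' @param n_dims LSI dimensionality (default 30).
#' @param threshold Keep cutoff, strict (default 0.9).
#' @param nt_label Non-targeting label (default "NT").
#' @return A data.frame of class `purity_result`: `cell`, `purity_ratio`,
#'   `kept`.
#' @export
purity_ratio <- function(tiles, assignment, target, selected, k = 20L,
                         n_dims = 30L, threshold = 0.9, nt_label = "NT") {
  tab <- assignment[assignment$assigned, , drop = FALSE]
  t_cells <- tab$cell[tab$target == target]
  nt_cells <- tab$cell[tab$target == nt_label]
  cells <- c(t_cells, nt_cells)
  sub <- tiles[cells, selected, drop = FALSE]
  nz <- Matrix::rowSums(sub) > 0
  if (any(!nz[seq_along(t_cells)])) {
    warning(sum(!nz[seq_along(t_cells)]),
            " target cell(s) with no signal on selected tiles; ",
            "purity set to 0")
  }
  emb <- lsi_embed(sub[nz, , drop = FALSE], n_dims = n_dims)$embedding
  is_target <- names(nz)[nz] %in% t_cells
  k_used <- min(k, nrow(emb) - 1L)
  if (k_used < k) message("fewer than k other cells; using k = ", k_used)
  En <- emb / sqrt(rowSums(emb^2))
  sim <- En %*% t(En)
  diag(sim) <- -Inf
  ratio <- rep(0, length(t_cells))
  names(ratio) <- t_cells
  tpos <- which(is_target)
  for (ii in tpos) {
    nb <- order(sim[ii, ], decreasing = TRUE)[seq_len(k_used)]
    ratio[rownames(emb)[ii]] <- mean(is_target[nb])
  }
  out <- data.frame(cell = t_cells, purity_ratio = unname(ratio[t_cells]),
                    kept = unname(ratio[t_cells]) > threshold,
                    stringsAsFactors = FALSE)
  attr(out, "k_used") <- k_used
  class(out) <- c("purity_result", "data.frame")
  out
}

#' Apply purity refinement to an assignment table
#'
#' Runs [reproducible_diff_tiles()] and [purity_ratio()] for every target
#' and unassigns cells below the purity threshold (reason
#' `low_purity`). Non-targeting cells are not filtered.
#'
#' @param tiles Sparse cells x tiles matrix.
#' @param assignment An [assign_cells()] table.
#' @param n_each,k,n_dims,threshold,nt_label See the two stage functions.
#' @return The refined assignment table; column `purity_ratio` added.
#' @export
refine_assignments <- function(tiles, assignment, n_each = 5000L, k = 20L,
                               n_dims = 30L, threshold = 0.9,
                               nt_label = "NT") {
  out <- assignment
  out$purity_ratio <- NA_real_
  targets <- setdiff(unique(out$target[out$assigned]), nt_label)
  for (tg in targets) {
    sel <- reproducible_diff_tiles(tiles, assignment, tg, n_each = n_each,
                                   nt_label = nt_label)
    pr <- purity_ratio(tiles, assignment, tg, sel, k = k, n_dims = n_dims,
                       threshold = threshold, nt_label = nt_label)
    m <- match(pr$cell, out$cell)
    out$purity_ratio[m] <- pr$purity_ratio
    drop <- m[!pr$kept]
    if (length(drop)) {
      out$assigned[drop] <- FALSE
      out$reason[drop] <- "low_purity"
      out$sgrna[drop] <- NA_character_
      out$target[drop] <- NA_character_
    }
  }
  out
}
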