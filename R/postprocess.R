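# Redundancy-aware selection of top biclusters, with Cheng-Church
# mean-squared-residue tie-breaking computed on the retained (non-error)
# cells only.

#' Cheng-Church mean squared residue of a bicluster
#'
#' Computes the mean squared residue `H = mean((a_ij - a_iJ - a_Ij + a_IJ)^2)`
#' over the bicluster's retained cells, where `a_iJ`, `a_Ij` and `a_IJ` are
#' the row, column and overall means. Cells the miner discarded as error
#' values are excluded both from the means and from the residue sum, since the
#' bicluster model treats them as corruptions. A block with a single retained
#' cell, or any constant or perfectly additive retained block, scores 0.
#'
#' @param bicluster one element of `fit$biclusters` from [et_bicluster()].
#' @param x the expression matrix the bicluster was mined from.
#' @return non-negative number.
#' @export
mean_squared_residue <- function(bicluster, x) {
  genes <- bicluster$genes
  trans <- bicluster$transactions
  a <- x[genes, trans, drop = FALSE]
  keep <- matrix(TRUE, nrow = length(genes), ncol = length(trans))
  for (j in seq_along(trans)) {
    drop_g <- bicluster$discarded[[j]]
    if (length(drop_g)) keep[match(drop_g, genes), j] <- FALSE
  }
  if (!any(keep)) stop("bicluster has no retained cells")
  a[!keep] <- NA_real_
  row_mean <- rowMeans(a, na.rm = TRUE)
  col_mean <- colMeans(a, na.rm = TRUE)
  all_mean <- mean(a, na.rm = TRUE)
  res <- sweep(sweep(a, 1, row_mean), 2, col_mean) + all_mean
  mean(res[keep]^2, na.rm = TRUE)
}

#' Select a non-redundant set of top biclusters
#'
#' Greedy selection of up to `max_selected` biclusters such that the gene-set
#' overlap between any two selected biclusters is at most `max_overlap`.
#' Biclusters are ranked by size, measured as the number of genes only (not
#' genes x conditions, which would favour wide error-tolerant biclusters);
#' ties are broken by lower mean squared residue (computed on retained cells),
#' then lexicographically by gene set for determinism. The overlap between two
#' gene sets is `|intersection| / min(|G1|, |G2|)`, so a near-subset of an
#' already selected bicluster is rejected regardless of the sizes involved.
#'
#' By default only biclusters with at least two genes compete; pass
#' `min_level = 1` to let singletons in.
#'
#' @param fit an `"et_bicluster"` object.
#' @param x the expression matrix the fit was mined from (needed for the
#'   mean-squared-residue tie-break).
#' @param max_selected maximum number of biclusters to select (default 500).
#' @param max_overlap maximum pairwise gene-set overlap in `[0, 1]`
#'   (default 0.25).
#' @param min_level smallest bicluster level eligible for selection
#'   (default 2).
#' @return an `"et_bicluster"` object whose `biclusters` are the selected ones
#'   in selection order, with the per-bicluster `mse` attached.
#' @export
select_top <- function(fit, x, max_selected = 500, max_overlap = 0.25,
                       min_level = 2L) {
  stopifnot(inherits(fit, "et_bicluster"))
  if (max_overlap < 0 || max_overlap > 1)
    stop("'max_overlap' must lie in [0, 1]")
  if (max_selected < 1) stop("'max_selected' must be positive")

  pool <- Filter(function(b) b$level >= min_level, fit$biclusters)
  if (length(pool) == 0L) {
    sel <- fit
    sel$biclusters <- list()
    sel$selection <- list(max_selected = max_selected,
                          max_overlap = max_overlap, min_level = min_level)
    return(sel)
  }

  size <- vapply(pool, `[[`, integer(1), "level")
  mse <- vapply(pool, mean_squared_residue, numeric(1), x = x)
  key <- vapply(pool, function(b) .key(b$genes), character(1))
  ord <- order(-size, mse, key)
  pool <- pool[ord]
  mse <- mse[ord]

  selected <- list()
  sel_genes <- list()
  sel_mse <- numeric(0)
  for (i in seq_along(pool)) {
    g <- pool[[i]]$genes
    ok <- TRUE
    for (sg in sel_genes) {
      ov <- length(intersect(g, sg)) / min(length(g), length(sg))
      if (ov > max_overlap + .range_tol) { ok <- FALSE; break }
    }
    if (ok) {
      selected[[length(selected) + 1L]] <- pool[[i]]
      sel_genes[[length(sel_genes) + 1L]] <- g
      sel_mse <- c(sel_mse, mse[i])
      if (length(selected) >= max_selected) break
    }
  }
  sel <- fit
  sel$biclusters <- selected
  sel$mse <- sel_mse
  sel$selection <- list(max_selected = max_selected,
                        max_overlap = max_overlap, min_level = min_level)
  sel
}
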